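# Planted-partition synthetic z-score tables.
#
# The generator emulates the statistical shape of inhibitor-perturbation
# kinase-pair z-score tables: unordered pairs, a negative tail carrying the
# inhibited interactions (with a heavy-tailed component reaching magnitudes
# far beyond the bulk, as in the empirical summary statistics), a sprinkle
# of small positive values, and a planted community structure in which
# within-community pairs are more likely to receive strong negative
# z-scores than between-community pairs. The planted truth makes every
# pipeline stage testable end to end.

#' Specification of a planted z-score table
#'
#' Defaults describe a clearly recoverable three-community instance (60
#' kinases, communities of 20; within-community pairs present with
#' probability 0.6 at mean z -1.5, between-community pairs with
#' probability 0.1 at mean z -0.2). The heavy-tail component redraws a
#' small fraction of within-community z-scores from a much stronger
#' negative mean so minima can reach magnitudes of order 10-17, as in
#' empirical negative-tail summaries.
#'
#' @param n_kinases Number of kinases.
#' @param community_sizes Integer vector of planted community sizes,
#'   summing to `n_kinases`.
#' @param p_within,p_between Probability that a within-/between-community
#'   pair receives a negative z-score.
#' @param mu_within,mu_between Negative means of the (pre-truncation)
#'   normal draws for within-/between-community z-scores.
#' @param sigma_within,sigma_between Positive standard deviations of those
#'   draws.
#' @param heavy_tail_fraction Fraction of within-community negative draws
#'   redrawn from the heavy-tail component `Normal(mu_heavy, sigma_heavy)`.
#' @param mu_heavy,sigma_heavy Mean and sd of the heavy-tail component.
#' @param positive_noise_fraction Fraction of the remaining (absent) pairs
#'   given a small positive z-score `|Normal(0.3, 0.2)|`.
#' @param pathway_community Index of the community designated as the
#'   planted "pathway"; its first member is the target and its first three
#'   members are the anchors recorded in the ground truth.
#' @param seed Integer seed; generation is reproducible per seed.
#' @return An object of class `synthetic_spec`. A warning is raised if
#'   neither `p_within > p_between` nor `|mu_within| > |mu_between|`, since
#'   such an instance carries no recoverable planted signal.
#' @export
synthetic_spec <- function(n_kinases = 60L, community_sizes = c(20L, 20L, 20L),
                           p_within = 0.6, p_between = 0.1,
                           mu_within = -1.5, mu_between = -0.2,
                           sigma_within = 0.5, sigma_between = 0.2,
                           heavy_tail_fraction = 0.05,
                           mu_heavy = -8, sigma_heavy = 4,
                           positive_noise_fraction = 0.1,
                           pathway_community = 1L, seed = 1L) {
  spec <- list(n_kinases = as.integer(n_kinases),
               community_sizes = as.integer(community_sizes),
               p_within = p_within, p_between = p_between,
               mu_within = mu_within, mu_between = mu_between,
               sigma_within = sigma_within, sigma_between = sigma_between,
               heavy_tail_fraction = heavy_tail_fraction,
               mu_heavy = mu_heavy, sigma_heavy = sigma_heavy,
               positive_noise_fraction = positive_noise_fraction,
               pathway_community = as.integer(pathway_community),
               seed = as.integer(seed))
  if (sum(spec$community_sizes) != spec$n_kinases) {
    kc_abort("`community_sizes` must sum to `n_kinases`", "kc_validation_error")
  }
  if (any(spec$community_sizes < 1L)) {
    kc_abort("community sizes must be positive", "kc_validation_error")
  }
  probs <- c(spec$p_within, spec$p_between, spec$heavy_tail_fraction,
             spec$positive_noise_fraction)
  if (any(probs < 0 | probs > 1)) {
    kc_abort("probabilities and fractions must lie in [0, 1]",
             "kc_validation_error")
  }
  if (any(c(spec$sigma_within, spec$sigma_between, spec$sigma_heavy) <= 0)) {
    kc_abort("all sigmas must be positive", "kc_validation_error")
  }
  if (any(c(spec$mu_within, spec$mu_between, spec$mu_heavy) >= 0)) {
    kc_abort("negative-tail means must be strictly negative",
             "kc_validation_error")
  }
  if (spec$pathway_community < 1L ||
      spec$pathway_community > length(spec$community_sizes)) {
    kc_abort("`pathway_community` out of range", "kc_validation_error")
  }
  if (!(spec$p_within > spec$p_between ||
        abs(spec$mu_within) > abs(spec$mu_between))) {
    warning("neither p_within > p_between nor |mu_within| > |mu_between|: ",
            "the planted structure is not recoverable", call. = FALSE)
  }
  class(spec) <- "synthetic_spec"
  spec
}

# Normal draws truncated to the strictly negative half-line by redrawing,
# so the component means stay interpretable as the pre-truncation means.
rnorm_negative <- function(mu, sigma) {
  z <- stats::rnorm(length(mu), mu, sigma)
  while (any(pos <- z >= 0)) {
    z[pos] <- stats::rnorm(sum(pos), mu[pos], sigma[pos])
  }
  z
}

#' Generate a planted z-score table
#'
#' Draws one treatment column (named `"synthetic"`) of z-scores over all
#' unordered kinase pairs according to the spec: within-community pairs get
#' a negative z with probability `p_within` (mixture of bulk and heavy-tail
#' truncated-normal components), between-community pairs with probability
#' `p_between`; a `positive_noise_fraction` of the remaining pairs get a
#' small positive z; all other pairs are missing and are dropped from the
#' table. Kinases are named `KIN001`, `KIN002`, ...
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [zscore_table()]) and `truth` (class
#'   `ground_truth`: `partition` over all kinase names, `pathway_community`
#'   index, `target` and `anchors` drawn from the head of the pathway
#'   community).
#' @export
generate_planted_zscores <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_kinases
  nodes <- sprintf("KIN%03d", seq_len(n))
  memb <- rep(seq_along(spec$community_sizes), spec$community_sizes)
  idx <- utils::combn(n, 2L)
  ia <- idx[1L, ]; ib <- idx[2L, ]
  within <- memb[ia] == memb[ib]

  u <- stats::runif(length(ia))
  present <- ifelse(within, u < spec$p_within, u < spec$p_between)

  z <- rep(NA_real_, length(ia))
  if (any(present)) {
    heavy <- within & present &
      stats::runif(length(ia)) < spec$heavy_tail_fraction
    mu <- ifelse(within, spec$mu_within, spec$mu_between)
    sigma <- ifelse(within, spec$sigma_within, spec$sigma_between)
    mu[heavy] <- spec$mu_heavy
    sigma[heavy] <- spec$sigma_heavy
    z[present] <- rnorm_negative(mu[present], sigma[present])
  }
  absent <- !present
  if (any(absent)) {
    pos <- absent & stats::runif(length(ia)) < spec$positive_noise_fraction
    z[pos] <- abs(stats::rnorm(sum(pos), 0.3, 0.2))
  }

  keep <- !is.na(z)
  table <- zscore_table(data.frame(kinase_a = nodes[ia[keep]],
                                   kinase_b = nodes[ib[keep]],
                                   synthetic = z[keep],
                                   stringsAsFactors = FALSE))
  pathway_nodes <- nodes[memb == spec$pathway_community]
  truth <- structure(list(
    partition = stats::setNames(memb, nodes),
    pathway_community = spec$pathway_community,
    target = pathway_nodes[1L],
    anchors = pathway_nodes[seq_len(min(3L, length(pathway_nodes)))]),
    class = "ground_truth")
  list(table = table, truth = truth)
}

# Moments of a normal truncated to the strictly negative half-line.
tnorm_neg_moments <- function(mu, sigma) {
  beta <- -mu / sigma
  lam <- stats::dnorm(beta) / stats::pnorm(beta)
  m <- mu - sigma * lam
  v <- sigma^2 * (1 - beta * lam - lam^2)
  c(mean = m, var = v)
}

#' Theoretical negative-tail moments of a synthetic spec
#'
#' Mean and standard deviation of the mixture of truncated-normal
#' components that the generator's negative z-scores follow, weighted by
#' the expected number of draws of each component. Used to check that
#' empirical negative-tail statistics of generated tables converge to the
#' spec (law of large numbers) and to calibrate spec parameters against
#' empirical summary tables.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `mean`, `sd` and the expected number of negative
#'   draws `n_expected`.
#' @export
negative_tail_moments <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sizes <- spec$community_sizes
  n_within <- sum(choose(sizes, 2))
  n_between <- choose(spec$n_kinases, 2) - n_within
  w <- c(bulk = n_within * spec$p_within * (1 - spec$heavy_tail_fraction),
         heavy = n_within * spec$p_within * spec$heavy_tail_fraction,
         between = n_between * spec$p_between)
  mom <- rbind(bulk = tnorm_neg_moments(spec$mu_within, spec$sigma_within),
               heavy = tnorm_neg_moments(spec$mu_heavy, spec$sigma_heavy),
               between = tnorm_neg_moments(spec$mu_between, spec$sigma_between))
  p <- w / sum(w)
  mean <- sum(p * mom[, "mean"])
  var <- sum(p * (mom[, "var"] + mom[, "mean"]^2)) - mean^2
  list(mean = mean, sd = sqrt(var), n_expected = sum(w))
}

#' Score recovery of the planted structure
#'
#' Compares a detected partition with the planted ground truth: overall
#' partition similarity (ARI, NMI) and, for the community containing the
#' designated target, precision and recall against the planted pathway
#' community.
#'
#' @param found Detected partition (named membership vector) over the
#'   generated node set.
#' @param truth A `ground_truth` from [generate_planted_zscores()].
#' @param target Kinase whose detected community is scored;
#'   defaults to the truth's designated target.
#' @return List with `ari`, `nmi`, `precision`, `recall`, `selected_size`,
#'   `planted_size`.
#' @export
evaluate_recovery <- function(found, truth, target = truth$target) {
  stopifnot(inherits(truth, "ground_truth"))
  found <- as_partition(found)
  planted <- as_partition(truth$partition)
  if (!identical(names(found), names(planted))) {
    kc_abort("detected partition must cover exactly the generated node set",
             "kc_coverage_error")
  }
  sim <- compare_partitions(found, planted)
  pathway_nodes <- names(truth$partition)[
    truth$partition == truth$pathway_community]
  sel <- select_community(found, target)
  overlap <- length(intersect(sel, pathway_nodes))
  list(ari = sim$ari, nmi = sim$nmi,
       precision = overlap / length(sel),
       recall = overlap / length(pathway_nodes),
       selected_size = length(sel),
       planted_size = length(pathway_nodes))
}
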