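# Consensus clustering over ensembles of Louvain partitions.
#
# A single Louvain run is a local optimum that depends on the random node
# order. The consensus procedure runs an ensemble of seeded Louvain runs,
# summarises it as a co-classification matrix (entry (i, j) = fraction of
# runs placing i and j in the same community), then re-runs community
# detection on that matrix, iterating until the co-classification matrix is
# binary; the consensus partition is read off its blocks. Typically one or
# two iterations suffice.

#' Co-classification matrix of a partition ensemble
#'
#' @param partitions List of partitions (named membership vectors) over a
#'   common node set.
#' @return An object of class `coclassification`: list with `nodes` (sorted
#'   names), `values` (symmetric matrix of co-assignment fractions in
#'   `[0, 1]`, diagonal 1), `counts` (integer co-assignment counts) and
#'   `ensemble_size`. Every value times `ensemble_size` is an integer.
#' @export
coclassification <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 1L) {
    kc_abort("need at least one partition", "kc_validation_error")
  }
  parts <- lapply(partitions, as_partition)
  nodes <- names(parts[[1L]])
  for (p in parts[-1L]) {
    if (!identical(names(p), nodes)) {
      kc_abort("all partitions must cover the same node set",
               "kc_coverage_error")
    }
  }
  n <- length(nodes)
  counts <- matrix(0, n, n)
  for (p in parts) {
    M <- membership_matrix(unname(p))
    counts <- counts + tcrossprod(M)
  }
  dimnames(counts) <- list(nodes, nodes)
  structure(list(nodes = nodes, values = counts / length(parts),
                 counts = counts, ensemble_size = length(parts)),
            class = "coclassification")
}

#' @export
print.coclassification <- function(x, ...) {
  cat(sprintf("<coclassification> %d nodes, ensemble of %d partitions, %s\n",
              length(x$nodes), x$ensemble_size,
              if (is_binary_coclassification(x)) "binary" else "non-binary"))
  invisible(x)
}

is_binary_coclassification <- function(cc) {
  all(cc$counts == 0 | cc$counts == cc$ensemble_size)
}

# Partition read off a binary co-classification matrix: the connected
# blocks of the 0/1 matrix viewed as a graph.
partition_from_binary <- function(cc) {
  adj <- (cc$counts == cc$ensemble_size) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  out <- canonical_labels(as.integer(memb))
  names(out) <- cc$nodes
  out
}

run_ensemble <- function(B, seeds) {
  nodes <- rownames(B)
  lapply(seeds, function(s) {
    memb <- louvain_on_B(B, s)
    names(memb) <- nodes
    memb
  })
}

#' Consensus partition by iterated co-classification
#'
#' Runs `ensemble_size` Louvain runs on the network (per-run seeds derived
#' deterministically from the master `seed`), computes the
#' co-classification matrix, and — while that matrix is not binary —
#' treats it as a weighted network over the same nodes (zero diagonal,
#' optional threshold `tau`) and repeats the ensemble on it under the same
#' null-model family and resolution. Stops when the co-classification
#' matrix is exactly binary; the consensus partition is its block
#' structure.
#'
#' @param network A [kinase_network()].
#' @param null A [null_model()]; also used on co-classification iterations.
#' @param ensemble_size Number of Louvain runs per iteration.
#' @param seed Master seed; per-run seeds are drawn from it and recorded in
#'   the result.
#' @param max_iterations Safety valve: exceeding it raises a
#'   non-convergence error that carries the last co-classification matrix
#'   in its `last_coclassification` field.
#' @param tau Optional threshold: co-classification entries `<= tau` are
#'   zeroed before re-clustering. The default 0 reiterates on the matrix
#'   as is.
#' @return An object of class `consensus_result`: list with `partition`
#'   (named membership vector), `iterations`, `history` (one
#'   [coclassification()] per iteration), `ensemble_size`, `seed`,
#'   `seeds` (matrix of per-run seeds actually used) and `null`.
#' @export
consensus_partition <- function(network, null = null_model(),
                                ensemble_size = 100L, seed = 1L,
                                max_iterations = 20L, tau = 0) {
  stopifnot(inherits(network, "kinase_network"))
  if (ensemble_size < 1L) {
    kc_abort("`ensemble_size` must be at least 1", "kc_validation_error")
  }
  all_seeds <- matrix(derive_seeds(seed, ensemble_size * max(1L, max_iterations)),
                      nrow = max(1L, max_iterations), byrow = TRUE)
  W <- network$weights
  history <- list()
  it <- 0L
  repeat {
    if (it >= max_iterations) {
      kc_abort(sprintf(
        "co-classification matrix not binary after %d iterations", it),
        "kc_convergence_error",
        last_coclassification = if (length(history)) history[[length(history)]])
    }
    it <- it + 1L
    B <- W - null_matrix_from_weights(W, null)
    parts <- run_ensemble(B, all_seeds[it, ])
    cc <- coclassification(parts)
    history[[it]] <- cc
    if (is_binary_coclassification(cc)) break
    W <- cc$values
    diag(W) <- 0
    if (tau > 0) W[W <= tau] <- 0
    dimnames(W) <- list(cc$nodes, cc$nodes)
  }
  structure(list(partition = partition_from_binary(history[[it]]),
                 iterations = it, history = history,
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed),
                 seeds = all_seeds[seq_len(it), , drop = FALSE],
                 null = null),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  k <- length(unique(x$partition))
  cat(sprintf(
    "<consensus_result> %d nodes in %d communities after %d iteration(s) (ensemble %d, %s null)\n",
    length(x$partition), k, x$iterations, x$ensemble_size, x$null$kind))
  invisible(x)
}

#' Similarity of two partitions
#'
#' Adjusted Rand index and normalised mutual information between two
#' partitions of the same node set, computed from the contingency table of
#' community co-memberships. Both equal 1 exactly when the partitions are
#' identical up to relabeling; the ARI is 0 in expectation for independent
#' partitions (and exactly 0 against the all-singletons partition), and
#' the NMI uses the symmetric `2 I / (H1 + H2)` normalisation (defined as
#' 1 when both partitions are trivial, hence identical).
#'
#' @param p1,p2 Partitions (named membership vectors) over the same nodes.
#' @return List with fields `ari` and `nmi`.
#' @export
compare_partitions <- function(p1, p2) {
  a <- as_partition(p1)
  b <- as_partition(p2)
  if (!identical(names(a), names(b))) {
    kc_abort("partitions must cover the same node set", "kc_coverage_error")
  }
  n <- length(a)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) {
    # both partitions trivial (all-in-one or all-singletons): identical
    if (identical(unname(a), unname(b))) 1 else 0
  } else {
    (sum_ij - expected) / denom
  }
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  pj <- tab / n
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  nmi <- if (ha + hb == 0) 1 else 2 * mi / (ha + hb)
  list(ari = ari, nmi = nmi)
}

#' Robustness of the consensus procedure
#'
#' Repeats the whole consensus procedure with distinct master seeds and
#' reports all pairwise partition similarities. On networks with clear-cut
#' community structure every pairwise similarity should be 1.
#'
#' @inheritParams consensus_partition
#' @param repeats Number of independent consensus runs (at least 2).
#' @return List with `repeats`, `partitions`, a `pairwise` data frame of
#'   per-pair ARI/NMI, and summary fields `min_ari`, `mean_ari`, `min_nmi`,
#'   `mean_nmi`.
#' @export
consensus_robustness <- function(network, null = null_model(), repeats = 5L,
                                 ensemble_size = 100L, seed = 1L,
                                 max_iterations = 20L) {
  if (repeats < 2L) {
    kc_abort("`repeats` must be at least 2", "kc_validation_error")
  }
  master_seeds <- derive_seeds(seed, repeats)
  runs <- lapply(master_seeds, function(s) {
    consensus_partition(network, null, ensemble_size = ensemble_size,
                        seed = s, max_iterations = max_iterations)
  })
  parts <- lapply(runs, `[[`, "partition")
  pairs <- utils::combn(repeats, 2L)
  pw <- data.frame(first = pairs[1L, ], second = pairs[2L, ],
                   ari = NA_real_, nmi = NA_real_)
  for (r in seq_len(ncol(pairs))) {
    s <- compare_partitions(parts[[pairs[1L, r]]], parts[[pairs[2L, r]]])
    pw$ari[r] <- s$ari
    pw$nmi[r] <- s$nmi
  }
  list(repeats = as.integer(repeats), partitions = parts, pairwise = pw,
       min_ari = min(pw$ari), mean_ari = mean(pw$ari),
       min_nmi = min(pw$nmi), mean_nmi = mean(pw$nmi))
}
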