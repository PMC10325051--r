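# Pathway-orientated analysis of detected communities: select the community
# containing an inhibitor's main target, measure per-node community
# strength, intersect selected communities across treatments, apply the
# anchor-edge filter and rank candidate pathway members.

#' Community containing a target kinase
#'
#' @param partition Named membership vector (e.g. from
#'   [consensus_partition()]).
#' @param target Kinase name, after any alias merging (e.g. `"AKT1/2"`).
#' @return Sorted character vector: the members of the unique community
#'   containing `target`.
#' @export
select_community <- function(partition, target) {
  p <- as_partition(partition)
  if (!target %in% names(p)) {
    kc_abort(sprintf(
      "target '%s' is not a node of the partitioned network; check spelling or apply alias merging first",
      target),
      "kc_lookup_error")
  }
  sort(names(p)[p == p[[target]]])
}

#' Community strength of a node
#'
#' The community strength (CS) of a member is the sum of the weights of its
#' edges to the other members of its community; edges to nodes outside the
#' community do not contribute. With |z| edge weights, a large CS means the
#' node's within-community interactions were strongly inhibited.
#'
#' @param network A [kinase_network()].
#' @param community Character vector of community members (a subset of the
#'   network's nodes).
#' @param member One community member.
#' @return Non-negative real: the community strength of `member`.
#' @export
community_strength <- function(network, community, member) {
  stopifnot(inherits(network, "kinase_network"))
  extra <- setdiff(community, network$nodes)
  if (length(extra)) {
    kc_abort(sprintf("community members not in network: %s",
                     paste(extra, collapse = ", ")),
             "kc_coverage_error")
  }
  if (!member %in% community) {
    kc_abort(sprintf("'%s' is not a member of the community", member),
             "kc_argument_error")
  }
  others <- setdiff(community, member)
  if (!length(others)) return(0)
  sum(network$weights[member, others])
}

#' Per-member community report for a target's community
#'
#' Convenience constructor: selects the community containing `target`,
#' computes every member's community strength and ranks members by
#' decreasing absolute CS (ties share the smaller rank).
#'
#' @param network A [kinase_network()].
#' @param partition Named membership vector over the network's nodes.
#' @param target Kinase whose community is reported.
#' @return An object of class `community_report`: list with `network_id`
#'   (treatment and sign), `target`, `members`, `strength` (named numeric)
#'   and `strength_rank` (named integer).
#' @export
community_report <- function(network, partition, target) {
  stopifnot(inherits(network, "kinase_network"))
  align_partition(partition, network$nodes)   # coverage check
  members <- select_community(partition, target)
  cs <- vapply(members, function(m) community_strength(network, members, m),
               numeric(1))
  rk <- rank(-abs(cs), ties.method = "min")
  structure(list(
    network_id = paste0(network$treatment %||% "network", "_",
                        network$sign %||% "any"),
    target = target,
    members = members,
    strength = cs,
    strength_rank = stats::setNames(as.integer(rk), members)),
    class = "community_report")
}

#' @export
print.community_report <- function(x, ...) {
  cat(sprintf("<community_report> %s: community of %s (%d members)\n",
              x$network_id, x$target, length(x$members)))
  ord <- order(x$strength_rank)
  df <- data.frame(member = x$members[ord],
                   strength = unname(x$strength[ord]),
                   rank = unname(x$strength_rank[ord]))
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("... and %d more members\n", nrow(df) - 10L))
  invisible(x)
}

#' Intersection of two selected communities
#'
#' @param first,second Character vectors of community members.
#' @return List of class `intersection_report` with disjoint sorted sets
#'   `shared`, `only_first`, `only_second`.
#' @export
intersect_communities <- function(first, second) {
  structure(list(shared = sort(intersect(first, second)),
                 only_first = sort(setdiff(first, second)),
                 only_second = sort(setdiff(second, first))),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("<intersection_report> shared %d | only first %d | only second %d\n",
              length(x$shared), length(x$only_first), length(x$only_second)))
  invisible(x)
}

#' Anchor-edge filter
#'
#' Keeps the community members (excluding the anchors themselves) that have
#' a direct positive-weight edge to every anchor kinase in the full
#' treatment network. A kinase lacking a direct interaction with any one
#' anchor of a canonical pathway is less likely to sit downstream of the
#' whole pathway. Adding anchors can only shrink the result.
#'
#' @param network A [kinase_network()] (the full network for the treatment,
#'   not the community subgraph).
#' @param community Character vector of community members scoping the
#'   candidate list.
#' @param anchors Character vector of anchor kinases; all must be nodes of
#'   the network.
#' @return Sorted character vector of surviving candidate kinases.
#' @export
anchor_filter <- function(network, community, anchors) {
  stopifnot(inherits(network, "kinase_network"))
  missing <- setdiff(anchors, network$nodes)
  if (length(missing)) {
    kc_abort(sprintf("anchor(s) not in network: %s",
                     paste(missing, collapse = ", ")),
             "kc_lookup_error")
  }
  candidates <- setdiff(intersect(community, network$nodes), anchors)
  if (!length(candidates) || !length(anchors)) return(sort(candidates))
  Wc <- network$weights[candidates, anchors, drop = FALSE]
  sort(candidates[rowSums(Wc > 0) == length(anchors)])
}

#' Rank candidate kinases across community reports
#'
#' Joins per-report community strengths and ranks for a set of candidate
#' kinases, ordering the table by the best (minimum) across-report CS rank,
#' then by mean CS (descending), then by name.
#'
#' @param reports List of [community_report()] objects.
#' @param candidates Character vector of kinases present in every report's
#'   community.
#' @return Data frame with one row per candidate: per-report `cs_*` and
#'   `rank_*` columns, `min_rank`, `mean_cs`, sorted as described.
#' @export
rank_candidates <- function(reports, candidates) {
  if (!length(reports)) kc_abort("need at least one report", "kc_validation_error")
  if (inherits(reports, "community_report")) reports <- list(reports)
  candidates <- sort(unique(candidates))
  for (rep in reports) {
    absent <- setdiff(candidates, rep$members)
    if (length(absent)) {
      kc_abort(sprintf("candidate(s) absent from report %s: %s",
                       rep$network_id, paste(absent, collapse = ", ")),
               "kc_coverage_error")
    }
  }
  ids <- vapply(reports, `[[`, character(1), "network_id")
  ids <- make.unique(ids, sep = "_")
  out <- data.frame(candidate = candidates, stringsAsFactors = FALSE)
  for (r in seq_along(reports)) {
    out[[paste0("cs_", ids[r])]] <- unname(reports[[r]]$strength[candidates])
    out[[paste0("rank_", ids[r])]] <-
      unname(reports[[r]]$strength_rank[candidates])
  }
  rank_cols <- grep("^rank_", names(out))
  cs_cols <- grep("^cs_", names(out))
  out$min_rank <- do.call(pmin, out[rank_cols])
  out$mean_cs <- rowMeans(as.matrix(out[cs_cols]))
  out <- out[order(out$min_rank, -out$mean_cs, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    kc_abort("`config` must be a list or a path to a YAML file",
             "kc_config_error")
  }
  trt <- config$treatments
  if (is.list(trt)) trt <- unlist(trt)
  if (is.null(trt) || is.null(names(trt)) || any(names(trt) == "")) {
    kc_abort("config$treatments must map treatment names to target kinases",
             "kc_config_error")
  }
  if (any(is.na(trt) | trt == "")) {
    bad <- names(trt)[is.na(trt) | trt == ""]
    kc_abort(sprintf("config is missing a target kinase for treatment(s): %s",
                     paste(bad, collapse = ", ")),
             "kc_config_error")
  }
  config$treatments <- trt
  config$sign <- config$sign %||% "negative"
  if (!config$sign %in% c("negative", "positive")) {
    kc_abort("config$sign must be 'negative' or 'positive'", "kc_config_error")
  }
  config$null <- config$null %||% "uniform"
  config$gamma <- config$gamma %||% 1
  config$ensemble <- as.integer(config$ensemble %||% 100L)
  config$seed <- as.integer(config$seed %||% 1L)
  config$max_iterations <- as.integer(config$max_iterations %||% 20L)
  config$aliases <- config$aliases %||% character(0)
  if (is.list(config$aliases)) config$aliases <- unlist(config$aliases)
  config$anchors <- unlist(config$anchors %||% character(0), use.names = FALSE)
  config$anchor_treatment <- config$anchor_treatment %||% names(trt)[1L]
  if (!config$anchor_treatment %in% names(trt)) {
    kc_abort("config$anchor_treatment must be one of the named treatments",
             "kc_config_error")
  }
  config$excluded_known_members <-
    unlist(config$excluded_known_members %||% character(0), use.names = FALSE)
  config
}

#' Run the full community-to-candidates pipeline
#'
#' Composes the whole analysis for a z-score table: optional alias merging;
#' per-treatment network construction at the configured sign; consensus
#' community detection; selection of the community containing each
#' treatment's target; intersection of the first two selected communities;
#' anchor-edge filtering of the anchor treatment's community; and CS-based
#' ranking of surviving candidates across all selected communities. The
#' result is fully determined by the table, the config and the master seed.
#'
#' @param table A [zscore_table()].
#' @param config A list (or path to a YAML file) with fields: `treatments`
#'   (named vector, treatment column -> target kinase; required), `sign`
#'   (`"negative"` default), `null` (`"uniform"` default or
#'   `"newman-girvan"`), `gamma` (resolution, default 1), `ensemble`
#'   (default 100), `seed` (default 1), `max_iterations` (default 20),
#'   `aliases` (named vector old -> merged name), `anchors` (anchor
#'   kinases for the filter), `anchor_treatment` (which treatment's network
#'   scopes the filter; default the first), and `excluded_known_members`
#'   (kinases flagged as already-known pathway members, excluded from the
#'   candidate ranking).
#' @return An object of class `pipeline_report`: a nested list with the
#'   resolved `config` (including derived per-treatment seeds), one entry
#'   per treatment (network size, consensus partition and iterations,
#'   community report), the `intersection`, `anchor_survivors`, `ranking`
#'   (data frame) and `unranked_candidates`. Serialise with
#'   [write_report()]; identical inputs give byte-identical reports.
#' @export
run_pipeline <- function(table, config) {
  stopifnot(inherits(table, "zscore_table"))
  config <- validate_pipeline_config(config)
  missing_trt <- setdiff(names(config$treatments), treatments(table))
  if (length(missing_trt)) {
    kc_abort(sprintf("config names treatments absent from the table: %s",
                     paste(missing_trt, collapse = ", ")),
             "kc_config_error")
  }
  if (length(config$aliases)) {
    table <- merge_aliases(table, config$aliases)
  }
  null <- null_model(config$null, resolution = config$gamma)
  trt_names <- names(config$treatments)
  trt_seeds <- derive_seeds(config$seed, length(trt_names))

  networks <- list()
  reports <- list()
  per_treatment <- list()
  for (i in seq_along(trt_names)) {
    trt <- trt_names[i]
    target <- unname(config$treatments[[trt]])
    net <- build_network(table, trt, config$sign)
    cons <- consensus_partition(net, null, ensemble_size = config$ensemble,
                                seed = trt_seeds[i],
                                max_iterations = config$max_iterations)
    rep <- community_report(net, cons$partition, target)
    networks[[trt]] <- net
    reports[[trt]] <- rep
    per_treatment[[trt]] <- list(
      target = target,
      seed = trt_seeds[i],
      n_nodes = length(net$nodes),
      n_edges = nrow(network_edges(net)),
      consensus_iterations = cons$iterations,
      n_communities = length(unique(cons$partition)),
      partition = as.list(cons$partition),
      community = list(members = rep$members,
                       strength = as.list(rep$strength),
                       strength_rank = as.list(rep$strength_rank)))
  }

  intersection <- NULL
  if (length(trt_names) >= 2L) {
    ir <- intersect_communities(reports[[trt_names[1L]]]$members,
                                reports[[trt_names[2L]]]$members)
    intersection <- list(first = trt_names[1L], second = trt_names[2L],
                         shared = ir$shared, only_first = ir$only_first,
                         only_second = ir$only_second)
  }

  survivors <- character(0)
  if (length(config$anchors)) {
    at <- config$anchor_treatment
    survivors <- anchor_filter(networks[[at]], reports[[at]]$members,
                               config$anchors)
  }

  candidates <- setdiff(survivors, config$excluded_known_members)
  in_all <- candidates[vapply(candidates, function(k) {
    all(vapply(reports, function(r) k %in% r$members, logical(1)))
  }, logical(1))]
  ranking <- NULL
  if (length(in_all)) {
    ranking <- rank_candidates(unname(reports), in_all)
  }

  structure(list(
    config = config[order(names(config))],
    treatment_seeds = stats::setNames(as.list(trt_seeds), trt_names),
    treatments = per_treatment,
    intersection = intersection,
    anchor_survivors = survivors,
    unranked_candidates = setdiff(candidates, in_all),
    ranking = ranking),
    class = "pipeline_report")
}

#' Serialise a pipeline report to JSON
#'
#' Stable, replayable JSON: the embedded config and derived seeds allow the
#' exact run to be reproduced, and two runs with the same inputs produce
#' byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output path; if `NULL`, the JSON string is returned instead.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", dataframe = "rows")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d treatment(s): %s\n",
              length(x$treatments), paste(names(x$treatments), collapse = ", ")))
  for (trt in names(x$treatments)) {
    t <- x$treatments[[trt]]
    cat(sprintf("  %s: %d nodes, %d edges, %d communities (%d consensus iteration(s)); community of %s has %d members\n",
                trt, t$n_nodes, t$n_edges, t$n_communities,
                t$consensus_iterations, t$target, length(t$community$members)))
  }
  if (!is.null(x$intersection)) {
    cat(sprintf("  intersection %s vs %s: %d shared\n", x$intersection$first,
                x$intersection$second, length(x$intersection$shared)))
  }
  if (length(x$anchor_survivors)) {
    cat(sprintf("  anchor survivors: %s\n",
                paste(x$anchor_survivors, collapse = ", ")))
  }
  if (!is.null(x$ranking)) {
    cat("  candidate ranking:\n")
    print(x$ranking, row.names = FALSE)
  }
  invisible(x)
}
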