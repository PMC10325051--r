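# Weighted, undirected kinase networks built from sign-filtered z-scores.
#
# One network per treatment and sign: edges are the kinase pairs whose
# z-score is strictly of the requested sign, edge weight is |z| (the extent
# of inhibition for the negative tail), and the node set is the union of the
# endpoints of retained edges. No self-loops, no isolated nodes.

#' Construct a kinase network from an adjacency matrix
#'
#' Low-level constructor validating the invariants of the weighted
#' undirected kinase network: symmetric non-negative weights, zero diagonal,
#' and every node incident to at least one edge.
#'
#' @param nodes Character vector of kinase names (row/column order of
#'   `weights`).
#' @param weights Symmetric numeric matrix of non-negative edge weights with
#'   zero diagonal.
#' @param treatment,sign Optional metadata recording which treatment column
#'   and which z-score sign produced the network.
#' @return An object of class `kinase_network`: a list with fields `nodes`,
#'   `weights` (dimnames set to `nodes`), `treatment`, `sign` and
#'   `total_weight` (the sum of all matrix entries, i.e. twice the total
#'   edge weight, written 2m).
#' @export
kinase_network <- function(nodes, weights, treatment = NA_character_,
                           sign = NA_character_) {
  nodes <- as.character(nodes)
  if (!is.matrix(weights) || nrow(weights) != length(nodes) ||
      ncol(weights) != length(nodes)) {
    kc_abort("`weights` must be a square matrix matching `nodes`",
             "kc_validation_error")
  }
  if (anyDuplicated(nodes)) {
    kc_abort("node names must be unique", "kc_validation_error")
  }
  if (anyNA(weights)) {
    kc_abort("weights must not contain NA", "kc_validation_error")
  }
  if (any(weights < 0)) {
    kc_abort("negative edge weight", "kc_validation_error")
  }
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    kc_abort("weight matrix must be symmetric (undirected network)",
             "kc_validation_error")
  }
  if (any(diag(weights) != 0)) {
    kc_abort("self-loops are not allowed (non-zero diagonal)",
             "kc_validation_error")
  }
  if (length(nodes) && any(rowSums(weights) == 0)) {
    isolated <- nodes[rowSums(weights) == 0]
    kc_abort(sprintf("isolated node(s) not allowed: %s",
                     paste(isolated, collapse = ", ")),
             "kc_validation_error")
  }
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights,
                 treatment = treatment, sign = sign,
                 total_weight = sum(weights)),
            class = "kinase_network")
}

#' Build the kinase network of one treatment
#'
#' Retains the kinase pairs whose z-score for `treatment` is strictly of the
#' requested sign, sets the edge weight to the absolute value of the
#' z-score, and takes as nodes exactly the kinases participating in a
#' retained pair. Nodes are ordered lexicographically so the adjacency
#' matrix is reproducible regardless of input row order.
#'
#' @param table A [zscore_table()].
#' @param treatment Treatment name.
#' @param sign `"negative"` (inhibited interactions, the default analysis)
#'   or `"positive"` (upregulated interactions).
#' @return A [kinase_network()].
#' @export
build_network <- function(table, treatment, sign = c("negative", "positive")) {
  stopifnot(inherits(table, "zscore_table"))
  sign <- match.arg(sign)
  if (!treatment %in% treatments(table)) {
    kc_abort(sprintf("treatment '%s' not present", treatment), "kc_lookup_error")
  }
  z <- table[[treatment]]
  keep <- !is.na(z) & if (sign == "negative") z < 0 else z > 0
  if (!any(keep)) {
    kc_abort(sprintf("no %s z-scores for treatment '%s': empty network",
                     sign, treatment),
             "kc_empty_network_error")
  }
  a <- table$kinase_a[keep]
  b <- table$kinase_b[keep]
  w <- abs(z[keep])
  nodes <- sort(unique(c(a, b)))
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(a, nodes); ib <- match(b, nodes)
  W[cbind(ia, ib)] <- w
  W[cbind(ib, ia)] <- w
  kinase_network(nodes, W, treatment = treatment, sign = sign)
}

#' Edge list of a kinase network
#' @param network A [kinase_network()].
#' @return Data frame with columns `kinase_a`, `kinase_b`, `weight`, one row
#'   per undirected edge, pair members in lexicographic order.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "kinase_network"))
  W <- network$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(kinase_a = network$nodes[idx[, 1L]],
             kinase_b = network$nodes[idx[, 2L]],
             weight = W[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.kinase_network <- function(x, ...) {
  cat(sprintf("<kinase_network> %d nodes, %d edges, total weight (2m) %.4g\n",
              length(x$nodes), nrow(network_edges(x)), x$total_weight))
  cat(sprintf("  treatment: %s   sign: %s\n", x$treatment, x$sign))
  invisible(x)
}

#' Write a kinase network to disk
#'
#' GraphML (via igraph) is lossless: node names, edge weights and the
#' treatment/sign metadata survive a round-trip through [read_network()].
#' The edge-list format is a plain CSV `kinase_a,kinase_b,weight` for
#' interoperability; treatment/sign are not stored.
#'
#' @param network A [kinase_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edge-list"`.
#' @export
write_network <- function(network, path, format = c("graphml", "edge-list")) {
  stopifnot(inherits(network, "kinase_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(network$weights,
                                             mode = "undirected",
                                             weighted = TRUE)
    if (!is.na(network$treatment)) {
      g <- igraph::set_graph_attr(g, "treatment", network$treatment)
    }
    if (!is.na(network$sign)) {
      g <- igraph::set_graph_attr(g, "sign", network$sign)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.csv(network_edges(network), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a kinase network from disk
#'
#' @param path File written by [write_network()].
#' @param format `"graphml"` or `"edge-list"`.
#' @param treatment,sign Metadata to attach when reading an edge list (the
#'   CSV format does not store them); ignored for GraphML, which carries its
#'   own.
#' @return A [kinase_network()].
#' @export
read_network <- function(path, format = c("graphml", "edge-list"),
                         treatment = NA_character_, sign = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path) || file.size(path) == 0) {
    kc_abort(sprintf("empty or missing network file: %s", path),
             "kc_format_error")
  }
  if (format == "graphml") {
    g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                  error = function(e) {
                    kc_abort(sprintf("malformed GraphML file %s: %s", path,
                                     conditionMessage(e)),
                             "kc_format_error")
                  })
    if (igraph::is_directed(g)) {
      kc_abort("directed graph in GraphML file; kinase networks are undirected",
               "kc_validation_error")
    }
    if (!"weight" %in% igraph::edge_attr_names(g)) {
      kc_abort("GraphML file lacks the 'weight' edge attribute",
               "kc_format_error")
    }
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    nodes <- igraph::V(g)$name %||% as.character(seq_len(nrow(W)))
    dimnames(W) <- list(nodes, nodes)
    ord <- order(nodes)
    gt <- function(at) {
      if (at %in% igraph::graph_attr_names(g)) igraph::graph_attr(g, at)
      else NA_character_
    }
    kinase_network(nodes[ord], W[ord, ord, drop = FALSE],
                   treatment = gt("treatment"), sign = gt("sign"))
  } else {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) {
                     kc_abort(sprintf("malformed edge list %s: %s", path,
                                      conditionMessage(e)),
                              "kc_format_error")
                   })
    need <- c("kinase_a", "kinase_b", "weight")
    if (!all(need %in% names(df))) {
      kc_abort("edge list must have columns kinase_a, kinase_b, weight",
               "kc_format_error")
    }
    if (anyNA(df$weight) || !is.numeric(df$weight)) {
      kc_abort("edge weights must be numeric and non-missing",
               "kc_validation_error")
    }
    if (any(df$weight < 0)) {
      kc_abort("negative edge weight in edge list", "kc_validation_error")
    }
    nodes <- sort(unique(c(df$kinase_a, df$kinase_b)))
    W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    ia <- match(df$kinase_a, nodes); ib <- match(df$kinase_b, nodes)
    W[cbind(ia, ib)] <- df$weight
    W[cbind(ib, ia)] <- df$weight
    kinase_network(nodes, W, treatment = treatment, sign = sign)
  }
}
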