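# Modularity maximisation on weighted kinase networks.
#
# The quality function is the unnormalised modularity
#
#     Q(C) = sum_{i,j} (A_ij - P_ij) * delta(c_i, c_j)
#
# summed over ordered node pairs, where A is the weighted adjacency matrix,
# P the expected adjacency of a null network scaled by the resolution
# parameter gamma, and c_i the community of node i. Two null models are
# supported:
#
#   * Newman-Girvan: P_ij = gamma * s_i s_j / (2m) for all ordered pairs
#     (diagonal included), with s_i the strength (weighted degree) of node i
#     and 2m the total weight. Preserves the expected strength sequence; Q
#     of the one-community partition is exactly 0 at gamma = 1.
#   * uniform: constant expected weight P_ij = gamma * <w> off the diagonal
#     (P_ii = 0), with <w> = 2m / (n (n - 1)) the mean weight over distinct
#     node pairs; Q is identically 0 on constant-weight complete networks
#     at gamma = 1.
#
# Maximisation uses the locally greedy Louvain heuristic with node order
# randomised at the start of every sweep (so different seeds can return
# different local optima), plus an exhaustive oracle for small networks.

#' Specify a modularity null model
#'
#' @param kind `"newman-girvan"` (accepted abbreviation `"ng"`) or
#'   `"uniform"`.
#' @param resolution Positive resolution parameter gamma multiplying the
#'   null matrix; `1` analyses the network at a single natural scale and is
#'   the default throughout.
#' @return An object of class `null_model`.
#' @export
null_model <- function(kind = c("uniform", "newman-girvan", "ng"),
                       resolution = 1) {
  kind <- match.arg(kind)
  if (kind == "ng") kind <- "newman-girvan"
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    kc_abort("`resolution` must be a single positive number",
             "kc_validation_error")
  }
  structure(list(kind = kind, resolution = as.numeric(resolution)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> %s, resolution %g\n", x$kind, x$resolution))
  invisible(x)
}

null_matrix_from_weights <- function(W, null) {
  n <- nrow(W)
  tw <- sum(W)
  if (tw <= 0) {
    kc_abort("network has zero total weight: null matrix undefined",
             "kc_degenerate_error")
  }
  if (null$kind == "newman-girvan") {
    # The quality function sums over all ordered pairs including i = j, so
    # the diagonal P_ii = gamma s_i^2 / (2m) is kept: it is a
    # partition-independent offset that makes the one-community partition
    # score exactly 0 at gamma = 1 (the null preserves total strength).
    s <- rowSums(W)
    P <- null$resolution * tcrossprod(s) / tw
  } else {
    # Constant expected weight between distinct node pairs; no self-pairs.
    P <- matrix(null$resolution * tw / (n * (n - 1)), n, n)
    diag(P) <- 0
  }
  dimnames(P) <- dimnames(W)
  P
}

#' Expected null-network adjacency matrix
#'
#' @param network A [kinase_network()].
#' @param null A [null_model()].
#' @return Symmetric matrix P of expected edge weights under the null
#'   model, scaled by the resolution parameter. The Newman-Girvan null
#'   keeps its diagonal (expected self-pair weight, a
#'   partition-independent offset of the quality function); the uniform
#'   null has zero diagonal.
#' @export
null_matrix <- function(network, null = null_model()) {
  stopifnot(inherits(network, "kinase_network"), inherits(null, "null_model"))
  null_matrix_from_weights(network$weights, null)
}

#' Modularity matrix A - P
#'
#' @inheritParams null_matrix
#' @return The matrix `B = A - P` whose within-community sum is the
#'   modularity of a partition.
#' @export
modularity_matrix <- function(network, null = null_model()) {
  network$weights - null_matrix(network, null)
}

# Normalise any partition-like input to a named integer vector with
# canonical labels (consecutive, in order of first occurrence over sorted
# node names so equality is well defined).
as_partition <- function(x) {
  if (is.list(x) && !is.null(x$assignment)) x <- x$assignment
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    kc_abort("a partition must be a vector named by node", "kc_validation_error")
  }
  nodes <- sort(names(x))
  v <- x[nodes]
  out <- canonical_labels(as.vector(v))
  names(out) <- nodes
  out
}

#' Communities of a partition
#' @param partition Named vector mapping node name to community label.
#' @return List of character vectors, one sorted node set per community.
#' @export
partition_communities <- function(partition) {
  p <- as_partition(partition)
  unname(lapply(split(names(p), p), sort))
}

align_partition <- function(partition, nodes) {
  p <- as_partition(partition)
  if (!setequal(names(p), nodes)) {
    missing <- setdiff(nodes, names(p))
    extra <- setdiff(names(p), nodes)
    kc_abort(sprintf(
      "partition must cover exactly the network's nodes (missing: %s; extra: %s)",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
      "kc_coverage_error")
  }
  unname(p[nodes])
}

#' Modularity of a partition
#'
#' Evaluates `sum_{i,j} (A_ij - P_ij) delta(c_i, c_j)` over ordered node
#' pairs. Under the Newman-Girvan null at resolution 1 the one-community
#' partition always scores exactly 0.
#'
#' @param network A [kinase_network()].
#' @param partition Named vector mapping every network node to a community
#'   label (labels are arbitrary; only label equality matters).
#' @param null A [null_model()].
#' @return The modularity value (a real number, not normalised by 2m).
#' @export
modularity_score <- function(network, partition, null = null_model()) {
  comm <- align_partition(partition, network$nodes)
  B <- modularity_matrix(network, null)
  M <- membership_matrix(comm)
  sum(crossprod(M, B %*% M)[cbind(seq_len(ncol(M)), seq_len(ncol(M)))])
}

# One local-moving phase of Louvain on a (possibly aggregated) modularity
# matrix B. Sweeps nodes in a random order until a full sweep makes no move;
# each node joins the community with the largest positive modularity gain
# (ties broken towards the lowest community index). `tol` guards against
# cycling on floating-point noise.
local_moving <- function(B, tol = 1e-12) {
  n <- nrow(B)
  comm <- seq_len(n)
  M <- diag(n)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      old <- comm[i]
      M[i, old] <- 0
      gains <- drop(B[i, ] %*% M)   # gain/2 of joining each community
      best <- which.max(gains)
      if (gains[best] > gains[old] + tol) {
        comm[i] <- best
        M[i, best] <- 1
        moved <- TRUE
      } else {
        M[i, old] <- 1
      }
    }
    if (!moved) break
  }
  canonical_labels(comm)
}

# Full Louvain on a modularity matrix: local moving, then aggregation of B
# itself (which carries the null matrix through correctly for any null
# model), repeated until no further merge. Returns a membership vector over
# the original nodes.
louvain_on_B <- function(B, seed, tol = 1e-12) {
  set.seed(as.integer(seed))
  n0 <- nrow(B)
  groups <- as.list(seq_len(n0))
  repeat {
    comm <- local_moving(B, tol)
    k <- max(comm)
    if (k == nrow(B)) break
    M <- membership_matrix(comm, k)
    B <- crossprod(M, B %*% M)
    groups <- unname(lapply(split(seq_along(comm), comm),
                            function(ix) unlist(groups[ix], use.names = FALSE)))
    if (k == 1L) break
  }
  memb <- integer(n0)
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  canonical_labels(memb)
}

#' Louvain partition of a kinase network
#'
#' Locally greedy modularity maximisation: starting from singleton
#' communities, nodes are swept in a seed-determined random order (freshly
#' randomised at the start of every sweep) and moved to the community with
#' the largest strictly positive modularity gain; the network is then
#' aggregated, carrying the null matrix along via `B = A - P`, and the
#' procedure repeats until no move improves modularity. The result is a
#' local optimum of the modularity; different seeds can return different
#' local optima, and the same seed always returns the same partition.
#'
#' @param network A [kinase_network()].
#' @param null A [null_model()].
#' @param seed Integer seed controlling the random node orders.
#' @return Named integer vector: community membership per node, labels
#'   canonical (1, 2, ... in order of first occurrence).
#' @export
louvain_partition <- function(network, null = null_model(), seed = 1L) {
  stopifnot(inherits(network, "kinase_network"))
  B <- modularity_matrix(network, null)
  memb <- louvain_on_B(B, seed)
  names(memb) <- network$nodes
  memb
}

# Enumerate all set partitions of n elements as a Bell(n) x n integer matrix
# of canonical membership vectors, in lexicographic order (restricted growth
# strings). Cached for small n.
.partition_cache <- new.env(parent = emptyenv())
enumerate_partitions <- function(n) {
  key <- as.character(n)
  cached <- .partition_cache[[key]]
  if (!is.null(cached)) return(cached)
  P <- matrix(1L, 1L, 1L)
  if (n > 1L) {
    for (i in 2:n) {
      mx <- P[, ncol(P)]
      for (j in seq_len(ncol(P) - 1L)) mx <- pmax(mx, P[, j])
      reps <- mx + 1L
      idx <- rep.int(seq_len(nrow(P)), reps)
      newcol <- unlist(lapply(reps, seq_len), use.names = FALSE)
      P <- cbind(P[idx, , drop = FALSE], newcol, deparse.level = 0)
    }
  }
  if (n <= 9L) .partition_cache[[key]] <- P
  P
}

#' Exhaustive modularity maximisation (testing oracle)
#'
#' Enumerates every set partition of the node set (Bell-number search, so
#' only feasible for small networks) and returns the global maximiser of
#' the modularity. Ties are broken towards the partition with the fewest
#' communities, then the lexicographically smallest canonical membership
#' vector.
#'
#' @param network A [kinase_network()] with at most 12 nodes.
#' @param null A [null_model()].
#' @param tol Two partitions whose modularities differ by at most `tol` are
#'   treated as tied.
#' @return Named integer membership vector, as [louvain_partition()].
#' @export
brute_force_partition <- function(network, null = null_model(), tol = 1e-10) {
  stopifnot(inherits(network, "kinase_network"))
  n <- length(network$nodes)
  if (n > 12L) {
    kc_abort(sprintf("exhaustive search refused for n = %d (> 12 nodes)", n),
             "kc_size_error")
  }
  B <- modularity_matrix(network, null)
  P <- enumerate_partitions(n)
  b <- as.vector(B)
  # Q per partition via the flattened same-community mask, in chunks.
  nP <- nrow(P)
  Q <- numeric(nP)
  chunk <- 200000L
  for (start in seq(1L, nP, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nP)
    D <- matrix(0, length(rows), n * n)
    col <- 0L
    for (jb in seq_len(n)) {
      for (ja in seq_len(n)) {
        col <- col + 1L
        D[, col] <- as.numeric(P[rows, ja] == P[rows, jb])
      }
    }
    Q[rows] <- drop(D %*% b)
  }
  best_q <- max(Q)
  cand <- which(Q >= best_q - tol)
  k <- apply(P[cand, , drop = FALSE], 1L, max)
  cand <- cand[k == min(k)]
  # rows are generated in lexicographic order, so the first candidate is
  # the lexicographically smallest canonical form
  memb <- P[cand[1L], ]
  names(memb) <- network$nodes
  memb
}
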