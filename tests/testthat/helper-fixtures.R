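# Fixtures built in code: toy tables and networks reused across tests.

toy_table <- function() {
  zscore_table(data.frame(kinase_a = c("K1", "K1", "K2"),
                          kinase_b = c("K2", "K3", "K3"),
                          trt = c(-2, 1.5, -0.5)))
}

# Two 4-cliques (within-weight w_in) joined by a single weak bridge.
two_clique_network <- function(w_in = 1, w_bridge = 0.1) {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- w_in
  W[5:8, 5:8] <- w_in
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- w_bridge
  kinase_network(sprintf("N%d", 1:8), W)
}

# Random weighted network: each pair gets an edge with probability p,
# weights |N(0,1)| + 0.05; isolated nodes are wired to a random neighbour
# so the network invariants hold.
random_network <- function(n, seed, p = 0.5) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        W[i, j] <- W[j, i] <- abs(stats::rnorm(1)) + 0.05
      }
    }
  }
  for (i in which(rowSums(W) == 0)) {
    j <- sample(setdiff(seq_len(n), i), 1)
    W[i, j] <- W[j, i] <- abs(stats::rnorm(1)) + 0.05
  }
  kinase_network(sprintf("N%02d", seq_len(n)), W)
}

# Independent oracle for the quality function: direct term-by-term
# evaluation of sum_{i,j} (A_ij - P_ij) delta(c_i, c_j), with P computed
# from its definition right here (never through the package).
oracle_modularity <- function(W, comm, kind, gamma = 1) {
  n <- nrow(W)
  tw <- sum(W)
  if (kind == "newman-girvan") {
    s <- rowSums(W)
    P <- gamma * outer(s, s) / tw
  } else {
    P <- matrix(gamma * tw / (n * (n - 1)), n, n)
    diag(P) <- 0
  }
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) q <- q + W[i, j] - P[i, j]
    }
  }
  q
}

# Strongly separated planted spec used where exact recovery is expected.
strong_spec <- function(seed) {
  synthetic_spec(p_within = 0.9, p_between = 0.02, seed = seed)
}
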