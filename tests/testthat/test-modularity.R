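# Null matrices, the quality function, Louvain and the exhaustive oracle.

test_that("null matrices follow their defining formulas", {
  # single edge of weight w: strengths w, total 2w, so NG P_12 = w^2/(2w) = w/2
  w <- 3
  n2 <- kinase_network(c("A", "B"), matrix(c(0, w, w, 0), 2))
  P <- null_matrix(n2, null_model("newman-girvan"))
  expect_equal(P["A", "B"], w / 2)
  expect_equal(P["A", "A"], w / 2)  # diagonal kept for the NG null

  # complete 3-node network with equal weights c: uniform P_ij = c off-diagonal
  cw <- 1.7
  W <- matrix(cw, 3, 3); diag(W) <- 0
  n3 <- kinase_network(c("A", "B", "C"), W)
  Pu <- null_matrix(n3, null_model("uniform"))
  expect_equal(Pu[upper.tri(Pu)], rep(cw, 3))
  expect_equal(diag(Pu), rep(0, 3), ignore_attr = TRUE)

  # linear in the resolution parameter
  net <- random_network(6, seed = 4)
  for (kind in c("uniform", "newman-girvan")) {
    expect_equal(null_matrix(net, null_model(kind, resolution = 2)),
                 2 * null_matrix(net, null_model(kind, resolution = 1)))
  }
  expect_error(null_model("uniform", resolution = 0),
               class = "kc_validation_error")
})

test_that("modularity matches direct term-by-term evaluation of the sum", {
  # frozen hand-computed case: edges K1-K2: 3, K3-K4: 3, K2-K3: 1;
  # partition {K1,K2} {K3,K4}; NG gamma = 1 gives Q = 5
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 3; W[3, 4] <- W[4, 3] <- 3; W[2, 3] <- W[3, 2] <- 1
  n4 <- kinase_network(paste0("K", 1:4), W)
  p <- setNames(c(1, 1, 2, 2), n4$nodes)
  expect_equal(modularity_score(n4, p, null_model("newman-girvan")), 5)
  expect_equal(oracle_modularity(W, c(1, 1, 2, 2), "newman-girvan"), 5)

  # random instances against the oracle, both nulls, gamma 1 and 1.4
  for (seed in 1:6) {
    net <- random_network(7, seed = seed)
    set.seed(seed + 100)
    comm <- sample(1:3, 7, replace = TRUE)
    p <- setNames(comm, net$nodes)
    for (kind in c("uniform", "newman-girvan")) {
      for (g in c(1, 1.4)) {
        expect_equal(modularity_score(net, p, null_model(kind, g)),
                     oracle_modularity(net$weights, comm, kind, g))
      }
    }
  }

  expect_error(
    modularity_score(random_network(5, 1), setNames(1:4, sprintf("N%02d", 1:4))),
    class = "kc_coverage_error")
})

test_that("closed forms: one-community NG and constant-complete uniform are zero", {
  for (seed in 1:8) {
    net <- random_network(sample(4:9, 1), seed = seed)
    one <- setNames(rep(1, length(net$nodes)), net$nodes)
    expect_equal(modularity_score(net, one, null_model("newman-girvan")), 0,
                 tolerance = 1e-12)
  }
  cw <- 0.8
  W <- matrix(cw, 6, 6); diag(W) <- 0
  net <- kinase_network(paste0("K", 1:6), W)
  set.seed(42)
  for (r in 1:5) {
    p <- setNames(sample(1:3, 6, replace = TRUE), net$nodes)
    expect_equal(modularity_score(net, p, null_model("uniform")), 0,
                 tolerance = 1e-12)
  }
})

test_that("modularity is invariant under relabeling and node permutation", {
  net <- random_network(8, seed = 21)
  set.seed(22)
  comm <- sample(1:3, 8, replace = TRUE)
  p1 <- setNames(comm, net$nodes)
  p2 <- setNames(c("x", "y", "z")[comm], net$nodes)  # relabeled
  perm <- sample(8)
  net_perm <- kinase_network(net$nodes[perm],
                             net$weights[perm, perm, drop = FALSE])
  for (kind in c("uniform", "newman-girvan")) {
    nl <- null_model(kind)
    q <- modularity_score(net, p1, nl)
    expect_equal(modularity_score(net, p2, nl), q)
    expect_equal(modularity_score(net_perm, p1, nl), q)
  }
})

test_that("Louvain recovers planted two-clique structure at the brute-force optimum", {
  net <- two_clique_network()
  truth <- setNames(rep(1:2, each = 4), net$nodes)
  for (kind in c("uniform", "newman-girvan")) {
    nl <- null_model(kind)
    lp <- louvain_partition(net, nl, seed = 3)
    bp <- brute_force_partition(net, nl)
    expect_equal(compare_partitions(lp, truth)$ari, 1)
    expect_equal(compare_partitions(bp, truth)$ari, 1)
    expect_equal(modularity_score(net, lp, nl), modularity_score(net, bp, nl))
  }
})

test_that("two disconnected equal-weight edges each form their own community", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  net <- kinase_network(c("A", "B", "C", "D"), W)
  truth <- setNames(c(1, 1, 2, 2), net$nodes)
  nl <- null_model("newman-girvan")
  expect_equal(compare_partitions(louvain_partition(net, nl, seed = 9),
                                  truth)$ari, 1)
  expect_equal(compare_partitions(brute_force_partition(net, nl), truth)$ari, 1)
})

test_that("Louvain never scores below the singleton partition and is seed-reproducible", {
  for (seed in 1:10) {
    net <- random_network(sample(5:9, 1), seed = seed)
    for (kind in c("uniform", "newman-girvan")) {
      nl <- null_model(kind)
      lp <- louvain_partition(net, nl, seed = seed * 7)
      singles <- setNames(seq_along(net$nodes), net$nodes)
      expect_gte(modularity_score(net, lp, nl),
                 modularity_score(net, singles, nl) - 1e-12)
      expect_identical(lp, louvain_partition(net, nl, seed = seed * 7))
    }
  }
})

test_that("brute force breaks ties towards fewer communities and refuses large n", {
  # single-edge 2-node network under the uniform null: both partitions
  # score 0, so the tie-break returns one community
  n2 <- kinase_network(c("A", "B"), matrix(c(0, 1, 1, 0), 2))
  bp <- brute_force_partition(n2, null_model("uniform"))
  expect_equal(length(unique(bp)), 1L)

  expect_error(brute_force_partition(random_network(13, 1), null_model()),
               class = "kc_size_error")
})

test_that("aggregating the modularity matrix preserves the partition's modularity", {
  for (kind in c("uniform", "newman-girvan")) {
    net <- random_network(9, seed = 33)
    nl <- null_model(kind)
    B <- modularity_matrix(net, nl)
    set.seed(34)
    comm <- sample(1:3, 9, replace = TRUE)
    M <- matrix(0, 9, max(comm)); M[cbind(1:9, comm)] <- 1
    B_agg <- t(M) %*% B %*% M
    # flat modularity equals the all-in-one-supernode-community score of
    # the aggregated matrix restricted to the diagonal blocks
    expect_equal(sum(diag(B_agg)),
                 modularity_score(net, setNames(comm, net$nodes), nl))
  }
})
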