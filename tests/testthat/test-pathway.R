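# Community selection, community strength, intersections, the anchor-edge
# filter and candidate ranking.

# 6-node fixture: community {P, Q, X, Y}, outsiders {O1, O2}.
pathway_fixture <- function() {
  nodes <- c("O1", "O2", "P", "Q", "X", "Y")
  W <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  add <- function(a, b, w) W[a, b] <<- W[b, a] <<- w
  add("P", "Q", 2)
  add("X", "P", 1.5); add("X", "Q", 2.0)
  add("Y", "P", 0.7)
  add("X", "O1", 5.0)   # heavy edge leaving the community
  add("O1", "O2", 1.0)
  list(network = kinase_network(nodes, W),
       partition = setNames(c(2, 2, 1, 1, 1, 1), nodes),
       community = c("P", "Q", "X", "Y"))
}

test_that("select_community returns the target's community and flags unknown targets", {
  fx <- pathway_fixture()
  expect_equal(select_community(fx$partition, "P"), c("P", "Q", "X", "Y"))
  expect_equal(select_community(fx$partition, "O2"), c("O1", "O2"))
  err <- expect_error(select_community(fx$partition, "AKT1"),
                      class = "kc_lookup_error")
  expect_match(conditionMessage(err), "alias")
})

test_that("community strength sums within-community edges only", {
  fx <- pathway_fixture()
  # X: edges to P (1.5) and Q (2.0) count; the 5.0 edge to O1 does not
  expect_equal(community_strength(fx$network, fx$community, "X"), 3.5)
  expect_equal(community_strength(fx$network, "Y", "Y"), 0)  # singleton
  expect_error(community_strength(fx$network, fx$community, "O1"),
               class = "kc_argument_error")

  # locality: changing an outside-community edge leaves CS unchanged
  W2 <- fx$network$weights
  W2["X", "O1"] <- W2["O1", "X"] <- 0.01
  net2 <- kinase_network(fx$network$nodes, W2)
  expect_equal(community_strength(net2, fx$community, "X"), 3.5)
})

test_that("community strengths sum to twice the intra-community weight", {
  for (seed in 1:5) {
    net <- random_network(10, seed = seed)
    p <- louvain_partition(net, null_model("newman-girvan"), seed = seed)
    for (comm in partition_communities(p)) {
      cs <- vapply(comm, function(m) community_strength(net, comm, m),
                   numeric(1))
      intra <- sum(net$weights[comm, comm]) / 2
      expect_equal(sum(cs), 2 * intra)
    }
  }
})

test_that("community reports rank members by decreasing |CS| with min-ties", {
  fx <- pathway_fixture()
  rep <- community_report(fx$network, fx$partition, "P")
  expect_equal(rep$members, c("P", "Q", "X", "Y"))
  expect_equal(unname(rep$strength[c("P", "Q", "X", "Y")]),
               c(2 + 1.5 + 0.7, 2 + 2, 3.5, 0.7))
  expect_equal(rep$strength_rank[["P"]], 1L)  # CS 4.2 beats Q's 4.0
  expect_equal(rep$strength_rank[["Q"]], 2L)
  expect_equal(rep$strength_rank[["Y"]], 4L)
})

test_that("intersection reports are disjoint, exhaustive and symmetric", {
  ir <- intersect_communities(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(ir$shared, c("B", "C"))
  expect_equal(ir$only_first, "A")
  expect_equal(ir$only_second, "D")
  swapped <- intersect_communities(c("B", "C", "D"), c("A", "B", "C"))
  expect_equal(swapped$shared, ir$shared)
  expect_equal(swapped$only_first, ir$only_second)

  same <- intersect_communities(c("A", "B"), c("B", "A"))
  expect_equal(same$shared, c("A", "B"))
  expect_length(same$only_first, 0)
  expect_length(same$only_second, 0)
})

test_that("the anchor filter requires a direct edge to every anchor", {
  fx <- pathway_fixture()
  # X touches both P and Q; Y touches only P
  expect_equal(anchor_filter(fx$network, fx$community, c("P", "Q")), "X")
  expect_equal(anchor_filter(fx$network, fx$community, "P"), c("Q", "X", "Y"))
  # adding anchors can only shrink the survivor set
  s1 <- anchor_filter(fx$network, fx$community, "P")
  s2 <- anchor_filter(fx$network, fx$community, c("P", "Q"))
  expect_true(all(s2 %in% s1))
  # no member touches an anchor outside the community's reach
  expect_equal(anchor_filter(fx$network, c("P", "Q"), c("P", "Q", "O2")),
               character(0))
  expect_error(anchor_filter(fx$network, fx$community, "MISSING"),
               class = "kc_lookup_error")
})

test_that("candidate ranking orders by best rank, then mean CS, then name", {
  fx <- pathway_fixture()
  repA <- community_report(fx$network, fx$partition, "P")
  # second report over the same members but different weights
  W <- fx$network$weights
  W["X", "P"] <- W["P", "X"] <- 0.1   # demote X in network B
  W["Y", "P"] <- W["P", "Y"] <- 3.0   # promote Y
  netB <- kinase_network(fx$network$nodes, W)
  repB <- community_report(netB, fx$partition, "P")

  tab <- rank_candidates(list(repA, repB), c("X", "Y"))
  expect_equal(tab$candidate, c("X", "Y"))  # X best rank in A, Y best in B
  expect_equal(tab$min_rank, c(min(repA$strength_rank[["X"]],
                                   repB$strength_rank[["X"]]),
                               min(repA$strength_rank[["Y"]],
                                   repB$strength_rank[["Y"]])))

  # exact ties everywhere fall back to the name: U and V are symmetric
  nodes <- c("P", "U", "V")
  Wt <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  Wt["P", "U"] <- Wt["U", "P"] <- 1
  Wt["P", "V"] <- Wt["V", "P"] <- 1
  tie_rep <- community_report(kinase_network(nodes, Wt),
                              setNames(c(1, 1, 1), nodes), "P")
  tie <- rank_candidates(list(tie_rep), c("V", "U"))
  expect_equal(tie$candidate, c("U", "V"))
  expect_equal(tie$min_rank, c(2L, 2L))
  expect_error(rank_candidates(list(repA), "O1"), class = "kc_coverage_error")

  single <- rank_candidates(list(repA), "X")
  expect_equal(nrow(single), 1L)
})

test_that("the pipeline is deterministic, validated, and closed over generated kinases", {
  gen <- generate_planted_zscores(strong_spec(seed = 17))
  config <- list(treatments = c(synthetic = gen$truth$target),
                 sign = "negative", null = "uniform", ensemble = 30,
                 seed = 5, anchors = gen$truth$anchors)
  rep1 <- run_pipeline(gen$table, config)
  rep2 <- run_pipeline(gen$table, config)
  expect_identical(write_report(rep1), write_report(rep2))

  # every kinase the report names was generated
  all_names <- unique(c(names(rep1$treatments[[1]]$partition),
                        rep1$treatments[[1]]$community$members,
                        rep1$anchor_survivors))
  expect_true(all(all_names %in% kinases(gen$table)))

  # survivors live in the planted pathway community at strong separation
  planted <- names(gen$truth$partition)[
    gen$truth$partition == gen$truth$pathway_community]
  expect_true(all(rep1$anchor_survivors %in% planted))

  expect_error(run_pipeline(gen$table, list(treatments = c(synthetic = ""))),
               class = "kc_config_error")
  expect_error(run_pipeline(gen$table, list(sign = "negative")),
               class = "kc_config_error")
  expect_error(run_pipeline(gen$table,
                            list(treatments = c(nope = "KIN001"))),
               class = "kc_config_error")
})

test_that("pipeline config round-trips through YAML", {
  gen <- generate_planted_zscores(strong_spec(seed = 23))
  cfg <- list(treatments = list(synthetic = gen$truth$target),
              sign = "negative", null = "uniform", ensemble = 20, seed = 3,
              anchors = as.list(gen$truth$anchors))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  rep_yaml <- run_pipeline(gen$table, path)
  rep_list <- run_pipeline(gen$table, cfg)
  expect_identical(write_report(rep_yaml), write_report(rep_list))
})
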