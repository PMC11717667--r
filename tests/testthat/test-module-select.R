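test_that("structure entropy matches direct evaluation of the formula", {
  k3 <- interaction_network(clique_edges(c("a", "b", "c")))
  expect_equal(structure_entropy(k3), log(3), tolerance = 1e-12)

  p3 <- path_net(c("a", "b", "c"))  # importances 0.25, 0.5, 0.25
  expect_equal(structure_entropy(p3),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-12)

  s4 <- interaction_network(edge_df(rep("h", 4), paste0("l", 1:4)))
  expect_equal(structure_entropy(s4),
               -(0.5 * log(0.5) + 4 * 0.125 * log(0.125)), tolerance = 1e-12)

  empty <- interaction_network(edge_df(character(0), character(0)),
                               nodes = c("a", "b"))
  expect_error(structure_entropy(empty), "undefined")
})

test_that("entropy is relabelling- and weight-scale-invariant, maximal for regular graphs", {
  net <- random_net(30, p = 0.2, seed = 5)
  e0 <- structure_entropy(net)
  # relabel nodes
  perm <- net
  igraph::V(perm)$name <- sample(paste0("x", 1:30))
  expect_equal(structure_entropy(perm), e0, tolerance = 1e-12)
  # uniform weight scaling
  scaled <- net
  igraph::E(scaled)$weight <- igraph::E(scaled)$weight * 7.5
  expect_equal(structure_entropy(scaled), e0, tolerance = 1e-12)
  # regular graph attains ln N; a star stays strictly below ln N
  ring <- interaction_network(edge_df(paste0("r", 1:10),
                                      paste0("r", c(2:10, 1))))
  expect_equal(structure_entropy(ring), log(10), tolerance = 1e-12)
  star <- interaction_network(edge_df(rep("h", 9), paste0("l", 1:9)))
  expect_lt(structure_entropy(star), log(10))
})

test_that("partition entropy variants evaluate the documented subgraphs", {
  two_k3 <- interaction_network(rbind(clique_edges(c("a", "b", "c")),
                                      clique_edges(c("x", "y", "z"))))
  ms <- module_set("greedy", list(c("a", "b", "c"), c("x", "y", "z")),
                   character(0))
  expect_equal(partition_entropy(two_k3, ms, "module_union")$entropy,
               log(6), tolerance = 1e-12)
  expect_equal(partition_entropy(two_k3, ms, "per_module_mean")$entropy,
               log(3), tolerance = 1e-12)
  # single module spanning the network: module_union == global entropy
  net <- random_net(25, p = 0.2, seed = 9)
  whole <- module_set("greedy", list(sort(igraph::V(net)$name)), character(0))
  expect_equal(partition_entropy(net, whole, "module_union")$entropy,
               structure_entropy(net), tolerance = 1e-12)
  expect_error(partition_entropy(net, module_set("mcl", list(), character(0))),
               "zero modules")
})

test_that("minimum-entropy selection picks MCODE on each disease entropy triple", {
  triples <- list(
    c(mcode = 3.288, mcl = 4.217, greedy = 4.205),
    c(mcode = 3.821, mcl = 4.272, greedy = 4.377),
    c(mcode = 3.184, mcl = 3.800, greedy = 3.859),
    c(mcode = 3.417, mcl = 3.868, greedy = 4.018)
  )
  for (tr in triples) expect_equal(select_method(tr), "mcode")
  expect_warning(win <- select_method(c(mcl = 1.0, greedy = 1.0)), "tie")
  expect_equal(win, "mcl")
})

test_that("main module follows metric consistency, with path-length tie-break", {
  # hub module dominates every metric: consistent branch
  net <- bridge_cliques_net()
  ms <- module_set("mcode", list(paste0("p", 1:5), paste0("q", 1:4)),
                   character(0))
  rep1 <- main_module(net, ms)
  expect_true(rep1$consistent)
  expect_equal(rep1$main_module_id, 1L)
  # strength aggregate equals 2*within + boundary edges (unweighted)
  expect_equal(unname(rep1$metrics[1, "strength"]), 2 * 10 + 1)
  expect_equal(unname(rep1$metrics[2, "strength"]), 2 * 6 + 1)

  # single-module set: trivially consistent
  one <- main_module(net, module_set("mcl", list(paste0("p", 1:5)),
                                     paste0("q", 1:4)))
  expect_true(one$consistent)
  expect_equal(one$main_module_id, 1L)

  # metrics made to disagree via edge weights (heavy K3 wins on strength,
  # the K6 + chain side on betweenness): tie-break removes each candidate
  # and compares characteristic path-length disturbance against a
  # BFS-oracle recomputation
  k6 <- clique_edges(paste0("p", 1:6)); k6$weight <- 1
  ew <- rbind(k6,
              edge_df(c("p6", "m1", "m2"), c("m1", "m2", "q1"), c(1, 1, 1)),
              edge_df(c("q1", "q1", "q2"), c("q2", "q3", "q3"),
                      c(50, 50, 50)))
  netw <- interaction_network(ew)
  mod1 <- c(paste0("p", 1:6), "m1", "m2")
  mod2 <- paste0("q", 1:3)
  msw <- module_set("mcode", list(mod1, mod2), character(0))
  repw <- main_module(netw, msw)
  expect_false(repw$consistent)
  d <- bfs_dist_oracle(netw)
  cpl <- function(nodes) {
    m <- d[nodes, nodes, drop = FALSE]
    v <- m[upper.tri(m)]
    mean(v[is.finite(v) & v > 0])
  }
  L0 <- cpl(c(mod1, mod2))
  dist1 <- abs(L0 - cpl(mod2))
  dist2 <- abs(L0 - cpl(mod1))
  expect_equal(repw$main_module_id, which.max(c(dist1, dist2)))
  expect_equal(repw$tie_break[1], dist1, tolerance = 1e-12)
  expect_true(all(repw$metrics >= 0))
})
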