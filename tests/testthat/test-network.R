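test_that("model_to_network draws reactant/modifier -> product edges", {
  m <- reaction_model(
    one_comp(),
    list(species_state("A", "A", "c", 10),
         species_state("B", "B", "c", 10),
         species_state("C", "C", "c", 0)),
    list(reaction("r1", "A+B->C", c(A = 1, B = 1), c(C = 1),
                  rate = rate_law("mass_action", k = 1e-3))),
    name = "pair")
  net <- model_to_network(m)
  e <- network_edges(net)
  expect_identical(nrow(e), 2L)
  expect_setequal(paste(e$source, e$target), c("A C", "B C"))
  expect_identical(length(net$nodes), 3L)
})

test_that("simple graphs have textbook topology summaries", {
  path <- network_from_edges(rbind(c("A", "B"), c("B", "C")))
  ts <- topology_summary(path)
  expect_identical(ts$diameter, 2)
  expect_identical(ts$radius, 1)
  tri <- network_from_edges(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_equal(topology_summary(tri)$avg_clustering, 1)
  expect_error(topology_summary(network_from_edges(
    matrix(character(), 0, 2))), "empty")
})

test_that("star and clique centralities take their closed-form values", {
  star <- network_from_edges(cbind("hub", paste0("leaf", 1:4)))
  expect_equal(centrality(star, "degree")[["hub"]], 4)
  expect_equal(centrality(star, "betweenness")[["hub"]], 6)  # C(4,2) pairs
  expect_equal(centrality(star, "stress")[["hub"]], 6)
  k5 <- random_graph(5, 1, seed = 1)
  expect_equal(unname(centrality(k5, "betweenness")), rep(0, 5))
  expect_equal(unname(centrality(k5, "stress")), rep(0, 5))
  expect_equal(unname(centrality(k5, "closeness")), rep(4, 5))
  expect_equal(unname(centrality(k5, "mcc")), rep(factorial(4), 5))
  tri <- network_from_edges(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_equal(unname(centrality(tri, "mcc")), rep(2, 3))  # (3-1)!
})

test_that("EPC is reproducible, seeded, and trivial at keep probability 1", {
  g <- random_graph(12, 0.3, seed = 5)
  expect_error(centrality(g, "epc"), "seed")
  e1 <- centrality(g, "epc", n_realizations = 50, seed = 9)
  e2 <- centrality(g, "epc", n_realizations = 50, seed = 9)
  expect_identical(e1, e2)
  comp <- igraph::components(g$ugraph)
  full <- centrality(g, "epc", n_realizations = 3, keep_probability = 1,
                     seed = 1)
  expect_equal(unname(full), comp$csize[comp$membership])
})

test_that("path-count and clique metrics equal brute-force oracles", {
  for (seed in 1:30) {
    g <- random_graph(10, 0.3, seed = seed)
    bs <- oracle_betweenness_stress(g)
    expect_equal(centrality(g, "betweenness"), bs$betweenness,
                 tolerance = 1e-12)
    expect_equal(centrality(g, "stress"), bs$stress)
    expect_equal(centrality(g, "mcc"), oracle_mcc(g))
    md <- oracle_mnc_dmnc(g)
    expect_equal(centrality(g, "mnc"), md$mnc)
    expect_equal(centrality(g, "dmnc"), md$dmnc, tolerance = 1e-12)
  }
})

test_that("centralities are equivariant under node relabeling", {
  g <- random_graph(9, 0.35, seed = 21)
  el <- igraph::as_edgelist(g$ugraph)
  perm <- stats::setNames(sprintf("z%02d", sample(9)), g$nodes)
  g2 <- network_from_edges(cbind(perm[el[, 1]], perm[el[, 2]]))
  for (metric in c("degree", "closeness", "betweenness", "stress",
                   "eccentricity", "radiality", "mnc", "dmnc", "mcc",
                   "clustering_coefficient", "bottleneck")) {
    c1 <- centrality(g, metric)
    c2 <- centrality(g2, metric)
    expect_equal(unname(c2[perm[names(c1)]]), unname(c1),
                 tolerance = 1e-12, label = metric)
  }
})

test_that("hub frequency counts top-k membership across metrics", {
  g <- random_graph(8, 0.4, seed = 2)
  ct <- centrality_table(g, epc_seed = 1, epc_realizations = 20)
  # k covering all nodes: every node appears in all 12 lists
  hub_all <- hub_frequency(ct, k = 8)
  expect_true(all(hub_all$frequency == 12L))
  hub1 <- hub_frequency(ct, k = 1)
  expect_true(all(hub1$frequency <= 12L))
  expect_true(!is.unsorted(rev(hub1$frequency)))
  expect_error(hub_frequency(ct, k = 0), "k")
  # a star center tops every metric list
  star <- network_from_edges(cbind("hub", paste0("leaf", 1:5)))
  cts <- centrality_table(star, epc_seed = 1, epc_realizations = 20)
  expect_identical(hub_frequency(cts, k = 1)$frequency[1], 12L)
  expect_identical(hub_frequency(cts, k = 1)$node[1], "hub")
})

test_that("unknown metrics are rejected", {
  g <- random_graph(5, 0.5, seed = 1)
  expect_error(centrality(g, "pagerank"), "unknown centrality")
})
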