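test_that("the generator is deterministic and hits its counts", {
  spec <- generator_spec(n_species = 20, n_reactions = 30, seed = 7)
  m1 <- random_model(spec)
  m2 <- random_model(spec)
  expect_identical(m1, m2)
  expect_identical(length(m1$species), 20L)
  expect_identical(length(m1$reactions), 30L)
  expect_identical(nrow(validate_model(m1)[
    validate_model(m1)$level == "error", ]), 0L)
  # different seed, different model
  expect_false(identical(m1, random_model(generator_spec(
    n_species = 20, n_reactions = 30, seed = 8))))
})

test_that("generated amounts sit in the signaling band and species react", {
  for (seed in c(2, 13, 99)) {
    m <- random_model(generator_spec(n_species = 12, n_reactions = 16,
                                     seed = seed))
    x0 <- vapply(m$species, `[[`, 0, "initial_amount")
    expect_true(all(x0 >= 1e3 & x0 <= 1e6))
    used <- unique(unlist(lapply(m$reactions, function(rx) {
      c(names(rx$reactants), names(rx$products), rx$modifiers)
    })))
    expect_setequal(used, species_ids(m))
    # connected reaction graph (undirected view)
    net <- model_to_network(m)
    expect_equal(igraph::components(net$ugraph)$no, 1)
  }
})

test_that("the rate-law mix is honored in expectation", {
  m <- random_model(generator_spec(n_species = 30, n_reactions = 60,
                                   rate_law_mix = c(mass_action = 1,
                                                    michaelis_menten = 0,
                                                    hill = 0),
                                   seed = 5))
  kinds <- vapply(m$reactions, function(r) r$rate$kind, "")
  expect_true(all(kinds == "mass_action"))
  expect_error(generator_spec(rate_law_mix = c(mass_action = 0.5,
                                               michaelis_menten = 0.2,
                                               hill = 0.2)),
               "sum to 1")
})

test_that("perturbation is seeded, bounded, and structure-preserving", {
  m <- random_model(generator_spec(seed = 3))
  p1 <- perturb_model(m, 0.2, seed = 11)
  p2 <- perturb_model(m, 0.2, seed = 11)
  expect_identical(p1, p2)
  expect_identical(reaction_names(p1), reaction_names(m))
  for (j in seq_along(m$reactions)) {
    r <- p1$reactions[[j]]$rate$parameters /
      m$reactions[[j]]$rate$parameters
    expect_true(all(r >= exp(-0.2) & r <= exp(0.2)))
  }
  tiny <- perturb_model(m, 1e-9, seed = 1)
  for (j in seq_along(m$reactions)) {
    expect_equal(tiny$reactions[[j]]$rate$parameters,
                 m$reactions[[j]]$rate$parameters, tolerance = 1e-6)
  }
  expect_error(perturb_model(m, 1.5, seed = 1))
})

test_that("random graphs cover the degenerate edge probabilities", {
  g0 <- random_graph(10, 0, seed = 1)
  expect_identical(igraph::ecount(g0$ugraph), 0)
  g1 <- random_graph(6, 1, seed = 1)
  expect_identical(igraph::ecount(g1$ugraph), choose(6, 2))
  ga <- random_graph(10, 0.3, seed = 42)
  gb <- random_graph(10, 0.3, seed = 42)
  expect_identical(igraph::as_edgelist(ga$ugraph),
                   igraph::as_edgelist(gb$ugraph))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(random_model(generator_spec(seed = 50)))
  invisible(random_graph(8, 0.5, seed = 51))
  after <- stats::runif(1)
  expect_identical(before, after)
})
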