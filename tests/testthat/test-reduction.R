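# synthetic landscape for arithmetic-level tests
toy_landscape <- function(n = 10) {
  data.frame(reaction = sprintf("r%02d", 1:n),
             name = sprintf("reaction %d", 1:n),
             sensitivity = seq(0.5, 2, length.out = n),
             flux = seq(1000, 100, length.out = n),
             concentration = seq(1e5, 1e3, length.out = n),
             combined_rank = seq_len(n),
             stringsAsFactors = FALSE)
}

test_that("reduction percentage follows the retained fraction", {
  m <- closed_cycle_model()
  ls <- toy_landscape(3)
  all_in <- reduce_model(m, reduction_criteria(
    sensitivity_half_width = 10, flux_min = 0,
    concentration_quantile = 0, max_retained = NULL), landscape = ls)
  expect_equal(all_in$reduction_percent, 0)
  expect_warning(
    none <- reduce_model(m, reduction_criteria(
      sensitivity_half_width = 1e-9, flux_min = 1e9,
      concentration_quantile = 1, max_retained = NULL), landscape = ls),
    "zero reactions")
  expect_equal(none$reduction_percent, 100)
})

test_that("retaining 12 of 83 reactions rounds to an 86% reduction", {
  ls <- toy_landscape(83)
  res <- reduce_model(closed_cycle_model(), reduction_criteria(
    sensitivity_half_width = 1e-9, flux_min = 1e9,
    concentration_quantile = 1, max_retained = 12), landscape = ls)
  expect_identical(length(res$retained), 12L)
  expect_equal(round(res$reduction_percent), 86)
})

test_that("reduction is monotone in max_retained", {
  ls <- toy_landscape(20)
  crit <- function(k) reduction_criteria(
    sensitivity_half_width = 1e-9, flux_min = 1e9,
    concentration_quantile = 1, max_retained = k)
  prev <- 100
  for (k in c(1, 5, 10, 20)) {
    res <- reduce_model(closed_cycle_model(), crit(k), landscape = ls)
    expect_lte(res$reduction_percent, prev)
    prev <- res$reduction_percent
  }
})

test_that("landscape has one point per reaction and a coherent apex", {
  m <- decay_model()
  tr <- simulate_model(m, t_end = 2, n_out = 5)
  sx <- local_sensitivities(m, t_end = 2, inputs = "parameters",
                            normalization = "none", n_out = 5,
                            n_sub = 200)
  A <- aggregate_sensitivities(sx)
  fx <- compute_fluxes(m, tr)
  ls <- quasi_potential_landscape(m, A, fx, tr)
  expect_identical(nrow(ls), 1L)
  # a reaction that maximizes all three axes is the combined-rank apex
  ls2 <- toy_landscape(6)
  ls2$sensitivity[3] <- 10; ls2$flux[3] <- 1e6; ls2$concentration[3] <- 1e9
  comb <- (rank(-ls2$sensitivity) + rank(-ls2$flux) +
           rank(-ls2$concentration)) / 3
  expect_identical(which.min(comb), 3L)
})

test_that("mismatched inputs are rejected", {
  m <- decay_model()
  tr <- simulate_model(m, t_end = 1, n_out = 3)
  A <- matrix(1, 2, 1, dimnames = list(c("A", "B"), "zz.k"))
  fx <- compute_fluxes(m, tr)
  expect_error(quasi_potential_landscape(m, A, fx, tr), "lacks parameter")
})

test_that("re-simulating the reduced curated model keeps retained outputs", {
  a <- curated_artifacts()
  res <- reduce_model(a$model, landscape = a$landscape)
  sub <- reduced_submodel(a$model, res)
  tr2 <- simulate_model(sub)
  full <- final_state(a$trajectory)
  reduced <- final_state(tr2)
  # the reduction is a selection tool, not a dynamics-preserving
  # projection: in isolation the retained subsystem loses its upstream
  # drives, so the documented band is three orders of magnitude, and the
  # FOXO-autophagy accumulation signature must persist
  prods <- unique(unlist(lapply(sub$reactions, function(rx) {
    setdiff(names(rx$products), union(names(rx$reactants), rx$modifiers))
  })))
  ratio <- (reduced[prods] + 1) / (full[prods] + 1)
  expect_true(all(ratio > 1e-3 & ratio < 1e3))
  top6 <- names(net_increase(tr2))[1:6]
  expect_true(all(c("foxo1_nuc", "foxo3_nuc") %in% top6))
})
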