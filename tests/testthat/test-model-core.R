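test_that("rate laws evaluate their closed forms", {
  r_ma <- reaction("r", "A+B->C", c(A = 1, B = 1), c(C = 1),
                   rate = rate_law("mass_action", k = 2))
  expect_equal(evaluate_rate(r_ma, c(A = 3, B = 4)), 24)

  r_mm <- reaction("r", "S->P", c(S = 1), c(P = 1),
                   rate = rate_law("michaelis_menten", Vmax = 10, Km = 50))
  expect_equal(evaluate_rate(r_mm, c(S = 50)), 5)  # half saturation

  # hill with n = 1 reduces to Michaelis-Menten with Km = K, pointwise
  r_h1 <- reaction("r", "S->P", c(S = 1), c(P = 1),
                   rate = rate_law("hill", Vmax = 10, K = 50, n = 1))
  for (S in c(0, 0.1, 1, 50, 500, 1e6)) {
    expect_equal(evaluate_rate(r_h1, c(S = S)),
                 evaluate_rate(r_mm, c(S = S)))
  }
})

test_that("rates are non-negative and finite over random states", {
  laws <- list(rate_law("mass_action", k = 0.3),
               rate_law("michaelis_menten", Vmax = 7, Km = 11),
               rate_law("hill", Vmax = 5, K = 9, n = 2))
  set.seed(42)
  for (law in laws) {
    rx <- reaction("r", "S->P", c(S = 1), c(P = 1), rate = law)
    for (i in 1:50) {
      v <- evaluate_rate(rx, c(S = stats::runif(1, 0, 1e6)))
      expect_true(is.finite(v) && v >= 0)
    }
  }
})

test_that("rate-law construction rejects bad input", {
  expect_error(rate_law("banana", k = 1), "unknown rate-law kind")
  expect_error(rate_law("mass_action", k = -1), "positive")
  expect_error(rate_law("michaelis_menten", Vmax = 1), "Km")
  r2 <- reaction("r", "A+B->C", c(A = 1, B = 1), c(C = 1),
                 rate = rate_law("michaelis_menten", Vmax = 1, Km = 1))
  expect_error(evaluate_rate(r2, c(A = 1, B = 1)),
               "exactly one driving species")
})

test_that("validate_model reports errors and band warnings", {
  m <- decay_model()
  expect_identical(nrow(validate_model(m)[
    validate_model(m)$level == "error", ]), 0L)
  # initial amount outside the 10^3-10^6 signaling band -> warning
  m$species[[1]]$initial_amount <- 100
  f <- validate_model(m)
  expect_true(any(f$level == "warning" & grepl("band", f$message)))
  # unresolved species id -> error
  m2 <- decay_model()
  m2$reactions[[1]]$products <- c(GHOST = 1L)
  f2 <- validate_model(m2)
  expect_identical(sum(f2$level == "error"), 1L)
  expect_match(f2$message[f2$level == "error"], "GHOST")
})

test_that("stoichiometric matrix encodes net change and clamps boundaries", {
  m <- closed_cycle_model()
  N <- stoichiometric_matrix(m)
  expect_equal(unname(colSums(N)), c(0, 0, 0))  # balanced cycle
  expect_equal(N["A", "r1"], -1)
  expect_equal(N["B", "r1"], 1)
  mb <- decay_model()
  mb$species[[1]]$boundary <- TRUE
  expect_equal(unname(stoichiometric_matrix(mb)["A", ]), 0)
})
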