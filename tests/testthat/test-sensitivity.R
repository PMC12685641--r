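test_that("decay sensitivity matches the analytic derivative", {
  # x' = -kx, x0 = 1, k = 1: dx/dk (t) = -t e^{-kt}
  m <- decay_model(k = 1, A0 = 1)
  sx <- local_sensitivities(m, t_end = 1, inputs = "parameters",
                            normalization = "none", n_out = 11,
                            n_sub = 2000)
  got <- sx$values[11, which(sx$outputs == "A"),
                   which(sx$inputs == "r1.k")]
  expect_equal(got, -exp(-1), tolerance = 1e-5)
  # initial-amount sensitivity is the fundamental solution
  sy <- local_sensitivities(m, t_end = 1, inputs = "initials",
                            normalization = "none", n_out = 11,
                            n_sub = 2000)
  expect_equal(sy$values[11, which(sy$outputs == "B"),
                         which(sy$inputs == "x0.A")],
               1 - exp(-1), tolerance = 1e-5)
})

test_that("decoupled subsystems have zero cross-sensitivity", {
  m <- decoupled_model()
  sx <- local_sensitivities(m, t_end = 3, inputs = "parameters",
                            normalization = "none", n_out = 7,
                            n_sub = 600)
  iA <- which(sx$outputs == "A")
  expect_equal(max(abs(sx$values[, iA, which(sx$inputs == "rB.k")])), 0)
  iB2 <- which(sx$outputs == "B2")
  expect_equal(max(abs(sx$values[, iB2, which(sx$inputs == "rA.k")])), 0)
})

test_that("linear-system initial sensitivities equal the matrix exponential", {
  # A -> B -> (loss to C): S wrt x0 is the fundamental matrix e^{Mt}
  m <- reaction_model(
    one_comp(),
    list(species_state("A", "A", "c", 10),
         species_state("B", "B", "c", 5),
         species_state("C", "C", "c", 0)),
    list(reaction("r1", "A->B", c(A = 1), c(B = 1),
                  rate = rate_law("mass_action", k = 0.7)),
         reaction("r2", "B->C", c(B = 1), c(C = 1),
                  rate = rate_law("mass_action", k = 0.4))),
    name = "linear")
  t1 <- 2
  sx <- local_sensitivities(m, t_end = t1, inputs = "initials",
                            normalization = "none", n_out = 3,
                            n_sub = 2000)
  M <- rbind(c(-0.7, 0, 0), c(0.7, -0.4, 0), c(0, 0.4, 0))
  expM <- Matrix::expm(Matrix::Matrix(M * t1))
  got <- sx$values[3, , ]  # outputs x inputs
  expect_equal(unname(as.matrix(got)), unname(as.matrix(expM)),
               tolerance = 1e-6)
})

test_that("forward sensitivities agree with central finite differences", {
  spec <- generator_spec(n_species = 5, n_reactions = 6, seed = 11)
  m <- random_model(spec)
  sx <- local_sensitivities(m, t_end = 5, inputs = "all",
                            normalization = "none", n_out = 3,
                            n_sub = 3000)
  set.seed(1)
  for (inp in sample(sx$inputs, 5)) {
    rel <- fd_relative_errors(m, inp, sx, t_end = 5)
    if (length(rel)) expect_lt(max(rel), 1e-4)
  }
})

test_that("full normalization dedimensionalizes and zeroes empty states", {
  m <- decay_model(k = 1, A0 = 1)
  sx <- local_sensitivities(m, t_end = 1, inputs = "parameters",
                            normalization = "full", n_out = 11,
                            n_sub = 500)
  # (k/x) dx/dk at t: for pure decay = -t * k
  iA <- which(sx$outputs == "A")
  expect_equal(sx$values[11, iA, 1], -1, tolerance = 1e-4)
  # B starts at 0: normalized entry must be exactly 0 there
  iB <- which(sx$outputs == "B")
  expect_identical(sx$values[1, iB, 1], 0)
})

test_that("aggregation collapses time as documented", {
  m <- decay_model(k = 1, A0 = 1)
  sx <- local_sensitivities(m, t_end = 1, inputs = "parameters",
                            normalization = "none", n_out = 201,
                            n_sub = 1000)
  # all-zero tensor -> all-zero matrix
  z <- sx; z$values[] <- 0
  expect_true(all(aggregate_sensitivities(z) == 0))
  # constant sensitivity c over [0,T]: integral aggregation gives c*T
  cst <- sx; cst$values[] <- 3
  expect_equal(unname(aggregate_sensitivities(
    cst, "time_integral_abs")[1, 1]), 3 * 1, tolerance = 1e-12)
  # L2 of the analytic decay sensitivity: integral of (t e^-t)^2 on [0,1]
  iA <- which(sx$outputs == "A")
  got <- aggregate_sensitivities(sx, "L2_over_time")[iA, "r1.k"]
  want <- sqrt(stats::integrate(function(t) (t * exp(-t))^2, 0, 1,
                                rel.tol = 1e-10)$value)
  expect_equal(unname(got), want, tolerance = 1e-4)
  # final-time aggregation is |S(T)|
  expect_equal(unname(aggregate_sensitivities(sx, "final_time")[iA, 1]),
               exp(-1), tolerance = 1e-4)
  expect_error(aggregate_sensitivities(
    structure(list(time = numeric(), inputs = character()),
              class = "sensitivity_tensor")), "empty")
})
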