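# Stiff deterministic time-course integration of a reaction model:
# dx/dt = N v(x), with N the stoichiometric matrix (boundary rows zeroed)
# and v the vector of reaction rates.

# rate vector at a state, same order as model$reactions
.rate_vector <- function(model, state) {
  vapply(model$reactions, evaluate_rate, 0, state = state)
}

#' Simulate a reaction model
#'
#' Integrates the reaction ODEs with an implicit multistep stiff solver
#' (backward differentiation formulas, the NDF/ODE15s family). Boundary
#' species are held constant. Tiny negative undershoots within the
#' absolute tolerance are clipped to zero after integration; larger
#' negativity raises an error.
#'
#' @param model A `reaction_model`.
#' @param t_end Simulation horizon in seconds (default: the model's
#'   declared horizon, 100 s for the curated model).
#' @param rel_tol,abs_tol Solver tolerances.
#' @param n_out Number of evenly spaced output times (including 0).
#' @return A `trajectory`: list with `time` (length `n_out`), `states`
#'   (matrix time x species), and `solver_report`.
#' @examples
#' m <- build_nsclc_model()
#' tr <- simulate_model(m, t_end = 1)
#' @export
simulate_model <- function(model, t_end = model$metadata$t_end,
                           rel_tol = 1e-6, abs_tol = 1e-9, n_out = 201) {
  assert_valid(model)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  x0 <- initial_state(model)
  N <- stoichiometric_matrix(model)
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, x, parms) {
    v <- .rate_vector(model, pmax(x, 0))
    if (any(!is.finite(v))) {
      bad <- reaction_ids(model)[!is.finite(v)][1]
      stop(sprintf("non-finite rate in reaction '%s' at t=%.4g", bad, t),
           call. = FALSE)
    }
    list(as.vector(N %*% v))
  }
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "bdf", rtol = rel_tol, atol = abs_tol)
  istate <- attr(sol, "istate")
  if (istate[1] < 0) {
    stop(sprintf("stiff integration failed near t=%.4g (istate=%d)",
                 sol[nrow(sol), "time"], istate[1]), call. = FALSE)
  }
  states <- unclass(sol)[, -1, drop = FALSE]
  low <- min(states)
  if (low < -abs_tol * 10) {
    stop(sprintf("state fell below tolerance: min=%.3g", low),
         call. = FALSE)
  }
  states[states < 0] <- 0
  structure(list(
    time = as.numeric(sol[, "time"]),
    states = states,
    solver_report = list(method = "bdf", rel_tol = rel_tol,
                         abs_tol = abs_tol, n_steps = istate[2],
                         n_evals = istate[3], success = TRUE)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over [0, %g] s, %d species\n",
              length(x$time), max(x$time), ncol(x$states)))
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param trajectory A successful `trajectory`.
#' @return Named numeric vector of species amounts at the last output time.
#' @export
final_state <- function(trajectory) {
  if (!isTRUE(trajectory$solver_report$success)) {
    stop("trajectory did not complete successfully", call. = FALSE)
  }
  trajectory$states[nrow(trajectory$states), ]
}

#' Net change of every species over a trajectory
#'
#' @param trajectory A `trajectory`.
#' @return Named numeric vector, `x(t_end) - x(0)`, sorted decreasing.
#' @export
net_increase <- function(trajectory) {
  d <- final_state(trajectory) - trajectory$states[1, ]
  sort(d, decreasing = TRUE)
}

#' Export a trajectory as a data frame
#'
#' @param trajectory A `trajectory`.
#' @param long If `TRUE` (default), tidy format (time, species, amount);
#'   otherwise wide (time x species).
#' @return A data frame.
#' @export
trajectory_frame <- function(trajectory, long = TRUE) {
  wide <- data.frame(time = trajectory$time, trajectory$states,
                     check.names = FALSE)
  if (!long) return(wide)
  sp <- colnames(trajectory$states)
  data.frame(
    time = rep(trajectory$time, times = length(sp)),
    species = rep(sp, each = length(trajectory$time)),
    amount = as.vector(trajectory$states),
    stringsAsFactors = FALSE)
}
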