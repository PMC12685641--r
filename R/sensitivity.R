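# Time-dependent local sensitivities dx_i(t)/dp_j of every species with
# respect to rate parameters and initial amounts, computed by
# co-integrating the forward (variational) equations
#   dS/dt = Jx(t) S + Jp(t),  S(0) = dx0/dp,
# with analytic Jacobians of the three rate-law families. States come from
# the stiff BDF solver on a fine grid; the linear time-varying sensitivity
# system is then advanced with the A-stable implicit trapezoid rule, one
# dense LU per step shared across every input column.

# enumerate parameter inputs as "<reaction id>.<parameter name>"
.param_table <- function(model) {
  rows <- lapply(model$reactions, function(rx) {
    data.frame(input = paste(rx$id, names(rx$rate$parameters), sep = "."),
               reaction = rx$id, parameter = names(rx$rate$parameters),
               value = unname(rx$rate$parameters),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-reaction evaluation context for fast rate/derivative assembly
.sens_context <- function(model) {
  ids <- species_ids(model)
  idx <- stats::setNames(seq_along(ids), ids)
  rx_info <- lapply(model$reactions, function(rx) {
    ri <- idx[names(rx$reactants)]
    info <- list(kind = rx$rate$kind, p = rx$rate$parameters,
                 r_idx = unname(ri), r_st = unname(rx$reactants))
    if (rx$rate$kind %in% c("michaelis_menten", "hill")) {
      info$d_idx <- unname(idx[driving_species(rx)])
    }
    info
  })
  pt <- .param_table(model)
  list(ids = ids, idx = idx, rx = rx_info, params = pt,
       N = stoichiometric_matrix(model),
       n_sp = length(ids), n_rx = length(model$reactions))
}

# rates v (n_rx), state Jacobian dv/dx (n_rx x n_sp) and parameter
# Jacobian dv/dp (n_rx x n_par) at one state
.rate_jacobians <- function(ctx, x) {
  n_rx <- ctx$n_rx
  v <- numeric(n_rx)
  dvdx <- matrix(0, n_rx, ctx$n_sp)
  dvdp <- matrix(0, n_rx, nrow(ctx$params))
  poff <- 0L
  for (j in seq_len(n_rx)) {
    info <- ctx$rx[[j]]
    p <- info$p
    np <- length(p)
    if (info$kind == "mass_action") {
      xs <- x[info$r_idx]
      terms <- xs ^ info$r_st
      prod_all <- prod(terms)
      v[j] <- p[["k"]] * prod_all
      for (m in seq_along(info$r_idx)) {
        rest <- prod(terms[-m])
        dvdx[j, info$r_idx[m]] <- dvdx[j, info$r_idx[m]] +
          p[["k"]] * info$r_st[m] * xs[m] ^ (info$r_st[m] - 1) * rest
      }
      dvdp[j, poff + 1L] <- prod_all
    } else if (info$kind == "michaelis_menten") {
      S <- x[info$d_idx]
      den <- p[["Km"]] + S
      v[j] <- p[["Vmax"]] * S / den
      dvdx[j, info$d_idx] <- p[["Vmax"]] * p[["Km"]] / den^2
      dvdp[j, poff + 1L] <- S / den                     # Vmax
      dvdp[j, poff + 2L] <- -p[["Vmax"]] * S / den^2    # Km
    } else {
      D <- x[info$d_idx]
      n <- p[["n"]]; K <- p[["K"]]
      Dn <- D^n; Kn <- K^n
      den <- Kn + Dn
      v[j] <- p[["Vmax"]] * Dn / den
      dvdx[j, info$d_idx] <- if (D > 0) {
        p[["Vmax"]] * n * Kn * D^(n - 1) / den^2
      } else if (n == 1) p[["Vmax"]] / K else 0
      dvdp[j, poff + 1L] <- Dn / den                            # Vmax
      dvdp[j, poff + 2L] <- -p[["Vmax"]] * Dn * n * K^(n - 1) / den^2  # K
      dvdp[j, poff + 3L] <- if (D > 0) {                        # n
        p[["Vmax"]] * Kn * Dn * (log(D) - log(K)) / den^2
      } else 0
    }
    poff <- poff + np
  }
  list(v = v, dvdx = dvdx, dvdp = dvdp)
}

#' Forward local sensitivities
#'
#' Computes the time-dependent derivatives of every species with respect
#' to every rate parameter and/or initial amount by integrating the
#' forward sensitivity (variational) equations alongside the state
#' trajectory. With `normalization = "full"` entries are dedimensionalized
#' to `(p_j / x_i(t)) * dx_i/dp_j`, set to 0 where `x_i(t) = 0`; `"none"`
#' returns raw derivatives.
#'
#' @param model A `reaction_model`.
#' @param t_end Horizon in seconds.
#' @param inputs `"all"` (parameters and initial amounts), `"parameters"`,
#'   or `"initials"`.
#' @param normalization `"full"` (default) or `"none"`.
#' @param n_out Output time points.
#' @param n_sub Internal integration substeps for the trapezoid march
#'   (accuracy is O(h^2) in `h = t_end/n_sub`).
#' @return A `sensitivity_tensor`: list with `time`, `outputs` (species
#'   ids), `inputs` (input ids: `"<reaction>.<parameter>"` or
#'   `"x0.<species>"`), `values` (array time x output x input), and
#'   `normalization`.
#' @export
local_sensitivities <- function(model, t_end = model$metadata$t_end,
                                inputs = c("all", "parameters", "initials"),
                                normalization = c("full", "none"),
                                n_out = 101, n_sub = 2000) {
  inputs <- match.arg(inputs)
  normalization <- match.arg(normalization)
  assert_valid(model)
  ctx <- .sens_context(model)
  n_sp <- ctx$n_sp
  n_par <- nrow(ctx$params)

  want_par <- inputs %in% c("all", "parameters")
  want_ini <- inputs %in% c("all", "initials")
  input_ids <- c(if (want_par) ctx$params$input,
                 if (want_ini) paste0("x0.", ctx$ids))
  n_in <- length(input_ids)

  # states on the fine grid (BDF), then trapezoid march for S
  fine <- simulate_model(model, t_end = t_end, n_out = n_sub + 1)
  X <- fine$states
  h <- t_end / n_sub

  S <- matrix(0, n_sp, n_in)
  if (want_ini) {
    off <- if (want_par) n_par else 0L
    S[cbind(seq_len(n_sp), off + seq_len(n_sp))] <- 1
  }

  keep <- unique(round(seq(1, n_sub + 1, length.out = n_out)))
  out_vals <- array(0, dim = c(length(keep), n_sp, n_in))
  out_time <- fine$time[keep]
  ko <- 1L
  if (keep[1] == 1L) { out_vals[1, , ] <- S; ko <- 2L }

  jac <- .rate_jacobians(ctx, X[1, ])
  A_prev <- ctx$N %*% jac$dvdx
  B_prev <- if (want_par) ctx$N %*% jac$dvdp else NULL
  I <- diag(n_sp)
  for (k in seq_len(n_sub)) {
    jac <- .rate_jacobians(ctx, X[k + 1, ])
    A_next <- ctx$N %*% jac$dvdx
    B_next <- if (want_par) ctx$N %*% jac$dvdp else NULL
    rhs <- S + (h / 2) * (A_prev %*% S)
    if (want_par) {
      rhs[, seq_len(n_par)] <- rhs[, seq_len(n_par)] +
        (h / 2) * (B_prev + B_next)
    }
    S <- solve(I - (h / 2) * A_next, rhs)
    if (any(!is.finite(S))) {
      stop(sprintf("sensitivity integration produced non-finite values at t=%.4g",
                   fine$time[k + 1]), call. = FALSE)
    }
    A_prev <- A_next
    B_prev <- B_next
    if (ko <= length(keep) && keep[ko] == k + 1L) {
      out_vals[ko, , ] <- S
      ko <- ko + 1L
    }
  }

  if (normalization == "full") {
    pvals <- c(if (want_par) ctx$params$value,
               if (want_ini) unname(initial_state(model)))
    Xk <- X[keep, , drop = FALSE]
    for (j in seq_len(n_in)) {
      scaled <- out_vals[, , j] * pvals[j] / Xk
      scaled[Xk == 0] <- 0
      out_vals[, , j] <- scaled
    }
  }
  structure(list(time = out_time, outputs = ctx$ids, inputs = input_ids,
                 values = out_vals, normalization = normalization),
            class = "sensitivity_tensor")
}

#' @export
print.sensitivity_tensor <- function(x, ...) {
  cat(sprintf("<sensitivity_tensor> %d times x %d outputs x %d inputs (%s)\n",
              length(x$time), length(x$outputs), length(x$inputs),
              x$normalization))
  invisible(x)
}

#' Aggregate a sensitivity tensor into the PCA score matrix
#'
#' Collapses the time axis of `|S(t, i, j)|` into the m x n score matrix A
#' consumed by the principal-component ranking: `"L2_over_time"` (default)
#' is the root integral of squared sensitivity over the horizon,
#' `"time_integral_abs"` the integral of the absolute value, and
#' `"final_time"` the absolute value at the last time point. Integrals use
#' the trapezoid rule on the tensor's time grid.
#'
#' @param tensor A `sensitivity_tensor`.
#' @param aggregation Aggregation mode.
#' @return A `score_matrix`: matrix (outputs x inputs) with attribute
#'   `aggregation`.
#' @export
aggregate_sensitivities <- function(tensor,
                                    aggregation = c("L2_over_time",
                                                    "time_integral_abs",
                                                    "final_time")) {
  aggregation <- match.arg(aggregation)
  if (length(tensor$time) == 0 || length(tensor$inputs) == 0) {
    stop("empty sensitivity tensor", call. = FALSE)
  }
  tt <- tensor$time
  nt <- length(tt)
  w <- numeric(nt)  # trapezoid weights
  if (nt > 1) {
    dt <- diff(tt)
    w[1] <- dt[1] / 2
    w[nt] <- dt[nt - 1] / 2
    if (nt > 2) w[2:(nt - 1)] <- (dt[-1] + dt[-length(dt)]) / 2
  }
  V <- tensor$values
  A <- switch(aggregation,
    final_time = abs(V[nt, , , drop = TRUE]),
    time_integral_abs = apply(abs(V), c(2, 3), function(s) sum(w * s)),
    L2_over_time = sqrt(apply(V, c(2, 3), function(s) sum(w * s^2))))
  A <- matrix(A, length(tensor$outputs), length(tensor$inputs),
              dimnames = list(tensor$outputs, tensor$inputs))
  structure(A, aggregation = aggregation, class = c("score_matrix",
                                                    class(A)))
}

#' Export a sensitivity tensor as a long data frame
#'
#' @param tensor A `sensitivity_tensor`.
#' @return Data frame (time, output, input, value).
#' @export
sensitivity_frame <- function(tensor) {
  d <- dim(tensor$values)
  data.frame(
    time = rep(tensor$time, times = d[2] * d[3]),
    output = rep(rep(tensor$outputs, each = d[1]), times = d[3]),
    input = rep(tensor$inputs, each = d[1] * d[2]),
    value = as.vector(tensor$values),
    stringsAsFactors = FALSE)
}
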