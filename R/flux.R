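# Per-reaction kinetic flux along a trajectory: ranking and threshold
# filtering of the reactions that dominate flow through the network.

#' Compute per-reaction fluxes
#'
#' Evaluates each reaction's instantaneous rate (mol/s) either at the
#' final state of the trajectory (default) or as the trapezoidal time
#' average over the whole horizon, and returns the reactions ranked by
#' descending flux.
#'
#' @param model A `reaction_model`.
#' @param trajectory A `trajectory` of that model.
#' @param evaluation_point `"final_time"` or `"time_average"`.
#' @return A `flux_table` data frame (rank, reaction, name, flux_mol_per_s)
#'   sorted descending by flux, ties broken by reaction id.
#' @export
compute_fluxes <- function(model, trajectory,
                           evaluation_point = c("final_time",
                                                "time_average")) {
  evaluation_point <- match.arg(evaluation_point)
  if (!identical(colnames(trajectory$states), species_ids(model))) {
    stop("trajectory species do not match the model", call. = FALSE)
  }
  flux <- if (evaluation_point == "final_time") {
    .rate_vector(model, final_state(trajectory))
  } else {
    tt <- trajectory$time
    V <- t(apply(trajectory$states, 1, function(x) .rate_vector(model, x)))
    w <- numeric(length(tt))
    dt <- diff(tt)
    w[1] <- dt[1] / 2; w[length(tt)] <- dt[length(dt)] / 2
    if (length(tt) > 2) w[2:(length(tt) - 1)] <- (dt[-1] + dt[-length(dt)]) / 2
    colSums(V * w) / (max(tt) - min(tt))
  }
  out <- data.frame(reaction = reaction_ids(model),
                    name = reaction_names(model),
                    flux_mol_per_s = flux,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$flux_mol_per_s, out$reaction), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out[, c("rank", "reaction", "name", "flux_mol_per_s")],
            evaluation_point = evaluation_point,
            class = c("flux_table", "data.frame"))
}

#' Filter a flux table by minimum flux
#'
#' Keeps rows with flux >= `min_flux` (mol/s), preserving the descending
#' order (ties by reaction id). Idempotent; raising the threshold never
#' adds rows.
#'
#' @param table A `flux_table` (or any data frame with a
#'   `flux_mol_per_s` column).
#' @param min_flux Threshold in mol/s (default 500, the conventional
#'   high-flux cutoff).
#' @return The filtered table, ranks renumbered.
#' @export
top_reactions <- function(table, min_flux = 500) {
  keep <- table$flux_mol_per_s >= min_flux
  out <- table[keep, , drop = FALSE]
  ord <- order(-out$flux_mol_per_s,
               if (!is.null(out$reaction)) out$reaction else seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Published high-flux reaction table
#'
#' Loads the packaged transcription of the published 27-row high-flux
#' reaction list (fluxes in mol/s, from 215,000 down to 501) as a
#' `flux_table`-shaped data frame. This fixture is the reference for the
#' high-flux filter; it is a verbatim transcription, not a simulation
#' output.
#'
#' @return Data frame (rank, name, flux_mol_per_s).
#' @export
published_flux_table <- function() {
  path <- system.file("extdata", "published_flux_table.csv",
                      package = "stingfoxo", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        encoding = "UTF-8", check.names = FALSE)
  df <- df[order(-df$flux_mol_per_s, df$name), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "name", "flux_mol_per_s")]
}
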