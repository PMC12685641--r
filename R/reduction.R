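# Quasi-potential model reduction: combine per-reaction sensitivity, flux
# and peak product concentration into a landscape, rank reactions, and
# retain the dominant subsystem.

#' Reduction criteria
#'
#' A reaction passes the explicit criteria when (a) its rescaled
#' sensitivity lies within `half_width` of 1, (b) its flux is at least
#' `flux_min` mol/s, and (c) its peak product concentration reaches the
#' `concentration_quantile` of the per-reaction concentration
#' distribution. Independently, the `max_retained` best reactions by
#' combined rank are always retained.
#'
#' @param sensitivity_half_width Half-width of the sensitivity window
#'   around 1 (default 0.2, mirroring the 0.8-1.2 key-species band).
#' @param flux_min Minimum flux in mol/s (default 500).
#' @param concentration_quantile Quantile cutoff in \[0, 1\]
#'   (default 0.85).
#' @param max_retained Number of top combined-rank reactions always kept
#'   (default 12); `NULL` disables the rank fill.
#' @return A `reduction_criteria` list.
#' @export
reduction_criteria <- function(sensitivity_half_width = 0.2,
                               flux_min = 500,
                               concentration_quantile = 0.85,
                               max_retained = 12) {
  stopifnot(sensitivity_half_width > 0,
            concentration_quantile >= 0, concentration_quantile <= 1)
  structure(list(sensitivity_half_width = sensitivity_half_width,
                 flux_min = flux_min,
                 concentration_quantile = concentration_quantile,
                 max_retained = max_retained),
            class = "reduction_criteria")
}

#' Quasi-potential landscape
#'
#' One (sensitivity, flux, concentration) triple per reaction:
#' sensitivity is the largest aggregated sensitivity over the reaction's
#' rate parameters (L2 over output species), rescaled to unit median
#' across reactions; flux comes from the flux table; concentration is the
#' maximum abundance over time of the reaction's first (non-template)
#' product. The combined rank is the mean of the three per-axis
#' descending ranks — the landscape apex (dome top) has rank near 1.
#'
#' @param model A `reaction_model`.
#' @param score_matrix Matrix from [aggregate_sensitivities()] whose
#'   columns include the model's `"<reaction>.<parameter>"` inputs.
#' @param flux_table A `flux_table` from [compute_fluxes()].
#' @param trajectory The `trajectory` the fluxes were computed from.
#' @return Data frame (reaction, name, sensitivity, flux, concentration,
#'   combined_rank), one row per reaction.
#' @export
quasi_potential_landscape <- function(model, score_matrix, flux_table,
                                      trajectory) {
  rids <- reaction_ids(model)
  if (!identical(colnames(trajectory$states), species_ids(model)) ||
      !all(rids %in% flux_table$reaction)) {
    stop("landscape inputs derive from different models", call. = FALSE)
  }
  input_rx <- sub("\\.[^.]+$", "", colnames(score_matrix))
  input_sens <- sqrt(colSums(as.matrix(score_matrix)^2))
  sens <- vapply(rids, function(r) {
    cols <- input_rx == r
    if (!any(cols)) return(NA_real_)
    max(input_sens[cols])
  }, 0)
  if (anyNA(sens)) {
    stop("score matrix lacks parameter columns for some reactions",
         call. = FALSE)
  }
  med <- stats::median(sens)
  if (med > 0) sens <- sens / med
  flux <- flux_table$flux_mol_per_s[match(rids, flux_table$reaction)]
  conc <- vapply(model$reactions, function(rx) {
    prods <- setdiff(names(rx$products),
                     union(names(rx$reactants), rx$modifiers))
    if (length(prods) == 0) prods <- names(rx$products)
    max(trajectory$states[, prods[1]])
  }, 0)
  combined <- (rank(-sens, ties.method = "average") +
               rank(-flux, ties.method = "average") +
               rank(-conc, ties.method = "average")) / 3
  data.frame(reaction = rids, name = reaction_names(model),
             sensitivity = unname(sens), flux = unname(flux),
             concentration = unname(conc),
             combined_rank = unname(combined),
             stringsAsFactors = FALSE)
}

#' Reduce a model to its dominant reactions
#'
#' A reaction is retained iff it passes all explicit criteria
#' (sensitivity window, flux floor, concentration quantile) or it is
#' among the `max_retained` best reactions by combined landscape rank.
#' The reduction percentage is `100 * (1 - retained/total)`.
#'
#' @param model A `reaction_model`.
#' @param criteria A [reduction_criteria()].
#' @param landscape Optional precomputed landscape (from
#'   [quasi_potential_landscape()]); when `NULL` the full pipeline
#'   (simulation, sensitivities, fluxes) is run with defaults.
#' @return A `reduction_result`: `retained`, `removed` (reaction ids),
#'   `reduction_percent` (exact; round for reporting), `landscape`.
#' @export
reduce_model <- function(model, criteria = reduction_criteria(),
                         landscape = NULL) {
  if (is.null(landscape)) {
    tr <- simulate_model(model)
    sens <- local_sensitivities(model, inputs = "parameters")
    A <- aggregate_sensitivities(sens)
    fx <- compute_fluxes(model, tr)
    landscape <- quasi_potential_landscape(model, A, fx, tr)
  }
  pass <- abs(landscape$sensitivity - 1) <= criteria$sensitivity_half_width &
    landscape$flux >= criteria$flux_min &
    landscape$concentration >= stats::quantile(
      landscape$concentration, criteria$concentration_quantile)
  retained <- landscape$reaction[pass]
  if (!is.null(criteria$max_retained)) {
    ord <- order(landscape$combined_rank, landscape$reaction)
    retained <- union(retained,
                      landscape$reaction[ord][
                        seq_len(min(criteria$max_retained,
                                    nrow(landscape)))])
  }
  all_ids <- landscape$reaction
  removed <- setdiff(all_ids, retained)
  if (length(retained) == 0) {
    warning("criteria retain zero reactions", call. = FALSE)
  }
  structure(list(
    retained = sort(retained), removed = sort(removed),
    reduction_percent = 100 * (1 - length(retained) / length(all_ids)),
    landscape = landscape), class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> retained %d / %d reactions (%.0f%% reduction)\n",
              length(x$retained), length(x$retained) + length(x$removed),
              round(x$reduction_percent)))
  invisible(x)
}

#' Submodel containing only the retained reactions
#'
#' Species (and their initial amounts) are kept; removed reactions are
#' dropped. Used by the steady-state smoke check of the reduction.
#'
#' @param model A `reaction_model`.
#' @param result A `reduction_result`.
#' @return A `reaction_model` with the retained reactions only.
#' @export
reduced_submodel <- function(model, result) {
  keep <- vapply(model$reactions,
                 function(rx) rx$id %in% result$retained, TRUE)
  reaction_model(model$compartments, model$species,
                 model$reactions[keep],
                 pathway_tags = model$pathway_tags,
                 name = paste(model$metadata$name, "(reduced)"),
                 t_end = model$metadata$t_end,
                 notes = model$metadata$notes)
}
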