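# Principal component analysis of the sensitivity score matrix and
# band-filter selection of key species.

#' Principal component analysis of a score matrix
#'
#' Columns are mean-centered (no variance scaling, classical princomp
#' behavior) and decomposed by singular values. Loadings follow a fixed
#' sign convention: the largest-magnitude element of each column is made
#' positive. The per-species "PCA score" is the variance-weighted L2 norm
#' of the species' component scores over the leading components that
#' explain at least 90% of the variance, rescaled so the score
#' distribution has unit median — this makes the conventional
#' \[0.8, 1.2\] selection band meaningful on arbitrary models.
#'
#' @param A Numeric matrix (species x inputs), e.g. a `score_matrix` from
#'   [aggregate_sensitivities()]. Needs >= 2 rows and columns and
#'   non-degenerate variance.
#' @param var_target Cumulative explained-variance threshold used for the
#'   species score (default 0.9).
#' @return A `pca_result`: `loadings` (inputs x components, orthonormal),
#'   `component_scores` (species x components),
#'   `explained_variance_ratio`, and `species_score` (named, unit median).
#' @export
run_pca <- function(A, var_target = 0.9) {
  A <- as.matrix(A)
  if (nrow(A) < 2 || ncol(A) < 2) {
    stop("score matrix needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(!is.finite(A))) stop("score matrix must be finite", call. = FALSE)
  X <- scale(A, center = TRUE, scale = FALSE)
  if (all(abs(X) < .Machine$double.eps * 100)) {
    stop("degenerate input: score matrix has zero variance", call. = FALSE)
  }
  sv <- svd(X)
  k <- min(nrow(A) - 1, ncol(A))
  d <- sv$d[seq_len(k)]
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- X %*% loadings
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- d^2 / sum(sv$d^2)
  ncomp <- which(cumsum(evr) >= var_target)[1]
  if (is.na(ncomp)) ncomp <- k
  w <- evr[seq_len(ncomp)] / sum(evr[seq_len(ncomp)])
  raw <- sqrt((scores[, seq_len(ncomp), drop = FALSE]^2 %*% w)[, 1])
  med <- stats::median(raw)
  species_score <- if (med > 0) raw / med else raw
  names(species_score) <- rownames(A)
  rownames(loadings) <- colnames(A)
  rownames(scores) <- rownames(A)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = loadings, component_scores = scores,
                 explained_variance_ratio = evr,
                 n_components_used = ncomp,
                 species_score = species_score),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d species, %d components (%d used, %.1f%% var)\n",
              nrow(x$component_scores), ncol(x$component_scores),
              x$n_components_used,
              100 * sum(x$explained_variance_ratio[
                seq_len(x$n_components_used)])))
  invisible(x)
}

#' Select key species by PCA score band
#'
#' Returns species whose (unit-median) PCA score lies in the closed
#' interval `[lo, hi]`, ordered by descending score. The conventional band
#' 0.8-1.2 captures species of near-median, system-wide sensitivity —
#' components whose perturbation propagates broadly without being
#' dominated by a single extreme direction.
#'
#' @param result A `pca_result`.
#' @param lo,hi Inclusive band bounds (defaults 0.8 and 1.2).
#' @return Character vector of species ids, descending by score.
#' @export
select_key_species <- function(result, lo = 0.8, hi = 1.2) {
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  sc <- result$species_score
  sel <- sc[sc >= lo & sc <= hi]
  names(sel)[order(-sel, names(sel))]
}
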