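## broom-style tidiers.

#' Turn a fitted object into a tidy tibble
#'
#' Generics in the broom style; methods exist for the package's fitted
#' object classes.
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a dose-response fit
#'
#' @param x A [fit_dose_response()] object.
#' @param ... Unused.
#' @return One row per parameter: `term, estimate`.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("p0", "ec50", "h"),
         estimate = c(x$p0, x$ec50, x$h))
}

#' @rdname tidy.dose_response_fit
#' @return `glance()`: one row with `loglik, converged, n_concentrations,
#'   n_scored`.
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged,
         n_concentrations = nrow(x$table),
         n_scored = sum(x$table$n_scored))
}

#' Tidy ToxPi profiles
#'
#' @param x A [toxpi_profiles()] object.
#' @param ... Unused.
#' @return Long tibble `chemical_id, slice, scaled, score, rank`.
#' @export
tidy.toxpi_profiles <- function(x, ...) {
  slice_cols <- intersect(x$slice_defs$slice, names(x$profiles))
  tidyr::pivot_longer(x$profiles, dplyr::all_of(slice_cols),
                      names_to = "slice", values_to = "scaled")
}

#' @rdname tidy.toxpi_profiles
#' @return `glance()`: one row with `n_chemicals, n_slices, score_range`.
#' @export
glance.toxpi_profiles <- function(x, ...) {
  tibble(n_chemicals = nrow(x$profiles),
         n_slices = nrow(x$slice_defs),
         min_score = min(x$profiles$score),
         max_score = max(x$profiles$score))
}

#' Tidy PCA scores
#'
#' @param x A [pca_scores()] object.
#' @param ... Unused.
#' @return The sample-coordinate tibble.
#' @export
tidy.count_pca <- function(x, ...) x$scores

#' @rdname tidy.count_pca
#' @export
glance.count_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), top_n = x$top_n,
         pc1_var = x$variance$var_fraction[1],
         pc2_var = x$variance$var_fraction[2])
}
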