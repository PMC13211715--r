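## Multi-domain chemical prioritization: potency transforms, slice scaling,
## equal-weight scoring, ranking, Venn domain classification, and biphenyl
## substituent counting.

#' Valid biphenyl ring positions
#'
#' @return Character vector `2..6` and `2'..6'`.
#' @export
biphenyl_positions <- function() {
  c(as.character(2:6), paste0(2:6, "'"))
}

#' Count ortho/meta/para substituents on biphenyl structures
#'
#' Classifies ring positions by the standard rule -- ortho = \{2, 6, 2', 6'\},
#' meta = \{3, 5, 3', 5'\}, para = \{4, 4'\} -- and counts substituents per
#' type for each chemical.
#'
#' @param structures Tibble `chemical_id, position, substituent` with at most
#'   one substituent per position per chemical; positions must be among
#'   [biphenyl_positions()].
#' @return Tibble `chemical_id, substituent, n_ortho, n_meta, n_para,
#'   n_total`.
#' @examples
#' pcb153 <- tibble::tibble(chemical_id = "PCB153",
#'   position = c("2", "2'", "4", "4'", "5", "5'"), substituent = "Cl")
#' count_substituents(pcb153)  # ortho 2, meta 2, para 2, total 6
#' @export
count_substituents <- function(structures) {
  assert_columns(structures, c("chemical_id", "position", "substituent"),
                 "structures")
  structures <- mutate(structures,
                       position = gsub("′", "'", .data$position))
  bad <- setdiff(unique(structures$position), biphenyl_positions())
  if (length(bad) > 0) {
    validation_error("invalid ring position '%s' (valid: 2-6, 2'-6')", bad[1])
  }
  dup <- structures %>%
    count(.data$chemical_id, .data$position) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    validation_error("chemical %s has multiple substituents at position %s",
                     dup$chemical_id[1], dup$position[1])
  }
  cls <- function(pos) {
    base <- sub("'", "", pos)
    c(`2` = "ortho", `6` = "ortho", `3` = "meta", `5` = "meta",
      `4` = "para")[base]
  }
  structures %>%
    mutate(ring_class = cls(.data$position)) %>%
    group_by(.data$chemical_id, .data$substituent) %>%
    summarise(n_ortho = sum(.data$ring_class == "ortho"),
              n_meta = sum(.data$ring_class == "meta"),
              n_para = sum(.data$ring_class == "para"),
              n_total = n(), .groups = "drop")
}

#' Potency transform for benchmark concentrations
#'
#' Maps a BMC in uM to `-log10(BMC)` so that more potent (lower) BMCs score
#' higher. `NA` (no BMC, i.e. inactive) is passed through as the sentinel
#' that [scale_slice()] maps to 0 -- absence of detectable potency is the
#' weakest signal.
#'
#' @param bmc Numeric vector of BMCs in uM; `NA` for inactive.
#' @return `-log10(bmc)`, with `NA` preserved.
#' @examples
#' potency_transform(c(1, 0.1, 100, NA))
#' @export
potency_transform <- function(bmc) {
  if (any(bmc <= 0, na.rm = TRUE)) validation_error("BMC must be positive")
  -log10(bmc)
}

#' Min-max scale a slice across the chemical set
#'
#' Linear scaling of the finite values to \[0, 1\]; `invert = TRUE` applies
#' `x -> (max - x) / (max - min)` instead, for descriptors where smaller
#' means stronger signal. A constant slice scales to all 0, and non-finite
#' inputs (the inactive sentinel) always scale to 0.
#'
#' @param x Numeric vector (one slice's raw values across chemicals).
#' @param invert Flip the direction.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' scale_slice(c(1, 2, 3))          # 0, 0.5, 1
#' scale_slice(c(1, 2, 3), TRUE)    # 1, 0.5, 0
#' @export
scale_slice <- function(x, invert = FALSE) {
  fin <- is.finite(x)
  if (!any(fin)) validation_error("slice has no finite value")
  rng <- range(x[fin])
  out <- numeric(length(x))
  if (rng[2] > rng[1]) {
    out[fin] <- if (invert) (rng[2] - x[fin]) / (rng[2] - rng[1]) else
      (x[fin] - rng[1]) / (rng[2] - rng[1])
  }                                   # constant slice stays all 0
  out[!fin] <- 0
  out
}

#' Weighted ToxPi score
#'
#' `score = sum(w_j * s_j) / sum(w_j)` over scaled slice values; with the
#' default equal weights this is the mean slice value.
#'
#' @param slices Numeric vector of scaled slice values in \[0, 1\].
#' @param weights Positive weights, same length.
#' @return Score in \[0, 1\].
#' @export
toxpi_score <- function(slices, weights = rep(1, length(slices))) {
  if (length(slices) != length(weights)) {
    validation_error("slices and weights differ in length")
  }
  if (any(weights <= 0)) validation_error("weights must be positive")
  sum(weights * slices) / sum(weights)
}

#' Build ToxPi profiles for a chemical set
#'
#' Scales each slice's raw values across the chemical set (per source column,
#' then averaging multiple sources within a slice), applies the slice
#' weights, and ranks chemicals by overall score (ties broken
#' lexicographically by `chemical_id`).
#'
#' @param slice_values Long tibble `chemical_id, slice, value` with an
#'   optional `source` column for multi-column slices; `NA` values are the
#'   inactive sentinel and scale to 0.
#' @param slice_defs Tibble `slice, domain, weight, invert`; defaults to
#'   equal weight 1 and no inversion for every slice present.
#' @return A `toxpi_profiles` object: list with `profiles` (wide tibble of
#'   scaled slices plus `score` and `rank`) and `slice_defs`. See
#'   [tidy.toxpi_profiles()] and [autoplot.toxpi_profiles()].
#' @export
toxpi_profiles <- function(slice_values, slice_defs = NULL) {
  assert_columns(slice_values, c("chemical_id", "slice", "value"),
                 "slice values")
  if (!"source" %in% names(slice_values)) slice_values$source <- "value"
  if (is.null(slice_defs)) {
    slice_defs <- tibble(slice = unique(slice_values$slice),
                         domain = unique(slice_values$slice),
                         weight = 1, invert = FALSE)
  }
  assert_columns(slice_defs, c("slice", "weight", "invert"), "slice definitions")
  if (anyDuplicated(slice_defs$slice)) {
    validation_error("slice names must be unique")
  }
  if (any(slice_defs$weight <= 0)) validation_error("weights must be positive")
  unknown <- setdiff(slice_values$slice, slice_defs$slice)
  if (length(unknown) > 0) {
    validation_error("slice '%s' has no definition", unknown[1])
  }
  scaled <- slice_values %>%
    left_join(slice_defs[c("slice", "invert")], by = "slice") %>%
    group_by(.data$slice, .data$source) %>%
    mutate(scaled = scale_slice(.data$value, invert = .data$invert[1])) %>%
    group_by(.data$chemical_id, .data$slice) %>%
    summarise(scaled = mean(.data$scaled), .groups = "drop")
  wide <- tidyr::pivot_wider(scaled, names_from = "slice",
                             values_from = "scaled", values_fill = 0)
  slice_cols <- slice_defs$slice[slice_defs$slice %in% names(wide)]
  w <- slice_defs$weight[match(slice_cols, slice_defs$slice)]
  wide$score <- apply(as.matrix(wide[slice_cols]), 1, toxpi_score, weights = w)
  wide <- wide %>%
    arrange(dplyr::desc(.data$score), .data$chemical_id) %>%
    mutate(rank = row_number())
  structure(list(profiles = wide, slice_defs = slice_defs),
            class = "toxpi_profiles")
}

#' @export
print.toxpi_profiles <- function(x, ...) {
  cat(sprintf("ToxPi profiles: %d chemicals x %d slices\n",
              nrow(x$profiles), nrow(x$slice_defs)))
  print(head(x$profiles[c("chemical_id", "score", "rank")], 10))
  invisible(x)
}

#' Slice matrix of a ToxPi profile set
#'
#' @param x A `toxpi_profiles` object.
#' @return Numeric matrix (chemicals x slices) with chemical row names,
#'   ready for [ward_cluster()].
#' @export
toxpi_matrix <- function(x) {
  stopifnot(inherits(x, "toxpi_profiles"))
  slice_cols <- intersect(x$slice_defs$slice, names(x$profiles))
  m <- as.matrix(x$profiles[slice_cols])
  rownames(m) <- x$profiles$chemical_id
  m
}

#' Classify chemicals by active assay domains
#'
#' Venn-style partition of a chemical set by which of the three biological
#' domains (morphology, EPR, LPR) produced a benchmark concentration (or any
#' other presence flag). Each chemical lands in exactly one of 8 regions.
#'
#' @param hits Tibble `chemical_id, morphology, epr, lpr` with
#'   logical/0-1 presence flags (`NA` treated as absent).
#' @return List: `chemicals` (tibble with a `region` label per chemical) and
#'   `regions` (tibble `region, n` whose counts partition the set).
#' @export
classify_activity_domains <- function(hits) {
  assert_columns(hits, c("chemical_id", "morphology", "epr", "lpr"), "hits")
  label <- function(m, e, l) {
    present <- c("morphology", "EPR", "LPR")[c(isTRUE(m), isTRUE(e), isTRUE(l))]
    if (length(present) == 0) "none"
    else if (length(present) == 1) paste0(present, "-only")
    else paste(present, collapse = "+")
  }
  chems <- hits %>%
    mutate(region = purrr::pmap_chr(
      list(as.logical(.data$morphology), as.logical(.data$epr),
           as.logical(.data$lpr)), label))
  all_regions <- c("none", "morphology-only", "EPR-only", "LPR-only",
                   "morphology+EPR", "morphology+LPR", "EPR+LPR",
                   "morphology+EPR+LPR")
  regions <- tibble(region = all_regions) %>%
    left_join(count(chems, .data$region), by = "region") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  list(chemicals = chems, regions = regions)
}
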