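## ggplot2 figures for the main result types.

#' Plot a fitted dose-response curve over the observed incidence
#'
#' @param object A [fit_dose_response()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  tab <- object$table %>%
    mutate(frac = ifelse(.data$n_scored > 0,
                         .data$n_affected / .data$n_scored, NA))
  nz <- tab$concentration_uM[tab$concentration_uM > 0]
  grid <- tibble(
    concentration_uM = 10^seq(log10(min(nz) / 10), log10(max(nz) * 2),
                              length.out = 200)
  ) %>%
    mutate(p = loglogistic_incidence(.data$concentration_uM, object$p0,
                                     object$ec50, object$h))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$concentration_uM)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$frac, size = .data$n_scored)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (uM, log scale)", y = "Fraction affected",
                  size = "n scored") +
    ggplot2::theme_minimal()
}

#' Plot ToxPi scores as a ranked bar chart
#'
#' @param object A [toxpi_profiles()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.toxpi_profiles <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$chemical_id, -.data$score),
                               y = .data$scaled, fill = .data$slice)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Summed scaled slice value", fill = "Slice") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot PCA sample coordinates
#'
#' @param object A [pca_scores()] object.
#' @param colour_by Optional named vector (sample_id -> group) for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.count_pca <- function(object, colour_by = NULL, ...) {
  sc <- object$scores
  if (!is.null(colour_by)) sc$group <- colour_by[sc$sample_id]
  vf <- object$variance$var_fraction
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Plot mean EPR movement traces per concentration
#'
#' @param frames Long frame tibble for one chemical's plate.
#' @param plates Validated plate table.
#' @param protocol An [epr_protocol()] (for pulse annotations).
#' @return A ggplot of the across-embryo mean movement index over time,
#'   one line per concentration, with the light pulses marked.
#' @export
plot_epr_traces <- function(frames, plates, protocol = epr_protocol()) {
  dat <- frames %>%
    left_join(plates[c("plate_barcode", "well_id", "concentration_uM")],
              by = c("plate_barcode", "well_id")) %>%
    group_by(.data$concentration_uM, .data$time_s) %>%
    summarise(mi = mean(.data$movement_index), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$mi,
                                    colour = factor(.data$concentration_uM))) +
    ggplot2::geom_vline(xintercept = protocol$pulse_times,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Mean movement index",
                  colour = "uM") +
    ggplot2::theme_minimal()
}

#' Plot mean LPR activity per 6-s bin
#'
#' @param bins Binned trace tibble for one chemical's plate.
#' @param plates Validated plate table.
#' @param protocol An [lpr_protocol()].
#' @return A ggplot of mean binned distance over time per concentration with
#'   dark epochs shaded.
#' @export
plot_lpr_traces <- function(bins, plates, protocol = lpr_protocol()) {
  lab <- lpr_bin_labels(bins$bin_start_s, protocol)
  dat <- bins %>%
    left_join(plates[c("plate_barcode", "well_id", "concentration_uM")],
              by = c("plate_barcode", "well_id")) %>%
    group_by(.data$concentration_uM, .data$bin_start_s) %>%
    summarise(distance = mean(.data$distance), .groups = "drop")
  cycle_len <- protocol$light_dur + protocol$dark_dur
  shades <- tibble(
    xmin = (seq_len(protocol$n_cycles) - 1) * cycle_len + protocol$light_dur,
    xmax = seq_len(protocol$n_cycles) * cycle_len
  )
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(data = shades,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       fill = "grey90") +
    ggplot2::geom_line(ggplot2::aes(x = .data$bin_start_s, y = .data$distance,
                                    colour = factor(.data$concentration_uM))) +
    ggplot2::labs(x = "Time (s)", y = "Mean distance per 6-s bin",
                  colour = "uM") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
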