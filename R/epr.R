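## Embryonic photomotor response: movement index, interval summaries, and the
## compound KS + peak-difference hit rule.

#' Frame-differencing movement index
#'
#' Mean absolute per-pixel difference between consecutive frames, normalized
#' by the mean intensity of the previous frame (plus epsilon = 1e-9 to keep
#' the ratio defined for dark frames). Identical frames give 0; rescaling
#' both frames by a common positive factor leaves the index unchanged.
#'
#' @param frame_t,frame_prev Equal-shaped non-negative numeric arrays (pixel
#'   intensities).
#' @return Scalar >= 0.
#' @examples
#' movement_index(matrix(2, 4, 4), matrix(1, 4, 4))  # 1
#' @export
movement_index <- function(frame_t, frame_prev) {
  if (!identical(dim(frame_t) %||% length(frame_t),
                 dim(frame_prev) %||% length(frame_prev))) {
    validation_error("frames must have identical shape")
  }
  if (any(frame_t < 0) || any(frame_prev < 0)) {
    validation_error("pixel intensities must be non-negative")
  }
  mean(abs(frame_t - frame_prev)) / (mean(frame_prev) + 1e-9)
}

#' Interval summaries of a movement-index series
#'
#' Arithmetic mean of the movement index over the protocol's three half-open
#' analysis windows: background \[21, 30), excitatory \[31, 39), refractory
#' \[41, 48) seconds from assay start.
#'
#' @param frames Long frame tibble (`plate_barcode`, `well_id`, `time_s`,
#'   `movement_index`) covering the assay; may hold many embryos.
#' @param protocol An [epr_protocol()].
#' @return Tibble `plate_barcode, well_id, B, E, R` (one row per embryo).
#' @export
summarize_intervals <- function(frames, protocol = epr_protocol()) {
  assert_columns(frames, c("plate_barcode", "well_id", "time_s", "movement_index"),
                 "frames")
  w <- protocol$windows
  in_win <- function(t, win) t >= win[1] & t < win[2]
  out <- frames %>%
    group_by(.data$plate_barcode, .data$well_id) %>%
    summarise(
      B = mean(.data$movement_index[in_win(.data$time_s, w$background)]),
      E = mean(.data$movement_index[in_win(.data$time_s, w$excitatory)]),
      R = mean(.data$movement_index[in_win(.data$time_s, w$refractory)]),
      .groups = "drop"
    )
  for (col in c("B", "E", "R")) {
    if (anyNA(out[[col]])) {
      validation_error(
        "no frames fall inside the %s window for well %s",
        switch(col, B = "background", E = "excitatory", R = "refractory"),
        out$well_id[is.na(out[[col]])][1])
    }
  }
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference of the two empirical CDFs, computed
#' over the pooled sample points (exact for any sample sizes); the p-value is
#' the asymptotic two-sample Kolmogorov tail
#' `Q(sqrt(n_x * n_y / (n_x + n_y)) * D)` with
#' `Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List `statistic` (D), `p_value`.
#' @examples
#' ks_two_sample(c(1, 2), c(1.5, 2.5))  # D = 0.5
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    validation_error("both samples must be non-empty")
  }
  pts <- sort(unique(c(x, y)))
  ## right-continuous ECDFs evaluated at every pooled point
  fx <- vapply(pts, function(p) mean(x <= p), 0)
  fy <- vapply(pts, function(p) mean(y <= p), 0)
  d <- max(abs(fx - fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  t <- sqrt(n_eff) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(statistic = d, p_value = min(max(p, 0), 1))
}

#' EPR compound hit call
#'
#' For each non-zero concentration and each interval (B, E, R), the
#' concentration is active in that interval iff both
#' \enumerate{
#'   \item the two-sample KS test on the per-embryo interval means (treated
#'     vs in-plate control) has `p < epr_alpha` (default 0.05/7 = 0.007), and
#'   \item the relative peak difference
#'     `|peak(treated mean trace) - peak(control mean trace)| / peak(control
#'     mean trace) >= epr_peak_diff` (default 0.5), peaks taken as the maxima
#'     of the across-embryo mean trace within that interval's window.
#' }
#' Arms with fewer than 3 embryos after exclusions are flagged `untestable`
#' rather than inactive. Wells dead at 24 hpf are excluded.
#'
#' @param frames Long frame tibble for one or more plates.
#' @param plates Validated plate table (for concentrations and exclusion
#'   flags).
#' @param thresholds A [hit_thresholds()].
#' @param protocol An [epr_protocol()].
#' @return Tibble, one row per chemical x concentration x interval:
#'   `D`, `p_value`, `peak_ratio`, `n_treated`, `n_control`, `untestable`,
#'   `active`.
#' @export
epr_hits <- function(frames, plates, thresholds = hit_thresholds(),
                     protocol = epr_protocol()) {
  alive <- plates[plates$dead_24h == 0L, ]
  frames <- semi_join(frames, alive, by = c("plate_barcode", "well_id"))
  summaries <- summarize_intervals(frames, protocol) %>%
    left_join(alive[c("plate_barcode", "well_id", "chemical_id", "concentration_uM")],
              by = c("plate_barcode", "well_id"))
  ## across-embryo mean trace per chemical x concentration x frame time
  mean_traces <- frames %>%
    left_join(alive[c("plate_barcode", "well_id", "chemical_id", "concentration_uM")],
              by = c("plate_barcode", "well_id")) %>%
    group_by(.data$chemical_id, .data$concentration_uM, .data$time_s) %>%
    summarise(mi = mean(.data$movement_index), .groups = "drop")
  window_peaks <- function(tr) {
    vapply(protocol$windows, function(win) {
      max(tr$mi[tr$time_s >= win[1] & tr$time_s < win[2]])
    }, 0)
  }
  purrr::map_dfr(unique(alive$chemical_id), function(chem) {
    ss <- summaries[summaries$chemical_id == chem, ]
    tr <- mean_traces[mean_traces$chemical_id == chem, ]
    ctrl <- ss[ss$concentration_uM == 0, ]
    ctrl_peaks <- window_peaks(tr[tr$concentration_uM == 0, ])
    concs <- sort(setdiff(unique(ss$concentration_uM), 0))
    purrr::map_dfr(concs, function(cc) {
      trt <- ss[ss$concentration_uM == cc, ]
      trt_peaks <- window_peaks(tr[tr$concentration_uM == cc, ])
      purrr::imap_dfr(c(background = "B", excitatory = "E", refractory = "R"),
                      function(col, interval) {
        untestable <- nrow(trt) < 3 || nrow(ctrl) < 3
        if (untestable) {
          return(tibble(chemical_id = chem, concentration_uM = cc,
                        interval = interval, D = NA_real_, p_value = NA_real_,
                        peak_ratio = NA_real_, n_treated = nrow(trt),
                        n_control = nrow(ctrl), untestable = TRUE,
                        active = NA))
        }
        ks <- ks_two_sample(trt[[col]], ctrl[[col]])
        pr <- abs(trt_peaks[[interval]] - ctrl_peaks[[interval]]) /
          ctrl_peaks[[interval]]
        tibble(chemical_id = chem, concentration_uM = cc, interval = interval,
               D = ks$statistic, p_value = ks$p_value, peak_ratio = pr,
               n_treated = nrow(trt), n_control = nrow(ctrl),
               untestable = FALSE,
               active = ks$p_value < thresholds$epr_alpha &
                 pr >= thresholds$epr_peak_diff)
      })
    })
  })
}

#' Per-chemical behavioral BMC from EPR interval means
#'
#' Summarizes each surviving embryo's chosen interval mean and converts the
#' per-animal responses into a benchmark concentration through the
#' percentile-classification rule of [behavioral_bmc()].
#'
#' @param frames Long frame tibble.
#' @param plates Validated plate table.
#' @param interval Which interval mean to use (`"E"` excitatory by default).
#' @param protocol An [epr_protocol()].
#' @param bmr Added-risk benchmark response.
#' @return Tibble `chemical_id, bmc` (`NA` when unattainable).
#' @export
epr_bmc <- function(frames, plates, interval = "E",
                    protocol = epr_protocol(), bmr = 0.10) {
  alive <- plates[plates$dead_24h == 0L, ]
  frames <- semi_join(frames, alive, by = c("plate_barcode", "well_id"))
  summaries <- summarize_intervals(frames, protocol) %>%
    left_join(alive[c("plate_barcode", "well_id", "chemical_id",
                      "concentration_uM")],
              by = c("plate_barcode", "well_id"))
  purrr::map_dfr(unique(summaries$chemical_id), function(chem) {
    ss <- summaries[summaries$chemical_id == chem, ]
    responses <- tibble(concentration_uM = ss$concentration_uM,
                        response = ss[[interval]])
    est <- tryCatch(behavioral_bmc(responses, bmr = bmr)$bmc,
                    error = function(e) NA_real_)
    tibble(chemical_id = chem, bmc = est)
  })
}
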