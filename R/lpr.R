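## Larval photomotor response: binning, exclusion, cycle AUC, and the
## KS + relative-AUC activity rule.

#' Integrate raw 40-ms samples into 6-s bins
#'
#' Each bin is the sum of the samples whose timestamps fall in its half-open
#' window (6 s / 0.04 s = 150 samples per bin), labeled with light/dark epoch
#' and cycle index. Binning conserves total distance exactly.
#'
#' @param samples Tibble `plate_barcode, well_id, time_s, distance` sampled
#'   every `protocol$sample_period` seconds, covering the assay without gaps.
#' @param protocol An [lpr_protocol()].
#' @return Tibble `plate_barcode, well_id, bin_start_s, distance, cycle,
#'   epoch`.
#' @export
bin_distances <- function(samples, protocol = lpr_protocol()) {
  assert_columns(samples, c("plate_barcode", "well_id", "time_s", "distance"),
                 "samples")
  if (any(samples$distance < 0)) validation_error("distances must be non-negative")
  gaps <- samples %>%
    group_by(.data$plate_barcode, .data$well_id) %>%
    summarise(max_gap = max(diff(sort(.data$time_s))), .groups = "drop")
  if (any(gaps$max_gap > protocol$sample_period + 1e-9)) {
    validation_error("gap larger than one sample period in well %s",
                     gaps$well_id[which.max(gaps$max_gap)])
  }
  out <- samples %>%
    mutate(bin_start_s = floor(.data$time_s / protocol$bin_width) *
             protocol$bin_width) %>%
    group_by(.data$plate_barcode, .data$well_id, .data$bin_start_s) %>%
    summarise(distance = sum(.data$distance), .groups = "drop")
  lab <- lpr_bin_labels(out$bin_start_s, protocol)
  out$cycle <- lab$cycle
  out$epoch <- lab$epoch
  arrange(out, .data$plate_barcode, .data$well_id, .data$bin_start_s)
}

#' Exclude traces of dead or malformed larvae
#'
#' Removes binned traces for wells flagged `dead_120h` or `malformed_120h`,
#' reporting how many larvae were dropped.
#'
#' @param bins Binned trace tibble.
#' @param plates Validated plate table.
#' @return Filtered bins tibble.
#' @export
exclude_invalid <- function(bins, plates) {
  bad <- plates[plates$dead_120h == 1L | plates$malformed_120h == 1L,
                c("plate_barcode", "well_id")]
  kept <- anti_join(bins, bad, by = c("plate_barcode", "well_id"))
  n_dropped <- nrow(distinct(semi_join(bins, bad,
                                       by = c("plate_barcode", "well_id")),
                             .data$plate_barcode, .data$well_id))
  if (n_dropped > 0) {
    inform(sprintf("excluded %d dead/malformed larva(e)", n_dropped))
  }
  if (nrow(kept) == 0) warn("all larvae excluded; no traces remain")
  kept
}

#' Per-larva AUC over the analysis cycle
#'
#' AUC is the sum of bin distances over both epochs of the protocol's
#' analysis cycle (default: the third analyzed cycle, i.e. overall cycle 4).
#' Per-plate and per-chemical values are means of these per-larva AUCs.
#'
#' @param bins Binned trace tibble (labeled or not; cycle labels are derived
#'   from `bin_start_s` when absent).
#' @param protocol An [lpr_protocol()].
#' @return Tibble `plate_barcode, well_id, auc`.
#' @export
cycle_auc <- function(bins, protocol = lpr_protocol()) {
  assert_columns(bins, c("plate_barcode", "well_id", "bin_start_s", "distance"),
                 "bins")
  if (!"cycle" %in% names(bins)) {
    bins$cycle <- lpr_bin_labels(bins$bin_start_s, protocol)$cycle
  }
  use <- bins[bins$cycle == protocol$analysis_cycle, ]
  if (nrow(use) == 0) {
    validation_error("analysis cycle %d not present in traces",
                     protocol$analysis_cycle)
  }
  use %>%
    group_by(.data$plate_barcode, .data$well_id) %>%
    summarise(auc = sum(.data$distance), .groups = "drop")
}

#' LPR activity call for one treated arm
#'
#' Computes the signed relative AUC change
#' `rel = (mean AUC_treated - mean AUC_control) / mean AUC_control` and calls
#' the arm active iff the two-sample KS test on the per-larva AUCs has
#' `p < lpr_alpha` and `rel >= lpr_up` (hyperactivity) or `rel <= lpr_down`
#' (hypoactivity).
#'
#' @param treated,control Numeric vectors of per-larva AUCs (>= 3 each).
#' @param thresholds A [hit_thresholds()].
#' @return Tibble with one row: `rel_change, D, p_value, active,
#'   untestable`.
#' @export
lpr_hit_call <- function(treated, control, thresholds = hit_thresholds()) {
  if (length(treated) < 3 || length(control) < 3) {
    return(tibble(rel_change = NA_real_, D = NA_real_, p_value = NA_real_,
                  active = NA, untestable = TRUE))
  }
  mc <- mean(control)
  if (mc == 0) validation_error("degenerate control: mean control AUC is 0")
  rel <- (mean(treated) - mc) / mc
  ks <- ks_two_sample(treated, control)
  tibble(rel_change = rel, D = ks$statistic, p_value = ks$p_value,
         active = ks$p_value < thresholds$lpr_alpha &
           (rel >= thresholds$lpr_up | rel <= thresholds$lpr_down),
         untestable = FALSE)
}

#' LPR hit table for a screen
#'
#' Excludes dead/malformed larvae, computes per-larva analysis-cycle AUCs,
#' and applies [lpr_hit_call()] per chemical x non-zero concentration against
#' the in-plate 0-uM controls.
#'
#' @param bins Binned trace tibble for one or more plates.
#' @param plates Validated plate table.
#' @param thresholds A [hit_thresholds()].
#' @param protocol An [lpr_protocol()].
#' @return Tibble, one row per chemical x concentration: `rel_change, D,
#'   p_value, n_treated, n_control, active, untestable`.
#' @export
lpr_hits <- function(bins, plates, thresholds = hit_thresholds(),
                     protocol = lpr_protocol()) {
  kept <- exclude_invalid(bins, plates)
  aucs <- cycle_auc(kept, protocol) %>%
    left_join(plates[c("plate_barcode", "well_id", "chemical_id", "concentration_uM")],
              by = c("plate_barcode", "well_id"))
  purrr::map_dfr(unique(aucs$chemical_id), function(chem) {
    aa <- aucs[aucs$chemical_id == chem, ]
    ctrl <- aa$auc[aa$concentration_uM == 0]
    concs <- sort(setdiff(unique(aa$concentration_uM), 0))
    purrr::map_dfr(concs, function(cc) {
      trt <- aa$auc[aa$concentration_uM == cc]
      lpr_hit_call(trt, ctrl, thresholds) %>%
        mutate(chemical_id = chem, concentration_uM = cc,
               n_treated = length(trt), n_control = length(ctrl)) %>%
        select("chemical_id", "concentration_uM", "rel_change", "D",
               "p_value", "n_treated", "n_control", "active", "untestable")
    })
  })
}

#' Per-chemical behavioral BMC from LPR AUCs
#'
#' Converts per-larva analysis-cycle AUCs (after dead/malformed exclusion)
#' into a benchmark concentration through the percentile-classification rule
#' of [behavioral_bmc()].
#'
#' @param bins Binned trace tibble.
#' @param plates Validated plate table.
#' @param protocol An [lpr_protocol()].
#' @param bmr Added-risk benchmark response.
#' @return Tibble `chemical_id, bmc` (`NA` when unattainable).
#' @export
lpr_bmc <- function(bins, plates, protocol = lpr_protocol(), bmr = 0.10) {
  kept <- exclude_invalid(bins, plates)
  aucs <- cycle_auc(kept, protocol) %>%
    left_join(plates[c("plate_barcode", "well_id", "chemical_id",
                      "concentration_uM")],
              by = c("plate_barcode", "well_id"))
  purrr::map_dfr(unique(aucs$chemical_id), function(chem) {
    aa <- aucs[aucs$chemical_id == chem, ]
    responses <- tibble(concentration_uM = aa$concentration_uM,
                        response = aa$auc)
    est <- tryCatch(behavioral_bmc(responses, bmr = bmr)$bmc,
                    error = function(e) NA_real_)
    tibble(chemical_id = chem, bmc = est)
  })
}
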