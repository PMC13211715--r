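#' Default screen design
#'
#' The standard high-throughput exposure layout: one chemical per 96-well
#' plate, seven nominal concentrations (0, 0.01, 0.1, 1, 10, 50, 100 uM) with
#' one plate row per concentration (n = 12 embryos each). Concentration 0 is
#' the in-plate vehicle control.
#'
#' @param chemical_id Chemical identifier for the plate.
#' @param plate_barcode Plate barcode (unique per plate).
#' @param concentrations Non-negative uM values, must include exactly one 0.
#' @param n_per_concentration Embryos per concentration (plate row width).
#' @return A `screen_design` list with validated fields.
#' @examples
#' screen_design("PCB126", "P0001")
#' @export
screen_design <- function(chemical_id,
                          plate_barcode,
                          concentrations = c(0, 0.01, 0.1, 1, 10, 50, 100),
                          n_per_concentration = 12L) {
  concentrations <- as.numeric(concentrations)
  if (anyNA(concentrations) || any(concentrations < 0)) {
    validation_error("concentrations must be non-negative numbers")
  }
  if (anyDuplicated(concentrations)) {
    validation_error("concentrations must be unique")
  }
  if (sum(concentrations == 0) != 1L) {
    validation_error("concentrations must include exactly one 0 (control)")
  }
  if (n_per_concentration < 1L) {
    validation_error("n_per_concentration must be >= 1")
  }
  if (length(concentrations) > 8L || n_per_concentration > 12L) {
    validation_error("design exceeds 96-well plate geometry (8 rows x 12 columns)")
  }
  structure(
    list(chemical_id = as.character(chemical_id),
         plate_barcode = as.character(plate_barcode),
         concentrations = sort(concentrations),
         n_per_concentration = as.integer(n_per_concentration)),
    class = "screen_design"
  )
}

#' Default developmental endpoint catalog
#'
#' Binary endpoints scored at 24 hpf (mortality, developmental progression,
#' spontaneous movement, notochord) and at 120 hpf (mortality plus a suite of
#' ten developmental abnormalities). The 120-hpf abnormality list is an
#' editorial default -- the screening literature enumerates categories, not a
#' frozen ID list -- and any catalog with the same columns is accepted
#' everywhere a catalog is taken.
#'
#' @return Tibble with columns `endpoint_id`, `stage` (`"24hpf"`/`"120hpf"`),
#'   `is_mortality` (0/1).
#' @examples
#' default_endpoint_catalog()
#' @export
default_endpoint_catalog <- function() {
  tibble(
    endpoint_id = c("MO24", "DP24", "SM24", "NC24",
                    "MORT", "YSE", "AXIS", "EYE", "SNOU", "JAW",
                    "PE", "TRUN", "CFIN", "PIG", "SOMI"),
    stage = c(rep("24hpf", 4), rep("120hpf", 11)),
    is_mortality = as.integer(c(1, 0, 0, 0, 1, rep(0, 10)))
  )
}

validate_endpoint_catalog <- function(catalog) {
  assert_columns(catalog, c("endpoint_id", "stage", "is_mortality"),
                 "endpoint catalog")
  if (anyDuplicated(catalog$endpoint_id)) {
    validation_error("endpoint catalog has duplicate endpoint_id values")
  }
  if (!all(catalog$stage %in% c("24hpf", "120hpf"))) {
    validation_error("endpoint stage must be '24hpf' or '120hpf'")
  }
  for (st in unique(catalog$stage)) {
    if (sum(catalog$is_mortality[catalog$stage == st]) < 1) {
      validation_error("endpoint catalog needs a mortality endpoint at stage %s", st)
    }
  }
  invisible(catalog)
}

#' Hit-calling thresholds
#'
#' All statistical thresholds used by the hit-calling stages, with the
#' screen's standard values as defaults:
#' \itemize{
#'   \item `lel_alpha`: one-sided exact binomial alpha for the lowest effect
#'     level (0.05).
#'   \item `fisher_family_alpha`: family-wise alpha for the per-concentration
#'     Fisher activity flags; Bonferroni-split across the non-zero
#'     concentrations of an endpoint (0.05).
#'   \item `bmr`: benchmark response as added risk over background (0.10).
#'   \item `epr_alpha`: per-test KS alpha for the embryonic photomotor
#'     response, Bonferroni-corrected 0.05 / 7 concentration groups = 0.007.
#'   \item `epr_peak_diff`: minimum relative peak difference of the mean
#'     movement trace (0.50).
#'   \item `lpr_alpha`: KS alpha for the larval photomotor response (0.01).
#'   \item `lpr_up`, `lpr_down`: relative AUC change thresholds for
#'     hyperactivity (>= +1.0) and hypoactivity (<= -0.3).
#'   \item `deg_alpha`: raw p-value cutoff defining differentially expressed
#'     genes, inclusive, with no fold-change filter (0.05).
#' }
#'
#' @param ... Named overrides for any threshold.
#' @return A `hit_thresholds` list.
#' @examples
#' hit_thresholds()
#' hit_thresholds(lpr_alpha = 0.05)
#' @export
hit_thresholds <- function(...) {
  th <- list(
    lel_alpha = 0.05,
    fisher_family_alpha = 0.05,
    bmr = 0.10,
    epr_alpha = 0.05 / 7,
    epr_peak_diff = 0.50,
    lpr_alpha = 0.01,
    lpr_up = 1.0,
    lpr_down = -0.3,
    deg_alpha = 0.05,
    control_rate_floor_num = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown) > 0) {
    validation_error("unknown threshold(s): %s", paste(unknown, collapse = ", "))
  }
  th[names(dots)] <- dots
  alphas <- c("lel_alpha", "fisher_family_alpha", "epr_alpha", "lpr_alpha",
              "deg_alpha")
  for (a in alphas) {
    if (th[[a]] <= 0 || th[[a]] >= 1) validation_error("%s must be in (0,1)", a)
  }
  if (th$bmr <= 0 || th$bmr >= 1) validation_error("bmr must be in (0,1)")
  structure(th, class = "hit_thresholds")
}

#' Embryonic photomotor response protocol
#'
#' The 51-s assay: 30 s of background activity in darkness, a 1-s visible
#' light pulse, 9 s of darkness, a second 1-s pulse, then 10 s of darkness.
#' Movement is summarized over three half-open analysis windows: background
#' \[21, 30), the 9 s before the first pulse; excitatory \[31, 39), the 8 s
#' after the first pulse; refractory \[41, 48), the 7 s after the second
#' pulse. Times are anchored to assay start at t = 0.
#'
#' @param frame_rate Camera frame rate in frames per second.
#' @return An `epr_protocol` list with phase durations and analysis windows
#'   (named list of `c(start, end)` half-open intervals, seconds).
#' @examples
#' epr_protocol()
#' @export
epr_protocol <- function(frame_rate = 10) {
  stopifnot(frame_rate > 0)
  structure(
    list(
      background_dur = 30, pulse_dur = 1, interpulse_dark = 9, post_dur = 10,
      assay_length = 51,
      pulse_times = c(30, 40),
      windows = list(background = c(21, 30),
                     excitatory = c(31, 39),
                     refractory = c(41, 48)),
      frame_rate = frame_rate
    ),
    class = "epr_protocol"
  )
}

#' Larval photomotor response protocol
#'
#' The 24-min assay: four sequential cycles of 3 min visible light followed by
#' 3 min infrared darkness, movement sampled every 40 ms and integrated into
#' 6-s bins. The first cycle is acclimation and excluded from analysis. By
#' default the statistics use the third analyzed cycle (overall cycle 4); set
#' `analysis_cycle` to use another.
#'
#' @param analysis_cycle Overall cycle index (1-4) used for AUC statistics.
#' @return An `lpr_protocol` list.
#' @examples
#' lpr_protocol()
#' @export
lpr_protocol <- function(analysis_cycle = 4L) {
  n_cycles <- 4L
  light_dur <- 180
  dark_dur <- 180
  bin_width <- 6
  if (light_dur %% bin_width != 0 || dark_dur %% bin_width != 0) {
    validation_error("epoch durations must be divisible by bin_width")
  }
  if (analysis_cycle < 1L || analysis_cycle > n_cycles) {
    validation_error("analysis_cycle must be in 1..%d", n_cycles)
  }
  structure(
    list(n_cycles = n_cycles, light_dur = light_dur, dark_dur = dark_dur,
         bin_width = bin_width, sample_period = 0.04,
         acclimation_cycles = 1L, analysis_cycle = as.integer(analysis_cycle),
         assay_length = n_cycles * (light_dur + dark_dur)),
    class = "lpr_protocol"
  )
}

## Label a vector of bin start times with cycle index and light/dark epoch.
lpr_bin_labels <- function(bin_start_s, protocol = lpr_protocol()) {
  cycle_len <- protocol$light_dur + protocol$dark_dur
  cycle <- floor(bin_start_s / cycle_len) + 1L
  within <- bin_start_s - (cycle - 1L) * cycle_len
  epoch <- ifelse(within < protocol$light_dur, "light", "dark")
  list(cycle = as.integer(cycle), epoch = epoch)
}
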