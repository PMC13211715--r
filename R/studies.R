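## Self-contained simulation studies: parameter recovery, type-I error
## control, and DE calibration at the screen's standard design. These back
## the package's validation claims and are what the acceptance script runs.

#' Benchmark-concentration recovery study
#'
#' Simulates active chemicals at the standard plate design (7 concentrations,
#' n = 12 per concentration), runs the morphology stage end to end
#' (incidence, log-logistic fit, added-risk BMC), and compares each estimated
#' BMC with the generative truth's closed-form BMC on the log10 scale.
#'
#' @param n_chemicals Number of active chemicals to simulate.
#' @param seed Master integer seed.
#' @param catalog Endpoint catalog; defaults to a compact four-endpoint
#'   catalog (mortality at both stages plus two abnormalities), which keeps
#'   the study inexpensive without changing the per-endpoint estimation
#'   problem.
#' @param bmr Benchmark response.
#' @return Tibble, one row per active chemical x endpoint with an estimable
#'   BMC: `chemical_id, endpoint_id, bmc_true, bmc_est, log10_error`.
#' @export
study_bmc_recovery <- function(n_chemicals = 100, seed = 1,
                               catalog = NULL, bmr = 0.10) {
  catalog <- catalog %||% dplyr::filter(
    default_endpoint_catalog(),
    .data$endpoint_id %in% c("MO24", "MORT", "YSE", "AXIS"))
  purrr::map_dfr(seq_len(n_chemicals), function(i) {
    id <- sprintf("REC%04d", i)
    tr <- random_chemical_truth(id, seed, active = 1L, catalog = catalog)
    des <- screen_design(id, sprintf("P%04d", i))
    sim <- simulate_morphology(tr, des, seed, catalog)
    active <- tr$morphology[tr$morphology$active == 1, ]
    purrr::map_dfr(active$endpoint_id, function(ep) {
      tab <- suppressWarnings(incidence_table(sim$morphology, sim$plates,
                                              ep, catalog))
      fit <- tryCatch(fit_dose_response(tab), error = function(e) NULL)
      est <- if (!is.null(fit)) {
        tryCatch(bmc(fit, bmr), zebratox_bmc_error = function(e) NA_real_)
      } else NA_real_
      row <- active[active$endpoint_id == ep, ]
      q <- bmr / (1 - row$p0)
      truth <- row$ec50 * (q / (1 - q))^(1 / row$h)
      tibble(chemical_id = id, endpoint_id = ep,
             bmc_true = truth, bmc_est = est,
             log10_error = abs(log10(est) - log10(truth)))
    })
  }) %>%
    filter(!is.na(.data$bmc_est))
}

#' Type-I error study for the three hit-calling stages
#'
#' Simulates null chemicals (flat dose-response, unit behavioral effect
#' curves) at the standard design and measures the observed false-positive
#' rates of (i) the EPR compound KS + peak rule per interval, (ii) the LPR
#' KS + relative-AUC rule, and (iii) the family-wise Fisher morphology flags
#' (fraction of chemicals with any significant concentration on the
#' consolidated Any Effect endpoint).
#'
#' @param n_chemicals Number of null chemicals.
#' @param seed Master integer seed.
#' @param thresholds A [hit_thresholds()].
#' @param frame_rate EPR camera rate used for the simulated traces
#'   (frames/s).
#' @return List: `epr_rate`, `lpr_rate`, `fisher_rate`, plus the raw
#'   numerator/denominator counts.
#' @export
study_null_hit_rates <- function(n_chemicals = 500, seed = 1,
                                 thresholds = hit_thresholds(),
                                 frame_rate = 5) {
  proto <- epr_protocol(frame_rate = frame_rate)
  cat_full <- default_endpoint_catalog()
  cat_aug <- augment_catalog_any_effect(cat_full)
  epr_hit <- 0L; epr_n <- 0L
  lpr_hit <- 0L; lpr_n <- 0L
  fisher_hit <- 0L; fisher_n <- 0L
  for (i in seq_len(n_chemicals)) {
    id <- sprintf("NULL%04d", i)
    tr <- random_chemical_truth(id, seed, active = 0L, catalog = cat_full)
    des <- screen_design(id, sprintf("P%04d", i))
    sim <- simulate_morphology(tr, des, seed, cat_full)
    he <- epr_hits(simulate_epr(tr, des, proto, seed), sim$plates,
                   thresholds, proto)
    epr_hit <- epr_hit + sum(he$active, na.rm = TRUE)
    epr_n <- epr_n + sum(!he$untestable)
    hl <- suppressMessages(suppressWarnings(
      lpr_hits(simulate_lpr(tr, des, seed = seed), sim$plates, thresholds)))
    lpr_hit <- lpr_hit + sum(hl$active, na.rm = TRUE)
    lpr_n <- lpr_n + sum(!hl$untestable)
    tab <- suppressWarnings(incidence_table(
      add_any_effect(sim$morphology, cat_full), sim$plates,
      "ANY_EFFECT", cat_aug))
    ff <- fisher_activity(tab, thresholds)
    fisher_hit <- fisher_hit + as.integer(any(ff$significant, na.rm = TRUE))
    fisher_n <- fisher_n + 1L
  }
  list(epr_rate = epr_hit / epr_n, lpr_rate = lpr_hit / lpr_n,
       fisher_rate = fisher_hit / fisher_n,
       epr_hits = epr_hit, epr_tests = epr_n,
       lpr_hits = lpr_hit, lpr_tests = lpr_n,
       fisher_hits = fisher_hit, fisher_tests = fisher_n)
}

#' Calibration study for the differential-expression summary
#'
#' Two parts. Null: counts with no differential genes (4 treated vs 8 pooled
#' control replicates) are tested and the p-value distribution is checked
#' against Uniform(0, 1). Power: a block of genes gets an exact planted
#' 4-fold increase at low dispersion and the fraction recovered at raw
#' p < 0.05 is reported.
#'
#' @param n_genes Genes in the null simulation.
#' @param seed Master integer seed.
#' @param n_planted Genes carrying the planted 4-fold change.
#' @param dispersion NB dispersion for the power simulation.
#' @return List: `ks_p` (uniformity KS p-value on the null), `power`
#'   (fraction of planted genes with p < 0.05), `n_genes`, `n_planted`.
#' @export
study_de_calibration <- function(n_genes = 5000, seed = 1,
                                 n_planted = 300, dispersion = 0.01) {
  man <- build_manifest(1, 4, 8, exposure_ids = "EXPO")
  null_tr <- chemical_truth(
    "EXPO", morphology = tibble(endpoint_id = "M", p0 = 0, ec50 = 10, h = 2),
    de_fraction = 0)
  cs <- simulate_counts(null_tr, man, n_genes = n_genes, seed = seed)
  de0 <- de_test(cs$counts, man, "EXPO")
  p <- de0$p_value[!is.na(de0$p_value)]
  ks_p <- stats::ks.test(p, "punif")$p.value
  pow <- with_child_seed(seed, "de-power", {
    mu <- exp(runif(n_genes, log(50), log(500)))
    lfc <- c(rep(2, n_planted), rep(0, n_genes - n_planted))
    mat <- matrix(0L, n_genes, nrow(man),
                  dimnames = list(sprintf("pg%05d", seq_len(n_genes)),
                                  man$sample_id))
    for (j in seq_len(nrow(man))) {
      up <- if (man$is_control[j] == 1) 0 else lfc
      mat[, j] <- rnbinom(n_genes, mu = mu * 2^up, size = 1 / dispersion)
    }
    de1 <- de_test(mat, man, "EXPO")
    mean(de1$p_value[seq_len(n_planted)] < 0.05, na.rm = TRUE)
  })
  list(ks_p = ks_p, power = pow, n_genes = n_genes, n_planted = n_planted)
}
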