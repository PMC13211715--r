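## Morphology hit-calling and benchmark-concentration modeling.
##
## Incidence model: p(c) = p0 + (1 - p0) * c^h / (c^h + ec50^h), a
## three-parameter log-logistic with upper asymptote 1 fitted by binomial
## maximum likelihood. The benchmark concentration at added-risk benchmark
## response BMR solves p(BMC) - p0 = BMR, giving the closed form
## BMC = ec50 * (q / (1 - q))^(1/h) with q = BMR / (1 - p0).

#' "Any Effect" consolidation for one larva
#'
#' Logical OR over the non-mortality 120-hpf abnormality endpoints of a
#' single well; mortality is handled as its own endpoint and never feeds the
#' summary.
#'
#' @param well_records Tibble of morphology records for one well
#'   (`endpoint_id`, `value`).
#' @param catalog Endpoint catalog.
#' @return Integer 0/1: 1 iff one or more abnormalities are present.
#' @examples
#' recs <- tibble::tibble(endpoint_id = c("YSE", "AXIS"), value = c(0L, 1L))
#' cat <- dplyr::filter(default_endpoint_catalog(), endpoint_id %in% c("YSE", "AXIS"))
#' any_effect(recs, catalog = cat)
#' @export
any_effect <- function(well_records, catalog = default_endpoint_catalog()) {
  wanted <- catalog$endpoint_id[catalog$stage == "120hpf" & catalog$is_mortality == 0]
  missing <- setdiff(wanted, well_records$endpoint_id)
  if (length(missing) > 0) {
    validation_error("well is missing endpoint '%s' required for Any Effect",
                     missing[1])
  }
  vals <- well_records$value[well_records$endpoint_id %in% wanted]
  as.integer(any(vals == 1L))
}

#' Add "Any Effect" records to a morphology table
#'
#' Computes the per-well abnormality OR and appends it as a synthetic
#' endpoint `ANY_EFFECT` (stage 120hpf, non-mortality), returning the
#' augmented morphology table. Use [augment_catalog_any_effect()] for the
#' matching catalog row.
#'
#' @param morphology Validated morphology table.
#' @param catalog Endpoint catalog.
#' @return Morphology tibble with `ANY_EFFECT` rows appended.
#' @export
add_any_effect <- function(morphology, catalog = default_endpoint_catalog()) {
  wanted <- catalog$endpoint_id[catalog$stage == "120hpf" & catalog$is_mortality == 0]
  extra <- morphology %>%
    filter(.data$endpoint_id %in% wanted) %>%
    group_by(.data$plate_barcode, .data$well_id) %>%
    summarise(value = as.integer(any(.data$value == 1L)), .groups = "drop") %>%
    mutate(endpoint_id = "ANY_EFFECT")
  bind_rows(morphology, extra)
}

#' @rdname add_any_effect
#' @export
augment_catalog_any_effect <- function(catalog = default_endpoint_catalog()) {
  bind_rows(catalog,
            tibble(endpoint_id = "ANY_EFFECT", stage = "120hpf",
                   is_mortality = 0L))
}

#' Per-concentration incidence table for one endpoint
#'
#' Aggregates binary morphology records into (affected, scored) counts per
#' concentration. For non-mortality endpoints, wells dead at the endpoint's
#' scoring stage are excluded from the denominator (dead at 24 hpf for 24-hpf
#' endpoints; dead at 120 hpf for 120-hpf endpoints); mortality endpoints
#' count all wells.
#'
#' @param morphology Validated morphology table (may include `ANY_EFFECT`).
#' @param plates Validated plate table carrying the status flags.
#' @param endpoint One endpoint id.
#' @param catalog Endpoint catalog (augment with
#'   [augment_catalog_any_effect()] if scoring `ANY_EFFECT`).
#' @return Tibble `endpoint_id, concentration_uM, n_affected, n_scored`, one
#'   row per tested concentration including the 0-uM control. Concentrations
#'   with no scorable wells are retained with `n_scored = 0` and a warning.
#' @export
incidence_table <- function(morphology, plates, endpoint,
                            catalog = default_endpoint_catalog()) {
  ep <- catalog[catalog$endpoint_id == endpoint, ]
  if (nrow(ep) != 1) validation_error("endpoint '%s' not in catalog", endpoint)
  dead_col <- if (ep$stage == "24hpf") "dead_24h" else "dead_120h"
  scorable <- if (ep$is_mortality == 1) plates else plates[plates[[dead_col]] == 0L, ]
  recs <- morphology %>%
    filter(.data$endpoint_id == endpoint) %>%
    semi_join(scorable, by = c("plate_barcode", "well_id")) %>%
    left_join(plates[c("plate_barcode", "well_id", "concentration_uM")],
              by = c("plate_barcode", "well_id"))
  out <- tibble(concentration_uM = sort(unique(plates$concentration_uM))) %>%
    left_join(recs %>%
                group_by(.data$concentration_uM) %>%
                summarise(n_affected = sum(.data$value), n_scored = n(),
                          .groups = "drop"),
              by = "concentration_uM") %>%
    mutate(endpoint_id = endpoint,
           n_affected = dplyr::coalesce(.data$n_affected, 0L),
           n_scored = dplyr::coalesce(.data$n_scored, 0L)) %>%
    select("endpoint_id", "concentration_uM", "n_affected", "n_scored")
  if (any(out$n_scored == 0)) {
    warn(sprintf("endpoint %s: no scorable wells at concentration(s) %s",
                 endpoint,
                 paste(out$concentration_uM[out$n_scored == 0], collapse = ", ")))
  }
  out
}

check_incidence <- function(table) {
  assert_columns(table, c("concentration_uM", "n_affected", "n_scored"),
                 "incidence table")
  if (any(table$n_affected < 0 | table$n_affected > table$n_scored)) {
    validation_error("need 0 <= n_affected <= n_scored")
  }
  if (!any(table$concentration_uM == 0)) {
    validation_error("incidence table lacks a control (0 uM) row")
  }
  if (anyDuplicated(table$concentration_uM)) {
    validation_error("one row per concentration required")
  }
  invisible(table)
}

#' Lowest effect level by one-sided exact binomial test
#'
#' Tests each non-zero concentration's incidence against the control rate
#' with a one-sided exact binomial test and returns the lowest concentration
#' significant at `lel_alpha`. A control incidence of zero makes the exact
#' test degenerate, so the null rate is floored at `0.5 / n_control`
#' (configurable through `hit_thresholds(control_rate_floor_num = )`).
#'
#' @param table Incidence table (one endpoint).
#' @param thresholds A [hit_thresholds()].
#' @return Tibble with one row: `lel` (uM, `NA` if no concentration is
#'   significant) and the per-concentration p-values as a list column
#'   `tests`.
#' @export
binomial_lel <- function(table, thresholds = hit_thresholds()) {
  check_incidence(table)
  ctrl <- table[table$concentration_uM == 0, ]
  if (ctrl$n_scored == 0) validation_error("control row has no scored wells")
  p_null <- max(ctrl$n_affected / ctrl$n_scored,
                thresholds$control_rate_floor_num / ctrl$n_scored)
  treated <- table[table$concentration_uM > 0, ]
  tests <- treated %>%
    mutate(p_value = ifelse(
      .data$n_scored == 0, NA_real_,
      pbinom(.data$n_affected - 1L, .data$n_scored, p_null, lower.tail = FALSE)
    ))
  if (any(tests$n_scored == 0)) {
    warn("concentration(s) with no scored wells skipped in LEL scan")
  }
  sig <- tests$concentration_uM[!is.na(tests$p_value) &
                                  tests$p_value < thresholds$lel_alpha]
  tibble(endpoint_id = table$endpoint_id[1] %||% NA_character_,
         lel = if (length(sig) > 0) min(sig) else NA_real_,
         tests = list(tests))
}

#' Per-concentration Fisher activity flags with family-wise control
#'
#' One-sided Fisher's exact test of each treated concentration's 2x2 table
#' (affected/unaffected vs control), flagged significant at the
#' Bonferroni-split family-wise level `fisher_family_alpha / (number of
#' non-zero concentrations)`.
#'
#' @param table Incidence table (one endpoint).
#' @param thresholds A [hit_thresholds()].
#' @return Tibble `concentration_uM, n_affected, n_scored, p_value,
#'   significant` for the non-zero concentrations.
#' @export
fisher_activity <- function(table, thresholds = hit_thresholds()) {
  check_incidence(table)
  ctrl <- table[table$concentration_uM == 0, ]
  treated <- table[table$concentration_uM > 0, ]
  n_tests <- sum(treated$n_scored > 0)
  alpha <- if (n_tests > 0) thresholds$fisher_family_alpha / n_tests else NA_real_
  treated %>%
    mutate(
      p_value = purrr::map2_dbl(.data$n_affected, .data$n_scored, function(a, n) {
        if (n == 0) return(NA_real_)
        m <- matrix(c(a, n - a, ctrl$n_affected, ctrl$n_scored - ctrl$n_affected),
                    nrow = 2)
        fisher.test(m, alternative = "greater")$p.value
      }),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) %>%
    select("concentration_uM", "n_affected", "n_scored", "p_value", "significant")
}

## Negated binomial log-likelihood of the incidence model (constants dropped)
ll_loglogistic <- function(par, conc, affected, scored) {
  p0 <- stats::plogis(par[1])
  ec50 <- exp(par[2])
  h <- exp(par[3])
  p <- loglogistic_incidence(conc, p0, ec50, h)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(affected * log(p) + (scored - affected) * log(1 - p))
}

#' Fit the binomial log-logistic dose-response model
#'
#' Maximizes the binomial log-likelihood of
#' `p(c) = p0 + (1 - p0) c^h / (c^h + ec50^h)` over (logit p0, log ec50,
#' log h) with bounded quasi-Newton (L-BFGS-B) started from a fixed 3x3x3
#' grid, keeping the best converged optimum. Deterministic; invariant to row
#' order.
#'
#' @param table Incidence table with >= 3 distinct non-zero concentrations
#'   with scored wells.
#' @return A `dose_response_fit` object: list with `p0`, `ec50`, `h`,
#'   `loglik`, `converged`, `table`. See [tidy.dose_response_fit()].
#' @examples
#' tab <- tibble::tibble(endpoint_id = "ANY_EFFECT",
#'   concentration_uM = c(0, 0.1, 1, 10, 100),
#'   n_affected = c(0L, 1L, 3L, 9L, 12L), n_scored = 12L)
#' fit <- fit_dose_response(tab)
#' bmc(fit)
#' @export
fit_dose_response <- function(table) {
  check_incidence(table)
  use <- table[table$n_scored > 0, ]
  if (sum(use$concentration_uM > 0) < 3) {
    validation_error("need >= 3 non-zero concentrations with scored wells")
  }
  use <- arrange(use, .data$concentration_uM)
  conc <- use$concentration_uM
  nz <- conc[conc > 0]
  ## fixed multi-start grid on (logit p0, log ec50, log h)
  starts <- expand.grid(
    lp0 = stats::qlogis(c(0.01, 0.05, 0.2)),
    lec = log(c(min(nz), exp(mean(log(range(nz)))), max(nz))),
    lh = log(c(0.5, 1, 3))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(as.numeric(starts[i, ]), ll_loglogistic, method = "L-BFGS-B",
            lower = c(stats::qlogis(1e-6), log(min(nz)) - log(1e4), log(0.05)),
            upper = c(stats::qlogis(1 - 1e-6), log(max(nz)) + log(1e4), log(50)),
            conc = conc, affected = use$n_affected, scored = use$n_scored),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best)) {
    fit <- list(p0 = NA_real_, ec50 = NA_real_, h = NA_real_,
                loglik = NA_real_, converged = FALSE, table = use)
  } else {
    fit <- list(p0 = stats::plogis(best$par[1]),
                ec50 = exp(best$par[2]),
                h = exp(best$par[3]),
                loglik = -best$value,
                converged = best$convergence == 0,
                table = use)
  }
  structure(fit, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Binomial log-logistic dose-response fit\n")
  cat(sprintf("  p0 = %.4g  ec50 = %.4g uM  h = %.4g  loglik = %.3f  converged: %s\n",
              x$p0, x$ec50, x$h, x$loglik, x$converged))
  invisible(x)
}

#' Benchmark concentration at an added-risk benchmark response
#'
#' Solves `p(BMC) - p0 = bmr` on the fitted curve. Closed form:
#' `BMC = ec50 * (q / (1 - q))^(1/h)` with `q = bmr / (1 - p0)`; the result
#' is verified against a bisection root of the fitted curve to 1e-6 relative.
#'
#' @param fit A converged [fit_dose_response()] object, or a list with
#'   `p0`, `ec50`, `h`, `converged`.
#' @param bmr Benchmark response as added risk over background (default
#'   0.10, i.e. a BMD10).
#' @return BMC in uM.
#' @export
bmc <- function(fit, bmr = 0.10) {
  if (!isTRUE(fit$converged)) {
    abort("bmc() requires a converged dose-response fit",
          class = "zebratox_bmc_error")
  }
  if ((1 - fit$p0) <= bmr) {
    abort(sprintf("benchmark response unattainable: 1 - p0 = %.4g <= bmr = %.3g",
                  1 - fit$p0, bmr),
          class = "zebratox_bmc_error")
  }
  q <- bmr / (1 - fit$p0)
  closed <- fit$ec50 * (q / (1 - q))^(1 / fit$h)
  ## a fit carrying its incidence table (e.g. on null data where no finite
  ## potency is demanded) must reach the benchmark response near the tested
  ## range; far-extrapolated benchmarks are reported as unattainable
  if (!is.null(fit$table)) {
    max_c <- max(fit$table$concentration_uM)
    if (!is.finite(closed) || closed > 100 * max_c) {
      abort(sprintf(
        "benchmark response not attained within the tested range (BMC estimate %.3g uM)",
        closed), class = "zebratox_bmc_error")
    }
  }
  root <- bmc_bisection(fit, bmr)
  if (abs(closed - root) > 1e-6 * closed) {
    abort("closed-form BMC disagrees with numeric root; fit is pathological",
          class = "zebratox_bmc_error")
  }
  closed
}

## Independent numeric route: bisection on p(c) - p0 - bmr.
bmc_bisection <- function(fit, bmr, lower = NULL, upper = NULL, tol = 1e-12) {
  f <- function(c) loglogistic_incidence(c, fit$p0, fit$ec50, fit$h) - fit$p0 - bmr
  lo <- lower %||% (fit$ec50 * 1e-9)
  hi <- upper %||% (fit$ec50 * 1e9)
  uniroot(f, c(lo, hi), tol = tol * fit$ec50)$root
}

#' Benchmark concentration for a continuous behavioral response
#'
#' Converts per-animal continuous responses into a binary incidence by
#' classifying a treated animal as affected when its summary response falls
#' outside the control empirical \[2.5th, 97.5th\] percentile interval, then
#' reuses the binomial dose-response fit and added-risk BMC. Controls are
#' classified against their own interval, so the control row sits near the
#' nominal 5% background.
#'
#' @param responses Tibble `concentration_uM, response`, one row per animal,
#'   including the 0-uM controls (>= 8 control animals).
#' @param bmr Added-risk benchmark response.
#' @param probs Control percentile interval.
#' @return List: `bmc` (uM or `NA` when the benchmark response is
#'   unattainable or the fit does not converge), `fit`, `incidence`.
#' @export
behavioral_bmc <- function(responses, bmr = 0.10, probs = c(0.025, 0.975)) {
  assert_columns(responses, c("concentration_uM", "response"), "responses")
  ctrl <- responses$response[responses$concentration_uM == 0]
  if (length(ctrl) < 8) validation_error("need >= 8 control animals")
  lims <- quantile(ctrl, probs = probs, names = FALSE, type = 7)
  inc <- responses %>%
    mutate(affected = .data$response < lims[1] | .data$response > lims[2]) %>%
    group_by(.data$concentration_uM) %>%
    summarise(n_affected = sum(.data$affected), n_scored = n(),
              .groups = "drop") %>%
    mutate(endpoint_id = "behavior") %>%
    select("endpoint_id", "concentration_uM", "n_affected", "n_scored")
  fit <- fit_dose_response(inc)
  est <- tryCatch(bmc(fit, bmr = bmr), zebratox_bmc_error = function(e) NA_real_)
  list(bmc = est, fit = fit, incidence = inc)
}

#' Morphology hit table for a screen
#'
#' Runs the full morphology stage per chemical x endpoint: incidence
#' aggregation (including the consolidated `ANY_EFFECT` endpoint), binomial
#' LEL, family-wise Fisher flags, the binomial log-logistic fit, and the
#' added-risk BMC.
#'
#' @param morphology Validated morphology table.
#' @param plates Validated plate table.
#' @param catalog Endpoint catalog.
#' @param thresholds A [hit_thresholds()].
#' @param endpoints Endpoints to score (default: all in catalog plus
#'   `ANY_EFFECT`).
#' @return Tibble, one row per chemical x endpoint: `lel`, `bmc`, `p0`,
#'   `ec50`, `h`, `converged`, `n_significant` (Fisher flag count),
#'   `any_fisher_hit`.
#' @export
morphology_hits <- function(morphology, plates,
                            catalog = default_endpoint_catalog(),
                            thresholds = hit_thresholds(),
                            endpoints = NULL) {
  catalog2 <- augment_catalog_any_effect(catalog)
  morph2 <- add_any_effect(morphology, catalog)
  endpoints <- endpoints %||% catalog2$endpoint_id
  combos <- tidyr::expand_grid(chemical_id = unique(plates$chemical_id),
                               endpoint_id = endpoints)
  purrr::pmap_dfr(combos, function(chemical_id, endpoint_id) {
    pl <- plates[plates$chemical_id == chemical_id, ]
    mo <- semi_join(morph2, pl, by = c("plate_barcode", "well_id"))
    tab <- suppressWarnings(incidence_table(mo, pl, endpoint_id, catalog2))
    lel <- binomial_lel(tab, thresholds)$lel
    fish <- fisher_activity(tab, thresholds)
    fit <- tryCatch(fit_dose_response(tab), error = function(e) NULL)
    est <- if (!is.null(fit)) {
      tryCatch(bmc(fit, bmr = thresholds$bmr),
               zebratox_bmc_error = function(e) NA_real_)
    } else NA_real_
    tibble(chemical_id = chemical_id, endpoint_id = endpoint_id,
           lel = lel, bmc = est,
           p0 = fit$p0 %||% NA_real_, ec50 = fit$ec50 %||% NA_real_,
           h = fit$h %||% NA_real_,
           converged = isTRUE(fit$converged),
           n_significant = sum(fish$significant, na.rm = TRUE),
           any_fisher_hit = any(fish$significant, na.rm = TRUE))
  })
}
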