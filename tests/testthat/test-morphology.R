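abn_catalog <- function() {
  dplyr::filter(default_endpoint_catalog(),
                stage == "120hpf" & is_mortality == 0)
}

test_that("Any Effect is the OR over 120-hpf abnormality endpoints", {
  cat1 <- abn_catalog()
  recs <- tibble::tibble(endpoint_id = cat1$endpoint_id, value = 0L)
  full_cat <- default_endpoint_catalog()
  expect_equal(any_effect(recs, full_cat), 0L)
  recs$value[4] <- 1L
  expect_equal(any_effect(recs, full_cat), 1L)
  recs$value <- 1L
  expect_equal(any_effect(recs, full_cat), 1L)
  expect_error(any_effect(recs[-1, ], full_cat), "missing endpoint")
})

test_that("incidence aggregation counts and exclusion rules", {
  # hand-built 2-concentration plate: 12 wells each, 2 dead at 10 uM
  plates <- tibble::tibble(
    plate_barcode = "P1", well_id = well_ids(c("A", "B"), 1:12),
    chemical_id = "X",
    concentration_uM = rep(c(0, 10), each = 12),
    dead_24h = 0L,
    dead_120h = rep(c(0L, 1L), c(22, 2)),
    malformed_120h = 0L)
  # YSE (non-mortality): 3 affected among the 10 live wells at 10 uM
  morph <- tibble::tibble(
    plate_barcode = "P1", well_id = plates$well_id,
    endpoint_id = "YSE",
    value = c(rep(0L, 12), rep(1L, 3), rep(0L, 9)))
  tab <- incidence_table(morph, plates, "YSE")
  expect_equal(tab$n_scored, c(12L, 10L))
  expect_equal(tab$n_affected, c(0L, 3L))
  # mortality endpoint counts every well
  mort <- tibble::tibble(
    plate_barcode = "P1", well_id = plates$well_id, endpoint_id = "MORT",
    value = plates$dead_120h)
  tabm <- incidence_table(mort, plates, "MORT")
  expect_equal(tabm$n_scored, c(12L, 12L))
  expect_equal(tabm$n_affected, c(0L, 2L))
})

test_that("binomial LEL matches exact tail computations", {
  base <- tibble::tibble(endpoint_id = "YSE",
                         concentration_uM = c(0, 0.01, 0.1, 1, 10, 50, 100),
                         n_affected = 0L, n_scored = 12L)
  expect_true(is.na(binomial_lel(base)$lel))

  # control 0/12 -> null rate floored at 0.5/12; treated 12/12 at 100 only
  hit <- base
  hit$n_affected[hit$concentration_uM == 100] <- 12L
  res <- binomial_lel(hit)
  expect_equal(res$lel, 100)
  p100 <- res$tests[[1]]$p_value[res$tests[[1]]$concentration_uM == 100]
  expect_equal(p100, (0.5 / 12)^12, tolerance = 1e-12)

  # a single affected well is not significant: P(K >= 1) ~ 0.400
  weak <- base
  weak$n_affected[weak$concentration_uM == 100] <- 1L
  resw <- binomial_lel(weak)
  expect_true(is.na(resw$lel))
  pw <- resw$tests[[1]]$p_value[resw$tests[[1]]$concentration_uM == 100]
  expect_equal(pw, 1 - (1 - 0.5 / 12)^12, tolerance = 1e-12)
})

test_that("LEL, when defined, is a tested concentration above zero", {
  for (seed in c(3, 17, 88)) {
    b <- make_test_bundle(seed, active = 1L)
    m2 <- add_any_effect(b$morphology)
    tab <- suppressWarnings(
      incidence_table(m2, b$plates, "ANY_EFFECT", augment_catalog_any_effect()))
    lel <- suppressWarnings(binomial_lel(tab))$lel
    if (!is.na(lel)) {
      nz <- tab$concentration_uM[tab$concentration_uM > 0]
      expect_true(lel %in% nz)
      expect_gte(lel, min(nz))
    }
  }
})

test_that("Fisher flags match exhaustive hypergeometric enumeration", {
  tab <- tibble::tibble(endpoint_id = "YSE",
                        concentration_uM = c(0, 1, 10, 50, 100, 0.1, 0.01),
                        n_affected = c(0L, 0L, 6L, 12L, 12L, 0L, 0L),
                        n_scored = 12L)
  res <- fisher_activity(tab)
  expect_equal(res$p_value[res$concentration_uM == 100], 1 / choose(24, 12),
               tolerance = 1e-12)
  expect_true(res$significant[res$concentration_uM == 100])
  expect_false(res$significant[res$concentration_uM == 1])
  # equality with the enumeration oracle over all treated rows
  for (i in seq_len(nrow(res))) {
    a <- res$n_affected[i]
    expect_equal(res$p_value[i], oracle_fisher_p(a, 12, 0, 12),
                 tolerance = 1e-12)
  }
  # equal proportions are never significant (upper tail covers the observed
  # count, so p is large)
  eq <- tibble::tibble(endpoint_id = "YSE", concentration_uM = c(0, 10),
                       n_affected = c(3L, 3L), n_scored = 12L)
  expect_gt(fisher_activity(eq)$p_value, 0.5)
  expect_false(fisher_activity(eq)$significant)
  eq0 <- tibble::tibble(endpoint_id = "YSE", concentration_uM = c(0, 10),
                        n_affected = c(0L, 0L), n_scored = 12L)
  expect_equal(fisher_activity(eq0)$p_value, 1)
})

test_that("Fisher p equals the enumeration oracle across random small tables", {
  set.seed(404)
  for (rep in 1:60) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    tab <- tibble::tibble(endpoint_id = "E",
                          concentration_uM = c(0, 10),
                          n_affected = c(b, a), n_scored = c(n2, n1))
    p <- fisher_activity(tab)$p_value
    expect_equal(p, oracle_fisher_p(a, n1, b, n2), tolerance = 1e-12)
  }
})

test_that("dose-response fit recovers parameters from exact proportions", {
  conc <- c(0, 0.01, 0.1, 1, 3, 10, 30, 100)
  n <- 100000L
  p <- zebratox:::loglogistic_incidence(conc, 0, 10, 1)
  tab <- tibble::tibble(endpoint_id = "E", concentration_uM = conc,
                        n_affected = as.integer(round(p * n)), n_scored = n)
  fit <- fit_dose_response(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 / 10 - 1), 0.01)
  expect_lt(abs(fit$h / 1 - 1), 0.01)
  # row permutation leaves the fit unchanged
  fit2 <- fit_dose_response(tab[sample(nrow(tab)), ])
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-9)
  expect_equal(fit$ec50, fit2$ec50, tolerance = 1e-6)
})

test_that("all-zero incidence drives the background estimate to zero", {
  tab <- tibble::tibble(endpoint_id = "E",
                        concentration_uM = c(0, 0.1, 1, 10, 100),
                        n_affected = 0L, n_scored = 12L)
  fit <- fit_dose_response(tab)
  expect_lt(fit$p0, 1e-4)
  expect_error(bmc(fit), class = "zebratox_bmc_error")
})

test_that("closed-form BMC matches worked values and the bisection route", {
  f1 <- list(p0 = 0, ec50 = 10, h = 1, converged = TRUE)
  expect_equal(bmc(f1, 0.10), 10 * (0.1 / 0.9), tolerance = 1e-9)
  f2 <- list(p0 = 0.05, ec50 = 5, h = 2, converged = TRUE)
  q <- 0.10 / 0.95
  expect_equal(bmc(f2, 0.10), 5 * sqrt(q / (1 - q)), tolerance = 1e-9)
  # step-function limit: BMC -> ec50 as h grows
  f3 <- list(p0 = 0, ec50 = 7, h = 1000, converged = TRUE)
  expect_equal(bmc(f3, 0.10), 7, tolerance = 0.01)
  # error branches
  expect_error(bmc(list(p0 = 0.95, ec50 = 1, h = 1, converged = TRUE)),
               "unattainable")
  expect_error(bmc(list(p0 = 0, ec50 = 1, h = 1, converged = FALSE)),
               "converged")
})

test_that("closed-form BMC equals bisection within 1e-6 relative, and is monotone", {
  set.seed(11)
  for (rep in 1:200) {
    p0 <- runif(1, 0, 0.5); ec50 <- 10^runif(1, -2, 2); h <- runif(1, 0.3, 6)
    fit <- list(p0 = p0, ec50 = ec50, h = h, converged = TRUE)
    closed <- bmc(fit, 0.10)
    root <- zebratox:::bmc_bisection(fit, 0.10)
    expect_lt(abs(closed - root) / closed, 1e-6)
    # strictly increasing in ec50 and in bmr (a larger benchmark response
    # requires a larger concentration on a monotone increasing curve)
    up <- bmc(list(p0 = p0, ec50 = ec50 * 2, h = h, converged = TRUE), 0.10)
    expect_gt(up, closed)
    expect_gt(bmc(fit, 0.20), closed)
    expect_lt(bmc(fit, 0.05), closed)
  }
})

test_that("behavioral BMC percentile rule behaves at the null and at saturation", {
  set.seed(21)
  null_resp <- tibble::tibble(
    concentration_uM = rep(c(0, 0.01, 0.1, 1, 10, 50, 100), each = 12),
    response = rnorm(84))
  res <- behavioral_bmc(null_resp)
  # ~5% affected everywhere: the 10% added-risk response is rarely attainable
  expect_true(is.na(res$bmc) || res$bmc > 10)
  # saturated top concentration: all responses above the control maximum
  sat <- null_resp
  sat$response[sat$concentration_uM >= 50] <-
    max(null_resp$response[null_resp$concentration_uM == 0]) + 5
  res2 <- behavioral_bmc(sat)
  expect_true(is.finite(res2$bmc))
  top <- res2$incidence[res2$incidence$concentration_uM == 100, ]
  expect_equal(top$n_affected, top$n_scored)
  # deterministic on fixed input
  expect_identical(res2$bmc, behavioral_bmc(sat)$bmc)
  expect_error(behavioral_bmc(null_resp[null_resp$concentration_uM > 0, ]),
               "control")
})

test_that("screen-level morphology hit table is well-formed", {
  b <- make_test_bundle(55, active = 1L)
  hits <- morphology_hits(b$morphology, b$plates,
                          endpoints = c("MORT", "YSE", "ANY_EFFECT"))
  expect_equal(nrow(hits), 3)
  expect_true(all(is.na(hits$bmc) | hits$bmc > 0))
  expect_true(all(is.na(hits$lel) |
                    hits$lel %in% b$design$concentrations))
})
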