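flat_truth <- function(id = "X", p0 = 0, active = 0L,
                       catalog = default_endpoint_catalog()) {
  chemical_truth(id, morphology = tibble::tibble(
    endpoint_id = catalog$endpoint_id, p0 = p0, ec50 = 10, h = 2,
    active = active))
}

test_that("inactive truth with zero background yields all-zero records", {
  sim <- simulate_morphology(flat_truth(), screen_design("X", "P1"), seed = 5)
  expect_true(all(sim$morphology$value == 0L))
  expect_true(all(sim$plates$dead_24h == 0L))
  expect_true(all(sim$plates$malformed_120h == 0L))
})

test_that("a near-step dose-response separates incidence across its EC50", {
  cat1 <- default_endpoint_catalog()
  tr <- chemical_truth("X", morphology = tibble::tibble(
    endpoint_id = cat1$endpoint_id, p0 = 0, ec50 = 1, h = 40, active = 1L))
  des <- screen_design("X", "P1", concentrations = c(0, 0.1, 0.2, 0.5, 10),
                       n_per_concentration = 12)
  counts <- c(low = 0L, high = 0L, n = 0L)
  for (seed in 1:20) {
    sim <- simulate_morphology(tr, des, seed, cat1)
    recs <- dplyr::left_join(
      sim$morphology,
      sim$plates[c("plate_barcode", "well_id", "concentration_uM")],
      by = c("plate_barcode", "well_id"))
    counts["low"] <- counts["low"] + sum(recs$value[recs$concentration_uM == 0.1])
    counts["high"] <- counts["high"] + sum(recs$value[recs$concentration_uM == 10])
    counts["n"] <- counts["n"] + sum(recs$concentration_uM == 0.1)
  }
  expect_lt(counts[["low"]] / counts[["n"]], 0.01)
  expect_gt(counts[["high"]] / counts[["n"]], 0.99)
})

test_that("generators are deterministic and chemicals have independent streams", {
  des <- screen_design("A", "P1")
  tr <- random_chemical_truth("A", 42, active = 1L)
  expect_identical(simulate_morphology(tr, des, 42),
                   simulate_morphology(tr, des, 42))
  expect_identical(simulate_epr(tr, des, seed = 42),
                   simulate_epr(tr, des, seed = 42))
  expect_identical(simulate_lpr(tr, des, seed = 42),
                   simulate_lpr(tr, des, seed = 42))
  s2 <- simulate_screen(c("A", "B"), seed = 42, with_behavior = FALSE)
  s3 <- simulate_screen(c("A", "B", "C"), seed = 42, with_behavior = FALSE)
  expect_identical(
    dplyr::filter(s2$morphology, plate_barcode == "P0001"),
    dplyr::filter(s3$morphology, plate_barcode == "P0001"))
})

test_that("null behavioral effects leave treated arms identical in law", {
  # with eff_max = 1 the effect curve is flat, so a treated well's generative
  # parameters equal a control's; check the curve itself and a moment match
  eff <- list(eff_max = 1, ec50 = 5, h = 2)
  expect_equal(zebratox:::effect_curve(c(0, 0.1, 10, 100), eff), rep(1, 4))
  tr <- flat_truth()
  bins <- simulate_lpr(tr, screen_design("X", "P1"), seed = 9)
  pl <- simulate_morphology(tr, screen_design("X", "P1"), seed = 9)$plates
  aucs <- cycle_auc(bins) %>%
    dplyr::left_join(pl[c("plate_barcode", "well_id", "concentration_uM")],
                     by = c("plate_barcode", "well_id"))
  m <- tapply(aucs$auc, aucs$concentration_uM > 0, mean)
  expect_lt(abs(m[["TRUE"]] / m[["FALSE"]] - 1), 0.15)
})

test_that("full suppression at the top concentration removes the excitation burst", {
  tr0 <- flat_truth("X")
  tr0$epr_effect <- list(eff_max = 0, ec50 = 0.001, h = 4)
  des <- screen_design("X", "P1")
  fr <- simulate_epr(tr0, des, seed = 3)
  pl <- simulate_morphology(tr0, des, seed = 3)$plates
  ss <- summarize_intervals(fr) %>%
    dplyr::left_join(pl[c("plate_barcode", "well_id", "concentration_uM")],
                     by = c("plate_barcode", "well_id"))
  top <- ss[ss$concentration_uM == 100, ]
  # excitatory means collapse to baseline means when the burst is suppressed
  expect_lt(abs(mean(top$E) - mean(top$B)), 0.15)
  ctrl <- ss[ss$concentration_uM == 0, ]
  expect_gt(mean(ctrl$E), mean(ctrl$B) + 0.5)
})

test_that("zero-noise LPR bins equal their expected epoch rates exactly", {
  bins <- simulate_lpr(flat_truth(), screen_design("X", "P1"), seed = 1,
                       light_mean = 4, dark_mean = 12, noise_cv = 0)
  lab <- zebratox:::lpr_bin_labels(bins$bin_start_s)
  expect_true(all(bins$distance[lab$epoch == "light"] == 4))
  expect_true(all(bins$distance[lab$epoch == "dark"] == 12))
})

test_that("a 3x activity multiplier yields mean relative AUC change near 2", {
  tr <- flat_truth("X")
  tr$lpr_effect <- list(eff_max = 3, ec50 = 0.001, h = 4)
  rels <- vapply(1:30, function(seed) {
    des <- screen_design("X", "P1")
    bins <- simulate_lpr(tr, des, seed = seed)
    pl <- tibble::tibble(plate_barcode = "P1",
                         well_id = unique(bins$well_id),
                         concentration_uM = rep(des$concentrations, each = 12))
    aucs <- cycle_auc(bins) %>%
      dplyr::left_join(pl, by = c("plate_barcode", "well_id"))
    ctrl <- mean(aucs$auc[aucs$concentration_uM == 0])
    (mean(aucs$auc[aucs$concentration_uM == 100]) - ctrl) / ctrl
  }, 0)
  expect_lt(abs(mean(rels) - 2), 0.1)
})

test_that("count generator plants the stated fraction of differential genes", {
  man <- build_manifest(1, 4, 8, exposure_ids = "A")
  tr <- flat_truth("A")
  tr$de_fraction <- 0.1
  cs <- simulate_counts(tr, man, n_genes = 4000, seed = 8)
  expect_equal(dim(zebratox:::as_count_matrix(cs$counts)), c(4000L, 12L))
  frac <- mean(cs$labels$is_de)
  expect_lt(abs(frac - 0.1), 0.02)
  expect_true(all(cs$labels$true_lfc[cs$labels$is_de == 0] == 0))
  cs2 <- simulate_counts(tr, man, n_genes = 4000, seed = 8)
  expect_identical(cs$counts, cs2$counts)
})

test_that("physicochemical generator stays in range and is reproducible", {
  pc <- simulate_physchem(c("A", "B", "C"), seed = 4)
  expect_true(all(pc$structures$position %in% biphenyl_positions()))
  expect_false(anyNA(pc$descriptors))
  expect_identical(pc, simulate_physchem(c("A", "B", "C"), seed = 4))
})
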