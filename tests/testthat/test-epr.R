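# Constant-index frame series builder: values per window, one embryo per well.
const_frames <- function(well_id, b = 1, e = 1, r = 1, base = 1,
                         frame_rate = 10) {
  times <- seq(0, 51 - 1 / frame_rate, by = 1 / frame_rate)
  w <- epr_protocol()$windows
  mi <- rep(base, length(times))
  mi[times >= w$background[1] & times < w$background[2]] <- b
  mi[times >= w$excitatory[1] & times < w$excitatory[2]] <- e
  mi[times >= w$refractory[1] & times < w$refractory[2]] <- r
  tibble::tibble(plate_barcode = "P1", well_id = well_id,
                 time_s = times, movement_index = mi)
}

two_conc_plate <- function(n = 12) {
  tibble::tibble(
    plate_barcode = "P1", well_id = well_ids(c("A", "B"), seq_len(n)),
    chemical_id = "X", concentration_uM = rep(c(0, 100), each = n),
    dead_24h = 0L, dead_120h = 0L, malformed_120h = 0L)
}

test_that("movement index: identity, arithmetic, scale invariance, shape check", {
  a <- matrix(1, 3, 3)
  expect_equal(movement_index(a, a), 0)
  expect_equal(movement_index(matrix(2, 3, 3), a), 1, tolerance = 1e-8)
  x <- matrix(runif(9), 3); y <- matrix(runif(9), 3)
  expect_equal(movement_index(2 * x, 2 * y), movement_index(x, y),
               tolerance = 1e-8)
  expect_error(movement_index(matrix(1, 2, 2), a), "shape")
})

test_that("interval summaries use half-open windows", {
  fr <- const_frames("A01", b = 1, e = 3, r = 0.5)
  s <- summarize_intervals(fr)
  expect_equal(c(s$B, s$E, s$R), c(1, 3, 0.5))
  # a frame exactly at t = 30 belongs to the pulse phase, not background
  fr2 <- tibble::tibble(plate_barcode = "P1", well_id = "A01",
                        time_s = c(21, 25, 30, 31, 35, 41, 45),
                        movement_index = c(1, 1, 99, 2, 2, 3, 3))
  s2 <- summarize_intervals(fr2)
  expect_equal(s2$B, 1)   # the t = 30 frame is excluded
  expect_equal(s2$E, 2)
  expect_equal(s2$R, 3)
  # constant series
  s3 <- summarize_intervals(const_frames("A01", 2, 2, 2, base = 2))
  expect_equal(c(s3$B, s3$E, s3$R), c(2, 2, 2))
  # missing window errors with the window name
  short <- fr[fr$time_s < 40, ]
  expect_error(summarize_intervals(short), "refractory")
})

test_that("KS statistic matches hand-derived and oracle values", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  set.seed(77)
  for (rep in 1:100) {
    nx <- sample(1:10, 1); ny <- sample(1:10, 1)
    x <- round(rnorm(nx), 1); y <- round(rnorm(ny), 1)  # force ties sometimes
    ks <- ks_two_sample(x, y)
    expect_equal(ks$statistic, oracle_ks_d(x, y), tolerance = 1e-12)
  }
})

test_that("KS asymptotic p agrees with the reference implementation", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12, 1)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("EPR hit rule: null arms inactive, constructed separation active", {
  plates <- two_conc_plate()
  # treated identical to control -> D = 0, peak diff 0 -> inactive
  fr <- dplyr::bind_rows(lapply(plates$well_id, const_frames))
  h <- epr_hits(fr, plates)
  expect_true(all(!h$active))
  expect_true(all(h$D == 0))
  # treated excitatory means far above control (disjoint samples, n = 12 v 12)
  fr2 <- dplyr::bind_rows(
    lapply(plates$well_id[1:12], function(w) const_frames(w, e = 2)),
    lapply(plates$well_id[13:24], function(w) const_frames(w, e = 8)))
  h2 <- epr_hits(fr2, plates)
  exc <- h2[h2$interval == "excitatory", ]
  expect_equal(exc$D, 1)
  expect_lt(exc$p_value, hit_thresholds()$epr_alpha)
  expect_equal(exc$peak_ratio, 3)   # |8 - 2| / 2
  expect_true(exc$active)
  expect_false(any(h2$active[h2$interval != "excitatory"]))
})

test_that("a 50% peak difference sits exactly at the threshold", {
  plates <- two_conc_plate()
  fr <- dplyr::bind_rows(
    lapply(plates$well_id[1:12], function(w) const_frames(w, e = 2)),
    lapply(plates$well_id[13:24], function(w) const_frames(w, e = 3)))
  h <- epr_hits(fr, plates)
  exc <- h[h$interval == "excitatory", ]
  expect_equal(exc$peak_ratio, 0.5)
  expect_true(exc$p_value < hit_thresholds()$epr_alpha)  # disjoint samples
  expect_true(exc$active)                                 # >= is inclusive
})

test_that("arms below 3 animals are untestable, not inactive", {
  plates <- two_conc_plate(n = 2)
  fr <- dplyr::bind_rows(lapply(plates$well_id, const_frames))
  h <- epr_hits(fr, plates)
  expect_true(all(h$untestable))
  expect_true(all(is.na(h$active)))
})

test_that("hit calls are invariant to common rescaling and animal order", {
  set.seed(31)
  plates <- two_conc_plate()
  tr <- random_chemical_truth("X", 13, active = 1L)
  des <- screen_design("X", "P1", concentrations = c(0, 100),
                       n_per_concentration = 12)
  fr <- simulate_epr(tr, des, seed = 13)
  h1 <- epr_hits(fr, plates)
  fr_scaled <- dplyr::mutate(fr, movement_index = movement_index * 7.3)
  h2 <- epr_hits(fr_scaled, plates)
  expect_equal(h1$active, h2$active)
  expect_equal(h1$D, h2$D, tolerance = 1e-12)
  expect_equal(h1$peak_ratio, h2$peak_ratio, tolerance = 1e-9)
  fr_shuffled <- fr[sample(nrow(fr)), ] %>%
    dplyr::arrange(well_id, time_s)   # per-well time order is an invariant
  h3 <- epr_hits(fr_shuffled, plates)
  expect_equal(h1$active, h3$active)
})

test_that("excluded dead-at-24h embryos do not enter the EPR comparison", {
  plates <- two_conc_plate()
  plates$dead_24h[13:22] <- 1L
  plates$dead_120h[13:22] <- 1L
  fr <- dplyr::bind_rows(lapply(plates$well_id, const_frames))
  h <- epr_hits(fr, plates)
  expect_true(all(h$n_treated == 2))
  expect_true(all(h$untestable))
})
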