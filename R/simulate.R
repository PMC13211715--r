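## Synthetic screen generator with known ground truth.
##
## One master seed threads hierarchically: each (chemical, assay) pair gets its
## own deterministic child stream, so adding a chemical to a simulated screen
## never perturbs the draws of the others.

#' Ground-truth parameters for one simulated chemical
#'
#' Holds the generative counterpart of every downstream estimate: a
#' log-logistic incidence model per morphology endpoint, Hill-shaped
#' multiplicative effect curves for the two behavioral assays, and the
#' differential-expression truth for the count generator.
#'
#' Behavioral effects are parameterized as
#' `eff(c) = 1 + (eff_max - 1) * c^h / (c^h + ec50^h)`, i.e. no effect at the
#' control and a plateau at `eff_max` (1 = null, 0 = full suppression,
#' 3 = three-fold excitation).
#'
#' @param chemical_id Chemical identifier.
#' @param morphology Tibble with columns `endpoint_id`, `p0` (background
#'   incidence in \[0,1)), `ec50` (uM, > 0), `h` (Hill slope, > 0), `active`
#'   (0/1; inactive endpoints stay at `p0` everywhere).
#' @param epr_effect,lpr_effect Lists `list(eff_max, ec50, h)` for the
#'   embryonic and larval photomotor effect curves.
#' @param de_fraction Fraction of genes truly differential under this
#'   exposure, in \[0,1\].
#' @param lfc_sd Standard deviation of true log2 fold-changes.
#' @return A `chemical_truth` object.
#' @examples
#' chemical_truth("CHEM1",
#'   morphology = tibble::tibble(endpoint_id = "MORT", p0 = 0.02,
#'                               ec50 = 10, h = 2, active = 1))
#' @export
chemical_truth <- function(chemical_id,
                           morphology,
                           epr_effect = list(eff_max = 1, ec50 = 10, h = 2),
                           lpr_effect = list(eff_max = 1, ec50 = 10, h = 2),
                           de_fraction = 0,
                           lfc_sd = 1) {
  morphology <- as_tibble(morphology)
  assert_columns(morphology, c("endpoint_id", "p0", "ec50", "h"),
                 "truth morphology table")
  if (!"active" %in% names(morphology)) morphology$active <- 1L
  if (any(morphology$p0 < 0 | morphology$p0 >= 1)) {
    validation_error("p0 must satisfy 0 <= p0 < 1")
  }
  if (any(morphology$ec50 <= 0) || any(morphology$h <= 0)) {
    validation_error("ec50 and h must be positive")
  }
  if (de_fraction < 0 || de_fraction > 1) {
    validation_error("de_fraction must lie in [0,1]")
  }
  structure(
    list(chemical_id = as.character(chemical_id), morphology = morphology,
         epr_effect = epr_effect, lpr_effect = lpr_effect,
         de_fraction = de_fraction, lfc_sd = lfc_sd),
    class = "chemical_truth"
  )
}

## Log-logistic incidence: p(c) = p0 + (1 - p0) c^h / (c^h + ec50^h), p(0)=p0.
## The Hill fraction is computed as plogis(h * (log c - log ec50)), which is
## overflow-safe for extreme slopes and concentrations.
loglogistic_incidence <- function(conc, p0, ec50, h) {
  frac <- ifelse(conc <= 0, 0,
                 stats::plogis(h * (log(pmax(conc, 1e-300)) - log(ec50))))
  p0 + (1 - p0) * frac
}

## Hill-shaped multiplicative effect curve, eff(0) = 1.
effect_curve <- function(conc, eff) {
  frac <- ifelse(conc <= 0, 0, conc^eff$h / (conc^eff$h + eff$ec50^eff$h))
  1 + (eff$eff_max - 1) * frac
}

#' Draw a random chemical truth
#'
#' Convenience generator for simulation studies. Active chemicals get a
#' morphology EC50 log-uniform within the tested concentration range, Hill
#' slopes around 1-3, and behavioral effect plateaus drawn away from 1; null
#' chemicals are flat everywhere (effect curves identically 1, `de_fraction`
#' 0), so any downstream hit is a false positive.
#'
#' @param chemical_id Chemical identifier (also seeds the child stream).
#' @param seed Master integer seed.
#' @param active 1 for an active chemical, 0 for a null chemical.
#' @param catalog Endpoint catalog to draw per-endpoint truths for.
#' @return A `chemical_truth`.
#' @export
random_chemical_truth <- function(chemical_id, seed, active = 1L,
                                  catalog = default_endpoint_catalog()) {
  with_child_seed(seed, paste0("truth/", chemical_id), {
    n <- nrow(catalog)
    morph <- tibble(
      endpoint_id = catalog$endpoint_id,
      p0 = runif(n, 0, 0.05),
      ec50 = 10^runif(n, log10(0.5), log10(60)),
      h = runif(n, 1, 3),
      active = if (active) rbinom(n, 1, 0.6) else 0L
    )
    ## guarantee at least one active endpoint for an active chemical
    if (active && sum(morph$active) == 0) morph$active[1] <- 1L
    behav <- function(direction) {
      if (!active) return(list(eff_max = 1, ec50 = 10, h = 2))
      list(eff_max = if (direction == "up") runif(1, 2.5, 4) else runif(1, 0, 0.3),
           ec50 = 10^runif(1, log10(0.5), log10(30)),
           h = runif(1, 1.5, 3))
    }
    chemical_truth(
      chemical_id,
      morphology = morph,
      epr_effect = behav(sample(c("up", "down"), 1)),
      lpr_effect = behav(sample(c("up", "down"), 1)),
      de_fraction = if (active) 0.05 else 0,
      lfc_sd = 1
    )
  })
}

#' Simulate morphology scoring for one plate
#'
#' Draws each endpoint Bernoulli per well with the truth's log-logistic
#' incidence; mortality endpoints also set the well status flags (`dead_24h`
#' implies `dead_120h`) and `malformed_120h` is the "Any Effect" OR over the
#' 120-hpf abnormality endpoints.
#'
#' @param truth A [chemical_truth()].
#' @param design A [screen_design()].
#' @param seed Master integer seed.
#' @param catalog Endpoint catalog.
#' @return List with tibbles `plates` (one row per well, status flags set) and
#'   `morphology` (one record per well x endpoint).
#' @export
simulate_morphology <- function(truth, design, seed,
                                catalog = default_endpoint_catalog()) {
  stopifnot(inherits(truth, "chemical_truth"), inherits(design, "screen_design"))
  validate_endpoint_catalog(catalog)
  concs <- design$concentrations
  rows <- LETTERS[seq_along(concs)]
  wells <- tibble(
    plate_barcode = design$plate_barcode,
    well_id = well_ids(rows, seq_len(design$n_per_concentration)),
    chemical_id = design$chemical_id,
    concentration_uM = rep(concs, each = design$n_per_concentration)
  )
  tr <- left_join(catalog["endpoint_id"], truth$morphology, by = "endpoint_id")
  if (anyNA(tr$p0)) {
    validation_error("truth lacks parameters for endpoint '%s'",
                     tr$endpoint_id[is.na(tr$p0)][1])
  }
  with_child_seed(seed, paste0("morph/", truth$chemical_id), {
    records <- tidyr::expand_grid(wells[c("plate_barcode", "well_id", "concentration_uM")],
                                  tr) %>%
      mutate(p = ifelse(.data$active == 1,
                        loglogistic_incidence(.data$concentration_uM, .data$p0,
                                              .data$ec50, .data$h),
                        .data$p0),
             value = rbinom(n(), 1L, .data$p)) %>%
      select("plate_barcode", "well_id", "endpoint_id", "value")
  })
  mort24 <- catalog$endpoint_id[catalog$is_mortality == 1 & catalog$stage == "24hpf"]
  mort120 <- catalog$endpoint_id[catalog$is_mortality == 1 & catalog$stage == "120hpf"]
  abn120 <- catalog$endpoint_id[catalog$is_mortality == 0 & catalog$stage == "120hpf"]
  flag_for <- function(ids) {
    records %>%
      filter(.data$endpoint_id %in% ids) %>%
      group_by(.data$plate_barcode, .data$well_id) %>%
      summarise(flag = as.integer(any(.data$value == 1L)), .groups = "drop")
  }
  plates <- wells %>%
    left_join(rename(flag_for(mort24), dead_24h = "flag"),
              by = c("plate_barcode", "well_id")) %>%
    left_join(rename(flag_for(mort120), d120 = "flag"),
              by = c("plate_barcode", "well_id")) %>%
    left_join(rename(flag_for(abn120), malformed_120h = "flag"),
              by = c("plate_barcode", "well_id")) %>%
    mutate(dead_24h = dplyr::coalesce(.data$dead_24h, 0L),
           dead_120h = pmax(.data$dead_24h, dplyr::coalesce(.data$d120, 0L)),
           malformed_120h = dplyr::coalesce(.data$malformed_120h, 0L)) %>%
    select(-"d120")
  list(plates = validate_plates(plates),
       morphology = validate_morphology(records, plates, catalog))
}

#' Simulate embryonic photomotor response traces
#'
#' Per embryo: a strictly positive lognormal baseline movement index at every
#' frame, plus an additive decaying-exponential burst after each light pulse.
#' The excitatory burst amplitude is scaled by the truth's `epr_effect` curve
#' at the well's concentration; the refractory (second-pulse) burst is an
#' attenuated copy, reflecting neural adaptation in controls.
#'
#' @param truth A [chemical_truth()].
#' @param design A [screen_design()].
#' @param protocol An [epr_protocol()].
#' @param seed Master integer seed.
#' @param baseline_mean,baseline_cv Lognormal baseline mean and coefficient of
#'   variation of the per-frame movement index.
#' @param burst_amp Control excitatory burst amplitude (movement-index units).
#' @param refractory_frac Refractory burst amplitude as a fraction of the
#'   excitatory one.
#' @param burst_tau Burst decay time constant (s).
#' @return Tibble `plate_barcode, well_id, time_s, movement_index` (long
#'   frame series, one row per frame per embryo).
#' @export
simulate_epr <- function(truth, design, protocol = epr_protocol(), seed = 1L,
                         baseline_mean = 0.5, baseline_cv = 0.6,
                         burst_amp = 3, refractory_frac = 0.35,
                         burst_tau = 2) {
  stopifnot(inherits(truth, "chemical_truth"), inherits(design, "screen_design"))
  concs <- design$concentrations
  n_w <- design$n_per_concentration
  times <- seq(0, protocol$assay_length - 1 / protocol$frame_rate,
               by = 1 / protocol$frame_rate)
  nt <- length(times)
  wells <- tibble(
    well_id = well_ids(LETTERS[seq_along(concs)], seq_len(n_w)),
    concentration_uM = rep(concs, each = n_w)
  )
  eff <- effect_curve(wells$concentration_uM, truth$epr_effect)
  sdlog <- sqrt(log(1 + baseline_cv^2))
  meanlog <- log(baseline_mean) - sdlog^2 / 2
  p1 <- protocol$pulse_times[1] + protocol$pulse_dur
  p2 <- protocol$pulse_times[2] + protocol$pulse_dur
  with_child_seed(seed, paste0("epr/", truth$chemical_id), {
    n_total <- nrow(wells) * nt
    base <- rlnorm(n_total, meanlog, sdlog)
    ## per-embryo amplitude heterogeneity
    amp_i <- burst_amp * rlnorm(nrow(wells), 0, 0.3) * eff
    tvec <- rep(times, times = nrow(wells))
    amp_vec <- rep(amp_i, each = nt)
    burst <- amp_vec * (ifelse(tvec >= p1, exp(-(tvec - p1) / burst_tau), 0) +
                          refractory_frac *
                            ifelse(tvec >= p2, exp(-(tvec - p2) / burst_tau), 0))
    tibble(
      plate_barcode = design$plate_barcode,
      well_id = rep(wells$well_id, each = nt),
      time_s = tvec,
      movement_index = base + burst
    )
  })
}

#' Simulate larval photomotor response bins
#'
#' Emits 6-s binned swim distances directly for the full four-cycle assay.
#' Controls alternate between a low light-epoch mean and a higher dark-epoch
#' mean; exposure multiplies both by the truth's `lpr_effect` curve at the
#' well's concentration. Noise is multiplicative lognormal with unit mean, so
#' `noise_cv = 0` yields bins exactly equal to the expected rates.
#'
#' @param truth A [chemical_truth()].
#' @param design A [screen_design()].
#' @param protocol An [lpr_protocol()].
#' @param seed Master integer seed.
#' @param light_mean,dark_mean Expected distance per 6-s bin in the light and
#'   dark epochs for controls (dark > light).
#' @param noise_cv Coefficient of variation of the multiplicative bin noise.
#' @return Tibble `plate_barcode, well_id, bin_start_s, distance`.
#' @export
simulate_lpr <- function(truth, design, protocol = lpr_protocol(), seed = 1L,
                         light_mean = 4, dark_mean = 12, noise_cv = 0.5) {
  stopifnot(inherits(truth, "chemical_truth"), inherits(design, "screen_design"))
  stopifnot(dark_mean > light_mean)
  concs <- design$concentrations
  n_w <- design$n_per_concentration
  bins <- seq(0, protocol$assay_length - protocol$bin_width,
              by = protocol$bin_width)
  lab <- lpr_bin_labels(bins, protocol)
  nb <- length(bins)
  wells <- tibble(
    well_id = well_ids(LETTERS[seq_along(concs)], seq_len(n_w)),
    concentration_uM = rep(concs, each = n_w)
  )
  eff <- effect_curve(wells$concentration_uM, truth$lpr_effect)
  epoch_mean <- ifelse(lab$epoch == "light", light_mean, dark_mean)
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_child_seed(seed, paste0("lpr/", truth$chemical_id), {
    mu <- rep(eff, each = nb) * rep(epoch_mean, times = nrow(wells))
    noise <- if (sdlog > 0) rlnorm(length(mu), -sdlog^2 / 2, sdlog) else 1
    tibble(
      plate_barcode = design$plate_barcode,
      well_id = rep(wells$well_id, each = nb),
      bin_start_s = rep(bins, times = nrow(wells)),
      distance = mu * noise
    )
  })
}

#' Simulate an RNA-seq count matrix with known differential genes
#'
#' Gene-wise negative binomial counts (variance mu + alpha mu^2) with
#' log-normal per-sample size factors. For each exposure in the manifest, a
#' `de_fraction` of genes receives a true log2 fold-change drawn
#' `Normal(0, lfc_sd)` relative to the control group; all other genes share
#' the control means.
#'
#' @param truths List of [chemical_truth()] objects whose `chemical_id`s match
#'   the manifest's non-control `exposure_id`s (supplying `de_fraction` and
#'   `lfc_sd`), or a single truth recycled for all exposures.
#' @param manifest Sample manifest from [build_manifest()].
#' @param n_genes Number of genes.
#' @param seed Master integer seed.
#' @param mean_range Range of baseline means (drawn log-uniform).
#' @param dispersion_range Range of gene-wise NB dispersions alpha (drawn
#'   log-uniform).
#' @param size_factor_sdlog Log-SD of the per-sample size factors.
#' @return List: `counts` (tibble, `gene_id` first column), `labels` (tibble
#'   `exposure_id, gene_id, true_lfc, is_de`), `size_factors` (named vector).
#' @export
simulate_counts <- function(truths, manifest, n_genes = 5000, seed = 1L,
                            mean_range = c(20, 500),
                            dispersion_range = c(0.01, 0.3),
                            size_factor_sdlog = 0.2) {
  manifest <- validate_manifest(manifest)
  stopifnot(n_genes >= 1)
  if (inherits(truths, "chemical_truth")) truths <- list(truths)
  truth_ids <- vapply(truths, function(t) t$chemical_id, "")
  exposures <- unique(manifest$exposure_id[manifest$is_control == 0])
  if (length(truths) == 1 && length(exposures) >= 1) {
    truths <- rep(truths, length(exposures))
    truth_ids <- exposures
  }
  missing <- setdiff(exposures, truth_ids)
  if (length(missing) > 0) {
    validation_error("no chemical_truth supplied for exposure '%s'", missing[1])
  }
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  with_child_seed(seed, "counts", {
    mu0 <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    alpha <- exp(runif(n_genes, log(dispersion_range[1]), log(dispersion_range[2])))
    sf <- rlnorm(nrow(manifest), 0, size_factor_sdlog)
    names(sf) <- manifest$sample_id
    labels <- purrr::map_dfr(exposures, function(ex) {
      tr <- truths[[match(ex, truth_ids)]]
      is_de <- rbinom(n_genes, 1L, tr$de_fraction)
      tibble(exposure_id = ex, gene_id = gene_id,
             true_lfc = ifelse(is_de == 1, rnorm(n_genes, 0, tr$lfc_sd), 0),
             is_de = is_de)
    })
    mat <- matrix(0L, n_genes, nrow(manifest),
                  dimnames = list(gene_id, manifest$sample_id))
    for (j in seq_len(nrow(manifest))) {
      ex <- manifest$exposure_id[j]
      lfc <- if (manifest$is_control[j] == 1) 0 else {
        labels$true_lfc[labels$exposure_id == ex]
      }
      mu <- mu0 * 2^lfc * sf[j]
      mat[, j] <- rnbinom(n_genes, mu = mu, size = 1 / alpha)
    }
    list(counts = as_count_tibble(mat), labels = labels, size_factors = sf)
  })
}

#' Simulate physicochemical descriptors and congener structures
#'
#' Draws plausible-range descriptor values (molecular weight, logP, logS,
#' density, polarizability, molar volume, surface tension) and random biphenyl
#' substitution patterns over the valid ring positions 2-6 and 2'-6'.
#'
#' @param chemical_ids Character vector of chemical identifiers.
#' @param seed Master integer seed.
#' @return List: `descriptors` (tibble, one row per chemical, no missing
#'   values) and `structures` (tibble `chemical_id, position, substituent`).
#' @export
simulate_physchem <- function(chemical_ids, seed = 1L) {
  positions <- biphenyl_positions()
  with_child_seed(seed, "physchem", {
    n <- length(chemical_ids)
    descriptors <- tibble(
      chemical_id = chemical_ids,
      mol_weight = runif(n, 150, 500),
      logP = runif(n, 4, 8),
      logS = runif(n, -9, -5),
      density = runif(n, 1.1, 1.6),
      polarizability = runif(n, 20, 45),
      molar_volume = runif(n, 150, 320),
      surface_tension = runif(n, 30, 60)
    )
    structures <- purrr::map_dfr(chemical_ids, function(id) {
      k <- sample(1:6, 1)
      pos <- sample(positions, k)
      tibble(chemical_id = id, position = pos,
             substituent = sample(c("Cl", "OH", "OCH3", "OSO3"), k,
                                  replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05)))
    })
    list(descriptors = descriptors, structures = structures)
  })
}

#' Simulate a full screen with ground truth
#'
#' Drives all generators for a set of chemicals at the standard plate design
#' and returns one bundle of tibbles ready for the downstream stages, plus a
#' flat ground-truth ledger. Child RNG streams are keyed by chemical id, so
#' the draws for any chemical are independent of which others are present.
#'
#' @param chemical_ids Chemicals to simulate (each gets one plate).
#' @param seed Master integer seed.
#' @param active 0/1 vector (recycled) marking which chemicals are active.
#' @param design_template Function `(chemical_id, plate_barcode)` returning a
#'   [screen_design()]; defaults to the standard 7-concentration, n = 12
#'   layout.
#' @param catalog Endpoint catalog.
#' @param epr_protocol,lpr_protocol Assay protocols.
#' @param with_behavior,with_counts Toggle the behavioral / transcriptomic
#'   generators (morphology is always generated).
#' @param n_genes,reps_per_exposure,n_controls Transcriptomic design.
#' @return Named list: `plates`, `morphology`, optionally `epr_frames`,
#'   `lpr_bins`, `manifest`, `counts`, `de_labels`, plus `truth` (ledger
#'   tibble) and `truths` (list of `chemical_truth` objects).
#' @export
simulate_screen <- function(chemical_ids, seed = 1L, active = 1L,
                            design_template = NULL,
                            catalog = default_endpoint_catalog(),
                            epr_protocol = zebratox::epr_protocol(),
                            lpr_protocol = zebratox::lpr_protocol(),
                            with_behavior = TRUE, with_counts = FALSE,
                            n_genes = 2000, reps_per_exposure = 4L,
                            n_controls = 8L) {
  active <- rep_len(as.integer(active), length(chemical_ids))
  if (is.null(design_template)) {
    design_template <- function(id, bc) screen_design(id, bc)
  }
  truths <- purrr::map2(chemical_ids, active,
                        ~ random_chemical_truth(.x, seed, active = .y,
                                                catalog = catalog))
  names(truths) <- chemical_ids
  plates <- list(); morph <- list(); epr <- list(); lpr <- list()
  for (i in seq_along(chemical_ids)) {
    des <- design_template(chemical_ids[i], sprintf("P%04d", i))
    sim <- simulate_morphology(truths[[i]], des, seed, catalog)
    plates[[i]] <- sim$plates
    morph[[i]] <- sim$morphology
    if (with_behavior) {
      epr[[i]] <- simulate_epr(truths[[i]], des, epr_protocol, seed)
      lpr[[i]] <- simulate_lpr(truths[[i]], des, lpr_protocol, seed)
    }
  }
  out <- list(plates = bind_rows(plates), morphology = bind_rows(morph))
  if (with_behavior) {
    out$epr_frames <- bind_rows(epr)
    out$lpr_bins <- bind_rows(lpr)
  }
  if (with_counts) {
    out$manifest <- build_manifest(length(chemical_ids), reps_per_exposure,
                                   n_controls, exposure_ids = chemical_ids)
    cs <- simulate_counts(truths, out$manifest, n_genes = n_genes, seed = seed)
    out$counts <- cs$counts
    out$de_labels <- cs$labels
  }
  out$truth <- purrr::map_dfr(truths, function(tr) {
    tr$morphology %>%
      mutate(chemical_id = tr$chemical_id,
             epr_eff_max = tr$epr_effect$eff_max,
             lpr_eff_max = tr$lpr_effect$eff_max,
             de_fraction = tr$de_fraction) %>%
      select("chemical_id", dplyr::everything())
  })
  out$truths <- truths
  out
}
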