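## Plate-table I/O and validation.
##
## All files are UTF-8 CSV with a header row. Canonical headers:
##   plates.csv     plate_barcode,well_id,chemical_id,concentration_uM,
##                  dead_24h,dead_120h,malformed_120h
##   morphology.csv plate_barcode,well_id,endpoint_id,value
##   epr_frames.csv plate_barcode,well_id,time_s,movement_index
##   lpr_bins.csv   plate_barcode,well_id,bin_start_s,distance
##   manifest.csv   sample_id,exposure_id,is_control,replicate,pool_size

plate_flag_cols <- c("dead_24h", "dead_120h", "malformed_120h")

#' Validate a plate well table
#'
#' Checks the per-well table against its invariants: well ids are canonical
#' `"A01"`-style and unique within plate, concentrations are non-negative,
#' status flags are 0/1, and death at 24 hpf implies death at 120 hpf.
#' Missing optional flag columns are added as 0 with a message.
#'
#' @param plates Data frame with at least `plate_barcode`, `well_id`,
#'   `chemical_id`, `concentration_uM`.
#' @return The validated tibble (invisibly usable in a pipe).
#' @export
validate_plates <- function(plates) {
  plates <- as_tibble(plates)
  assert_columns(plates,
                 c("plate_barcode", "well_id", "chemical_id", "concentration_uM"),
                 "plates table")
  for (fc in plate_flag_cols) {
    if (!fc %in% names(plates)) {
      inform(sprintf("plates table: optional column '%s' absent, defaulting to 0", fc))
      plates[[fc]] <- 0L
    }
    if (!all(plates[[fc]] %in% c(0, 1))) {
      validation_error("plates column '%s' must be binary 0/1", fc)
    }
    plates[[fc]] <- as.integer(plates[[fc]])
  }
  bad_well <- !is_valid_well_id(plates$well_id)
  if (any(bad_well)) {
    validation_error("invalid well_id '%s' (expected e.g. 'A01', rows A-H, columns 1-12)",
                     plates$well_id[which(bad_well)[1]])
  }
  dup <- plates %>%
    count(.data$plate_barcode, .data$well_id) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    validation_error("duplicate well '%s' on plate '%s'",
                     dup$well_id[1], dup$plate_barcode[1])
  }
  if (any(plates$concentration_uM < 0)) {
    validation_error("concentration_uM must be non-negative")
  }
  if (any(plates$dead_24h == 1L & plates$dead_120h == 0L)) {
    validation_error("dead_24h = 1 implies dead_120h = 1; inconsistent flags found")
  }
  plates
}

#' Validate a morphology record table
#'
#' Every record must reference an existing well and a cataloged endpoint,
#' carry a binary value, and appear at most once per (well, endpoint).
#'
#' @param morphology Data frame with `plate_barcode`, `well_id`,
#'   `endpoint_id`, `value`.
#' @param plates Validated plate table the records must resolve against.
#' @param catalog Endpoint catalog (see [default_endpoint_catalog()]).
#' @return The validated tibble.
#' @export
validate_morphology <- function(morphology, plates,
                                catalog = default_endpoint_catalog()) {
  morphology <- as_tibble(morphology)
  assert_columns(morphology,
                 c("plate_barcode", "well_id", "endpoint_id", "value"),
                 "morphology table")
  validate_endpoint_catalog(catalog)
  bad_value <- !(morphology$value %in% c(0, 1))
  if (any(bad_value)) {
    i <- which(bad_value)[1]
    validation_error(
      "non-binary morphology value '%s' at row %d (plate %s, well %s, endpoint %s)",
      morphology$value[i], i, morphology$plate_barcode[i],
      morphology$well_id[i], morphology$endpoint_id[i])
  }
  morphology$value <- as.integer(morphology$value)
  unknown <- setdiff(unique(morphology$endpoint_id), catalog$endpoint_id)
  if (length(unknown) > 0) {
    validation_error("unknown endpoint_id '%s' not in catalog", unknown[1])
  }
  orphans <- anti_join(morphology, plates, by = c("plate_barcode", "well_id"))
  if (nrow(orphans) > 0) {
    validation_error("morphology record references unknown well '%s' on plate '%s'",
                     orphans$well_id[1], orphans$plate_barcode[1])
  }
  dup <- morphology %>%
    count(.data$plate_barcode, .data$well_id, .data$endpoint_id) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    validation_error("duplicate morphology record for well %s endpoint %s",
                     dup$well_id[1], dup$endpoint_id[1])
  }
  morphology
}

#' Read a validated bundle of plate tables
#'
#' Reads `plates.csv` and `morphology.csv` (and, when present,
#' `epr_frames.csv`, `lpr_bins.csv`, `manifest.csv`) from a directory or an
#' explicitly named file set, validates every table against its invariants and
#' resolves cross-references.
#'
#' @param path Directory containing the canonical CSV files, or a named list /
#'   character vector with elements `plates`, `morphology` and optionally
#'   `epr_frames`, `lpr_bins`, `manifest` giving file paths.
#' @param catalog Endpoint catalog used for morphology validation.
#' @return Named list of tibbles: `plates`, `morphology`, and any optional
#'   tables found.
#' @export
read_plate_tables <- function(path, catalog = default_endpoint_catalog()) {
  files <- if (is.character(path) && length(path) == 1 && dir.exists(path)) {
    f <- c(plates = file.path(path, "plates.csv"),
           morphology = file.path(path, "morphology.csv"),
           epr_frames = file.path(path, "epr_frames.csv"),
           lpr_bins = file.path(path, "lpr_bins.csv"),
           manifest = file.path(path, "manifest.csv"))
    f[file.exists(f) | names(f) %in% c("plates", "morphology")]
  } else {
    unlist(path)
  }
  for (req in c("plates", "morphology")) {
    if (!req %in% names(files) || !file.exists(files[[req]])) {
      validation_error("required file '%s' not found", req)
    }
  }
  read_csv_strict <- function(f) {
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }
  out <- list()
  out$plates <- validate_plates(read_csv_strict(files[["plates"]]))
  out$morphology <- validate_morphology(read_csv_strict(files[["morphology"]]),
                                        out$plates, catalog)
  if ("epr_frames" %in% names(files) && file.exists(files[["epr_frames"]])) {
    out$epr_frames <- validate_frames(read_csv_strict(files[["epr_frames"]]),
                                      out$plates)
  }
  if ("lpr_bins" %in% names(files) && file.exists(files[["lpr_bins"]])) {
    out$lpr_bins <- validate_bins(read_csv_strict(files[["lpr_bins"]]),
                                  out$plates)
  }
  if ("manifest" %in% names(files) && file.exists(files[["manifest"]])) {
    out$manifest <- validate_manifest(read_csv_strict(files[["manifest"]]))
  }
  out
}

#' Write a bundle of plate tables to a directory
#'
#' Inverse of [read_plate_tables()]; writes each table under its canonical
#' file name so a write-then-read round trip is the identity.
#'
#' @param bundle Named list of tibbles as returned by [read_plate_tables()] or
#'   [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_tables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  names_map <- c(plates = "plates.csv", morphology = "morphology.csv",
                 epr_frames = "epr_frames.csv", lpr_bins = "lpr_bins.csv",
                 manifest = "manifest.csv", truth = "truth.csv")
  for (nm in intersect(names(bundle), names(names_map))) {
    readr::write_csv(bundle[[nm]], file.path(dir, names_map[[nm]]),
                     progress = FALSE)
  }
  if ("counts" %in% names(bundle)) {
    write_counts(bundle$counts, file.path(dir, "counts.tsv"))
  }
  invisible(dir)
}

validate_frames <- function(frames, plates) {
  frames <- as_tibble(frames)
  assert_columns(frames, c("plate_barcode", "well_id", "time_s", "movement_index"),
                 "epr_frames table")
  if (any(frames$movement_index < 0)) {
    validation_error("movement_index must be non-negative")
  }
  bad <- frames %>%
    group_by(.data$plate_barcode, .data$well_id) %>%
    summarise(ok = !is.unsorted(.data$time_s, strictly = TRUE), .groups = "drop")
  if (any(!bad$ok)) {
    validation_error("frame times must be strictly increasing within well %s",
                     bad$well_id[!bad$ok][1])
  }
  orphans <- anti_join(distinct(frames, .data$plate_barcode, .data$well_id),
                       plates, by = c("plate_barcode", "well_id"))
  if (nrow(orphans) > 0) {
    validation_error("epr_frames references unknown well '%s'", orphans$well_id[1])
  }
  frames
}

validate_bins <- function(bins, plates) {
  bins <- as_tibble(bins)
  assert_columns(bins, c("plate_barcode", "well_id", "bin_start_s", "distance"),
                 "lpr_bins table")
  if (any(bins$distance < 0)) validation_error("distances must be non-negative")
  orphans <- anti_join(distinct(bins, .data$plate_barcode, .data$well_id),
                       plates, by = c("plate_barcode", "well_id"))
  if (nrow(orphans) > 0) {
    validation_error("lpr_bins references unknown well '%s'", orphans$well_id[1])
  }
  bins
}

validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  assert_columns(manifest,
                 c("sample_id", "exposure_id", "is_control", "replicate", "pool_size"),
                 "manifest")
  if (anyDuplicated(manifest$sample_id)) {
    validation_error("duplicate sample_id in manifest")
  }
  if (any(manifest$pool_size < 1)) validation_error("pool_size must be >= 1")
  dup <- manifest %>%
    count(.data$exposure_id, .data$replicate) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    validation_error("replicate index %s duplicated within exposure '%s'",
                     dup$replicate[1], dup$exposure_id[1])
  }
  manifest
}

#' Build a transcriptomic sample manifest
#'
#' The screen's RNA-seq design: a fixed number of exposures each with the same
#' number of replicate pools, plus a set of control replicates that are pooled
#' downstream into a single global control. The standard design (10 exposures
#' x 4 replicates + 8 controls) yields 48 samples.
#'
#' @param n_exposures Number of chemical exposure groups.
#' @param reps_per_exposure Replicate pools per exposure.
#' @param n_controls Control replicate pools.
#' @param exposure_ids Optional exposure identifiers (length `n_exposures`).
#' @param pool_size Embryos per pool (default 8).
#' @return Tibble with columns `sample_id`, `exposure_id`, `is_control`,
#'   `replicate`, `pool_size`; `n_exposures * reps_per_exposure + n_controls`
#'   rows.
#' @examples
#' build_manifest(10, 4, 8)  # 48 samples, 8 of them controls
#' @export
build_manifest <- function(n_exposures, reps_per_exposure, n_controls,
                           exposure_ids = NULL, pool_size = 8L) {
  if (n_exposures < 0 || reps_per_exposure < 0 || n_controls < 0) {
    validation_error("manifest counts must be non-negative")
  }
  if (is.null(exposure_ids)) {
    exposure_ids <- if (n_exposures > 0) sprintf("EXP%02d", seq_len(n_exposures)) else character()
  }
  stopifnot(length(exposure_ids) == n_exposures)
  exposed <- if (n_exposures > 0 && reps_per_exposure > 0) {
    tidyr::expand_grid(exposure_id = exposure_ids,
                       replicate = seq_len(reps_per_exposure)) %>%
      mutate(is_control = 0L)
  } else {
    tibble(exposure_id = character(), replicate = integer(), is_control = integer())
  }
  controls <- if (n_controls > 0) {
    tibble(exposure_id = "CONTROL", replicate = seq_len(n_controls),
           is_control = 1L)
  } else {
    tibble(exposure_id = character(), replicate = integer(), is_control = integer())
  }
  bind_rows(exposed, controls) %>%
    mutate(sample_id = sprintf("S%03d", row_number()),
           pool_size = as.integer(pool_size)) %>%
    select("sample_id", "exposure_id", "is_control", "replicate", "pool_size")
}

#' Read / write a gene count matrix
#'
#' `counts.tsv` is tab-separated with `gene_id` as the first column and one
#' column per sample; counts are non-negative integers.
#'
#' @param path File path.
#' @return `read_counts()`: tibble with `gene_id` first; `write_counts()`:
#'   `path`, invisibly.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(counts)[1] != "gene_id") {
    validation_error("counts file must have 'gene_id' as its first column")
  }
  if (anyDuplicated(counts$gene_id)) {
    validation_error("duplicate gene_id in counts")
  }
  mat <- as.matrix(counts[-1])
  if (any(mat < 0) || any(mat != round(mat))) {
    validation_error("counts must be non-negative integers")
  }
  counts
}

#' @rdname read_counts
#' @param counts Count tibble (`gene_id` first column) or matrix with gene
#'   rownames.
#' @export
write_counts <- function(counts, path) {
  counts <- as_count_tibble(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

## Accept either a gene_id-first tibble or a rownamed matrix; return matrix.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) validation_error("count matrix needs gene rownames")
    return(counts)
  }
  counts <- as_tibble(counts)
  if (names(counts)[1] != "gene_id") {
    validation_error("count table must have 'gene_id' as its first column")
  }
  mat <- as.matrix(counts[-1])
  rownames(mat) <- counts$gene_id
  mat
}

as_count_tibble <- function(counts) {
  if (is.matrix(counts)) {
    counts <- bind_cols(tibble(gene_id = rownames(counts)), as_tibble(counts))
  }
  as_tibble(counts)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene ids. Empty sets are rejected.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  if (any(lengths(sets) == 0)) {
    validation_error("GMT contains empty gene set '%s'",
                     names(sets)[lengths(sets) == 0][1])
  }
  if (anyDuplicated(names(sets))) validation_error("GMT has duplicate set names")
  sets
}
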