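## Count normalization, the NB Wald differential-expression summary, DEG
## calling, overlap (UpSet) logic, PCA, hypergeometric enrichment, and
## hierarchy rollup.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factor: the median over all-positive genes of the ratio
#' of the sample's count to the gene's geometric-mean reference across
#' samples.
#'
#' @param counts Count matrix (gene rownames) or tibble with `gene_id` first.
#' @return Named positive numeric vector, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  mat <- as_count_matrix(counts)
  if (ncol(mat) < 2) validation_error("need >= 2 samples")
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) {
    validation_error(
      "no gene has positive counts in every sample; consider a pseudocount mode")
  }
  logref <- rowMeans(log(mat[pos, , drop = FALSE]))
  sf <- apply(mat[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
  sf
}

#' Negative binomial Wald test against the pooled global control
#'
#' The built-in differential-expression summary: all control replicates are
#' pooled into a single global control arm and each exposure's replicates are
#' compared against it. Counts are normalized by median-of-ratios size
#' factors; per gene, a method-of-moments NB dispersion (variance
#' `mu + alpha * mu^2`) is estimated from the within-group variances, and the
#' log2 fold-change of group means is tested with a Wald statistic referred
#' to a t distribution on `n1 + n2 - 2` degrees of freedom (the small-sample
#' reference for the plug-in variance). Deterministic given inputs; genes
#' with all-zero counts in both arms get `NA` p-values.
#'
#' This is a transparent, engine-agnostic summary statistic; externally
#' produced per-gene results tables can be ingested instead via
#' [read_deresults()], and everything downstream (DEG calling, overlaps,
#' prioritization counts) consumes either source identically.
#'
#' @param counts Count matrix or tibble (`gene_id` first column).
#' @param manifest Sample manifest (see [build_manifest()]).
#' @param exposure_id Exposure to test against the global control.
#' @param pseudocount Added to group means on the normalized scale before the
#'   log-ratio, keeping fold-changes finite for one-sided zeros.
#' @return Tibble, one row per gene: `gene_id, base_mean, log2fc, se,
#'   dispersion, stat, p_value, direction` (`"up"`/`"down"`).
#' @export
de_test <- function(counts, manifest, exposure_id, pseudocount = 0.5) {
  mat <- as_count_matrix(counts)
  manifest <- validate_manifest(manifest)
  ctrl_ids <- manifest$sample_id[manifest$is_control == 1]
  trt_ids <- manifest$sample_id[manifest$exposure_id == exposure_id &
                                  manifest$is_control == 0]
  if (length(trt_ids) < 2 || length(ctrl_ids) < 2) {
    validation_error("need >= 2 replicates per arm (found %d treated, %d control)",
                     length(trt_ids), length(ctrl_ids))
  }
  missing <- setdiff(c(ctrl_ids, trt_ids), colnames(mat))
  if (length(missing) > 0) {
    validation_error("sample '%s' missing from count matrix", missing[1])
  }
  sub <- mat[, c(ctrl_ids, trt_ids), drop = FALSE]
  sf <- size_factors(sub)
  y <- sweep(sub, 2, sf, "/")
  yc <- y[, ctrl_ids, drop = FALSE]
  yt <- y[, trt_ids, drop = FALSE]
  n1 <- length(ctrl_ids); n2 <- length(trt_ids)
  m1 <- rowMeans(yc); m2 <- rowMeans(yt)
  v1 <- apply(yc, 1, var); v2 <- apply(yt, 1, var)
  ## method-of-moments dispersion pooled across arms, floored at 0 (Poisson)
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  alpha <- pmax(0, ((n1 - 1) * mom(v1, m1) + (n2 - 1) * mom(v2, m2)) /
                  (n1 + n2 - 2))
  w1 <- m1 + alpha * m1^2
  w2 <- m2 + alpha * m2^2
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  se <- sqrt(w1 / (n1 * (m1 + pseudocount)^2) +
               w2 / (n2 * (m2 + pseudocount)^2)) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  p[m1 == 0 & m2 == 0] <- NA_real_
  tibble(gene_id = rownames(mat),
         base_mean = (m1 + m2) / 2,
         log2fc = lfc, se = se, dispersion = alpha, stat = stat,
         p_value = p,
         direction = if_else(lfc >= 0, "up", "down"))
}

#' Read an externally produced differential-expression table
#'
#' `deresults.tsv` has columns `gene_id`, `log2fc`, `pvalue`; direction is
#' derived from the fold-change sign so the table slots into [call_degs()]
#' and everything downstream.
#'
#' @param path TSV file path.
#' @return Tibble `gene_id, log2fc, p_value, direction`.
#' @export
read_deresults <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tab, c("gene_id", "log2fc", "pvalue"), "deresults")
  if (any(tab$pvalue < 0 | tab$pvalue > 1, na.rm = TRUE)) {
    validation_error("pvalue outside [0,1]")
  }
  tab %>%
    rename(p_value = "pvalue") %>%
    mutate(direction = if_else(.data$log2fc >= 0, "up", "down"))
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its raw p-value is `<= deg_alpha` (inclusive, default
#' 0.05) -- deliberately with no fold-change cutoff and no multiplicity
#' adjustment, the screen's broad exploratory definition. Split by
#' fold-change direction.
#'
#' @param de_table Result of [de_test()] or [read_deresults()].
#' @param thresholds A [hit_thresholds()].
#' @return Named list of character vectors: `up`, `down`, `all`.
#' @export
call_degs <- function(de_table, thresholds = hit_thresholds()) {
  assert_columns(de_table, c("gene_id", "p_value", "direction"), "DE table")
  hit <- !is.na(de_table$p_value) & de_table$p_value <= thresholds$deg_alpha
  list(up = de_table$gene_id[hit & de_table$direction == "up"],
       down = de_table$gene_id[hit & de_table$direction == "down"],
       all = de_table$gene_id[hit])
}

#' Exclusive-intersection (UpSet) counts for named gene sets
#'
#' For every combination of the input sets, the number of genes belonging to
#' exactly that combination (so rows are disjoint and their counts sum to the
#' union size). Per-set exclusive counts are the degree-1 rows.
#'
#' @param sets Named list of character vectors (>= 1 set).
#' @param keep_empty Include zero-count combinations (default when <= 12
#'   sets).
#' @return Tibble `combination` (set names joined by `&`), `degree`, `n`;
#'   attribute `union_size`.
#' @examples
#' overlap_matrix(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
overlap_matrix <- function(sets, keep_empty = length(sets) <= 12) {
  if (length(sets) < 1) validation_error("need >= 1 set")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    validation_error("sets must be named")
  }
  sets <- lapply(sets, unique)
  union_genes <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  if (length(union_genes) == 1) member <- matrix(member, nrow = 1,
                                                 dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  counted <- as_tibble(table(pattern), .name_repair = ~ c("combination", "n")) %>%
    mutate(n = as.integer(n))
  if (keep_empty) {
    all_combos <- unlist(lapply(seq_along(sets), function(k) {
      utils::combn(names(sets), k, paste, collapse = "&", simplify = TRUE)
    }))
    counted <- tibble(combination = all_combos) %>%
      left_join(counted, by = "combination") %>%
      mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  out <- counted %>%
    mutate(degree = stringr::str_count(.data$combination, stringr::fixed("&")) + 1L) %>%
    arrange(.data$degree, .data$combination) %>%
    select("combination", "degree", "n")
  attr(out, "union_size") <- length(union_genes)
  out
}

#' PCA of normalized, log-transformed counts
#'
#' Variance stabilization is approximated by `log2(count / size_factor + 1)`;
#' the analysis is restricted to the `top_n` most variable genes (default
#' 500) and the centered matrix is decomposed by SVD. Variance fractions are
#' relative to the total variance of the restricted matrix.
#'
#' @param counts Count matrix or tibble.
#' @param sf Size factors (computed from `counts` when `NULL`).
#' @param top_n Number of most-variable genes to keep.
#' @return A `count_pca` object: list with `scores` (tibble `sample_id`,
#'   `PC1`, ...), `variance` (tibble `component, var_fraction`), `top_n`.
#' @export
pca_scores <- function(counts, sf = NULL, top_n = 500) {
  mat <- as_count_matrix(counts)
  if (ncol(mat) < 3) validation_error("need >= 3 samples for PCA")
  sf <- sf %||% size_factors(mat)
  lt <- log2(sweep(mat, 2, sf, "/") + 1)
  vars <- apply(lt, 1, var)
  if (top_n > nrow(lt)) {
    warn(sprintf("top_n = %d exceeds gene count %d; using all genes",
                 top_n, nrow(lt)))
    top_n <- nrow(lt)
  }
  keep <- order(vars, decreasing = TRUE)[seq_len(top_n)]
  x <- t(lt[keep, , drop = FALSE])
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  k <- min(ncol(sv$u), nrow(x) - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  var_frac <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(
    list(scores = bind_cols(tibble(sample_id = colnames(mat)),
                            as_tibble(scores)),
         variance = tibble(component = paste0("PC", seq_len(k)),
                           var_fraction = var_frac),
         top_n = top_n),
    class = "count_pca"
  )
}

#' @export
print.count_pca <- function(x, ...) {
  cat(sprintf("PCA of %d samples on the %d most variable genes\n",
              nrow(x$scores), x$top_n))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$variance$var_fraction[1],
              100 * x$variance$var_fraction[2] %||% NA))
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a DEG list and each
#' gene set (sets intersected with the background first), with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param deg Character vector of DEG ids (must be a subset of `background`).
#' @param background Character vector: the gene universe.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @return Tibble `set, set_size, overlap, p_value, q_value` sorted by p.
#' @export
hypergeom_enrich <- function(deg, background, sets) {
  background <- unique(background)
  if (length(background) == 0) validation_error("empty background")
  deg <- unique(deg)
  if (length(setdiff(deg, background)) > 0) {
    validation_error("DEG list contains genes outside the background")
  }
  res <- purrr::imap_dfr(sets, function(genes, nm) {
    k_set <- intersect(unique(genes), background)
    ov <- length(intersect(deg, k_set))
    p <- phyper(ov - 1, length(k_set), length(background) - length(k_set),
                length(deg), lower.tail = FALSE)
    tibble(set = nm, set_size = length(k_set), overlap = ov, p_value = p)
  })
  res %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value)
}

#' Roll enriched pathways up a functional hierarchy
#'
#' Maps each enriched pathway to its top-level functional class and reports,
#' per class, the number of enriched pathways and the mean -log10 p.
#'
#' @param enriched Tibble with `set` (pathway id) and `p_value` columns (e.g.
#'   a filtered [hypergeom_enrich()] result).
#' @param hierarchy Tibble `pathway_id, class` giving the top-level class of
#'   every pathway.
#' @return Tibble `class, n_pathways, mean_neglog10_p`.
#' @export
brite_rollup <- function(enriched, hierarchy) {
  assert_columns(enriched, c("set", "p_value"), "enrichment table")
  assert_columns(hierarchy, c("pathway_id", "class"), "hierarchy")
  if (nrow(enriched) == 0) {
    return(tibble(class = character(), n_pathways = integer(),
                  mean_neglog10_p = double()))
  }
  unmapped <- setdiff(enriched$set, hierarchy$pathway_id)
  if (length(unmapped) > 0) {
    validation_error("pathway '%s' is not mapped in the hierarchy", unmapped[1])
  }
  enriched %>%
    left_join(hierarchy, by = c(set = "pathway_id")) %>%
    group_by(class = .data$class) %>%
    summarise(n_pathways = n(),
              mean_neglog10_p = mean(-log10(.data$p_value)),
              .groups = "drop")
}
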