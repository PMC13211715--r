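toy_counts <- function(n_genes = 200, n_samples = 6, seed = 1, mu = 100) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 10),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%d", 1:n_samples)))
  m
}

test_that("median-of-ratios size factors match worked values", {
  m <- toy_counts()
  expect_equal(unname(size_factors(m[, c(1, 1)])), c(1, 1))
  two <- cbind(a = m[, 1] + 1L, b = 2L * (m[, 1] + 1L))
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)
  # gene-row permutation invariance
  expect_equal(size_factors(m), size_factors(m[sample(nrow(m)), ]))
  # per-sample scaling constants recovered up to a common factor
  k <- c(0.5, 1, 2, 1, 1.5, 0.8)
  scaled <- round(sweep(m + 1L, 2, k, "*"))
  sf <- size_factors(scaled)
  ratio <- (sf / size_factors(m + 1L)) / k
  expect_lt(sd(ratio) / mean(ratio), 0.02)   # constant up to a common factor
  # all-zero gene everywhere -> no reference gene
  zeros <- matrix(0L, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_error(size_factors(zeros), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  m <- toy_counts(n_genes = 500, seed = 42)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("DE test handles degenerate genes and is replicate-order invariant", {
  man <- build_manifest(1, 4, 8, exposure_ids = "A")
  tr <- chemical_truth("A", morphology = tibble::tibble(
    endpoint_id = "MORT", p0 = 0, ec50 = 10, h = 2),
    de_fraction = 0.1, lfc_sd = 2)
  cs <- simulate_counts(tr, man, n_genes = 500, seed = 14)
  mat <- zebratox:::as_count_matrix(cs$counts)
  mat[1, ] <- 0L   # all-zero gene
  de <- de_test(mat, man, "A")
  expect_true(is.na(de$p_value[1]))
  expect_true(all(de$p_value >= 0 & de$p_value <= 1, na.rm = TRUE))
  expect_true(all(de$direction[!is.na(de$log2fc)] %in% c("up", "down")))
  expect_true(all((de$log2fc >= 0) == (de$direction == "up")))
  # permuting sample columns leaves the result unchanged
  de2 <- de_test(mat[, sample(ncol(mat))], man, "A")
  expect_equal(de$p_value, de2$p_value, tolerance = 1e-12)
  expect_error(de_test(mat, man[-(1:3), ], "A"), "replicates per arm")
})

test_that("planted strong fold-changes are recovered with high power", {
  man <- build_manifest(1, 4, 8, exposure_ids = "A")
  set.seed(5)
  n_genes <- 2000; n_planted <- 200
  mu <- exp(runif(n_genes, log(50), log(500)))
  lfc <- c(rep(2, n_planted), rep(0, n_genes - n_planted))  # 4-fold
  mat <- matrix(0L, n_genes, 12,
                dimnames = list(sprintf("g%04d", 1:n_genes), man$sample_id))
  for (j in 1:12) {
    up <- if (man$is_control[j] == 1) 0 else lfc
    mat[, j] <- rnbinom(n_genes, mu = mu * 2^up, size = 1 / 0.01)
  }
  de <- de_test(mat, man, "A")
  power <- mean(de$p_value[1:n_planted] < 0.05)
  expect_gt(power, 0.9)
  recall <- mean(sprintf("g%04d", 1:n_planted) %in% call_degs(de)$all)
  expect_gt(recall, 0.9)
})

test_that("null p-values are approximately uniform", {
  man <- build_manifest(1, 4, 8, exposure_ids = "A")
  tr <- chemical_truth("A", morphology = tibble::tibble(
    endpoint_id = "MORT", p0 = 0, ec50 = 10, h = 2), de_fraction = 0)
  cs <- simulate_counts(tr, man, n_genes = 5000, seed = 99)
  de <- de_test(cs$counts, man, "A")
  p <- de$p_value[!is.na(de$p_value)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("DEG calling uses an inclusive raw-p threshold split by direction", {
  tab <- tibble::tibble(gene_id = c("a", "b", "c"),
                        log2fc = c(1, -1, 2),
                        p_value = c(0.04, 0.05, 0.051),
                        direction = c("up", "down", "up"))
  degs <- call_degs(tab)
  expect_equal(degs$all, c("a", "b"))
  expect_equal(degs$up, "a")
  expect_equal(degs$down, "b")
  empty <- call_degs(dplyr::mutate(tab, p_value = 1))
  expect_equal(lengths(empty), c(up = 0L, down = 0L, all = 0L))
  none <- call_degs(tab[0, ])
  expect_equal(lengths(none), c(up = 0L, down = 0L, all = 0L))
})

test_that("overlap counts are exclusive, exhaustive, and conserve the union", {
  om <- overlap_matrix(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(om$n[om$combination == "A"], 1L)
  expect_equal(om$n[om$combination == "B"], 1L)
  expect_equal(om$n[om$combination == "A&B"], 1L)
  expect_equal(attr(om, "union_size"), 3L)
  # disjoint sets
  omd <- overlap_matrix(list(A = "g1", B = "g2"))
  expect_equal(omd$n[omd$combination == "A&B"], 0L)
  # identical sets: exclusive counts 0, shared = |A|
  omi <- overlap_matrix(list(A = c("g1", "g2"), B = c("g1", "g2")))
  expect_equal(omi$n[omi$degree == 1], c(0L, 0L))
  expect_equal(omi$n[omi$combination == "A&B"], 2L)
  # conservation over random families
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    fam <- lapply(seq_len(k), function(i)
      sample(sprintf("g%02d", 1:40), sample(1:30, 1)))
    names(fam) <- LETTERS[seq_len(k)]
    om <- overlap_matrix(fam)
    expect_equal(sum(om$n), attr(om, "union_size"))
  }
})

test_that("PCA scores have the expected geometry", {
  m <- toy_counts(n_genes = 300, n_samples = 8, seed = 3)
  p <- suppressWarnings(pca_scores(m, top_n = 100))
  sc <- as.matrix(p$scores[-1])
  # orthogonal components
  cp <- crossprod(sc)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)
  # non-increasing variance fractions summing to <= 1
  vf <- p$variance$var_fraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-9)
  # duplicated samples land on the same coordinates
  m2 <- cbind(m, dup = m[, 1])
  colnames(m2)[1] <- "orig"
  p2 <- pca_scores(m2, sf = rep(1, ncol(m2)), top_n = 100)
  s1 <- as.numeric(p2$scores[p2$scores$sample_id == "orig", -1])
  s2 <- as.numeric(p2$scores[p2$scores$sample_id == "dup", -1])
  expect_equal(s1, s2, tolerance = 1e-8)
  expect_warning(pca_scores(m, top_n = 1000), "using all genes")
})

test_that("hypergeometric enrichment matches enumeration", {
  bg <- sprintf("g%02d", 1:10)
  res <- hypergeom_enrich(bg[1:5], bg, list(S = bg[1:5]))
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  # deg = background saturates every set at p = 1
  sat <- hypergeom_enrich(bg, bg, list(S1 = bg[1:5], S2 = bg[2:4]))
  expect_true(all(sat$p_value == 1))
  # zero overlap has p = 1 under the upper tail
  dis <- hypergeom_enrich(bg[1:2], bg, list(S = bg[9:10]))
  expect_equal(dis$p_value, 1)
  expect_error(hypergeom_enrich(bg[1:2], character(), list(S = bg)), "background")
  expect_error(hypergeom_enrich(c(bg[1], "zzz"), bg, list(S = bg)), "outside")
})

test_that("hierarchy rollup aggregates counts and mean -log10 p", {
  hier <- tibble::tibble(pathway_id = c("p1", "p2", "p3"),
                         class = c("metabolism", "metabolism", "signaling"))
  enr <- tibble::tibble(set = c("p1", "p2", "p3"),
                        p_value = c(0.01, 0.0001, 0.05))
  roll <- brite_rollup(enr, hier)
  met <- roll[roll$class == "metabolism", ]
  expect_equal(met$n_pathways, 2L)
  expect_equal(met$mean_neglog10_p, 3)
  expect_equal(roll$n_pathways[roll$class == "signaling"], 1L)
  expect_equal(nrow(brite_rollup(enr[0, ], hier)), 0)
  expect_error(brite_rollup(tibble::tibble(set = "p9", p_value = 0.1), hier),
               "not mapped")
})
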