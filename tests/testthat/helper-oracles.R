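# Independent oracles used to cross-check the fast implementations.

# KS D by brute force: evaluate both ECDFs via stats::ecdf at every pooled
# sample point and take the largest absolute gap.
oracle_ks_d <- function(x, y) {
  pts <- c(x, y)
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

# One-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins: P(X >= a) for X hypergeometric, written out as a sum of
# binomial-coefficient ratios.
oracle_fisher_p <- function(a, n1, b, n2) {
  s <- a + b
  ks <- max(0, s - n2):min(n1, s)
  probs <- choose(n1, ks) * choose(n2, s - ks) / choose(n1 + n2, s)
  sum(probs[ks >= a])
}

# Ward merge tree by recomputing the criterion from scratch at every step:
# delta SS of merging A and B is SS(A u B) - SS(A) - SS(B). Ties broken by
# the lexicographically smallest creation-ordered cluster index pair,
# mirroring the documented convention.
oracle_ward <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)   # member row indices
  ids <- -seq_len(n)
  ss <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      if (is.null(clusters[[i]])) next
      for (j in seq_along(clusters)) {
        if (j <= i || is.null(clusters[[j]])) next
        d <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (is.null(best) || d < best$d - 1e-12) {
          best <- list(d = d, i = i, j = j)
        }
      }
    }
    pair <- c(ids[best$i], ids[best$j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[best$j] <- list(NULL)
    ids[best$i] <- step
  }
  list(merge = merge, height = height)
}

# Closed-form benchmark concentration from generative parameters.
true_bmc <- function(p0, ec50, h, bmr = 0.10) {
  q <- bmr / (1 - p0)
  ec50 * (q / (1 - q))^(1 / h)
}

# Small valid bundle used across I/O tests.
make_test_bundle <- function(seed = 101, active = 1L, chemical_id = "CHEM1") {
  tr <- random_chemical_truth(chemical_id, seed, active = active)
  des <- screen_design(chemical_id, "P0001")
  sim <- simulate_morphology(tr, des, seed)
  list(truth = tr, design = des, plates = sim$plates,
       morphology = sim$morphology)
}
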