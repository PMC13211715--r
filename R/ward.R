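## Ward agglomerative clustering via the Lance-Williams update.

#' Ward hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative Ward linkage on squared Euclidean distances using the
#' Lance-Williams recurrence. At each step the pair minimizing the increase
#' in within-cluster sum of squares,
#' `delta(A, B) = |A||B| / (|A| + |B|) * ||centroid_A - centroid_B||^2`,
#' is merged; exact ties are broken by the lexicographically smallest pair of
#' cluster indices (clusters ordered by creation), so results are identical
#' across platforms. Merge heights are the `delta` costs and are
#' non-decreasing. The result is a standard `hclust` object (heights on the
#' variance-increase scale; `stats::hclust(method = "ward.D2")` heights equal
#' `sqrt(2 * height)` here).
#'
#' @param x Numeric matrix or data frame of profiles (rows = objects, e.g.
#'   chemicals; columns = features). Row names label the leaves.
#' @return An `hclust` object.
#' @examples
#' ward_cluster(cbind(x = c(0, 1, 10)))$merge
#' @export
ward_cluster <- function(x) {
  if (is.data.frame(x)) {
    labs <- if ("chemical_id" %in% names(x)) x$chemical_id else rownames(x)
    x <- as.matrix(x[vapply(x, is.numeric, TRUE)])
    rownames(x) <- labs
  }
  if (!is.matrix(x) || nrow(x) < 2) validation_error("need a matrix with >= 2 rows")
  if (anyNA(x)) {
    validation_error("missing values in profile matrix; impute upstream before clustering")
  }
  n <- nrow(x)
  ## Lance-Williams state: d holds 2 * delta-SS between active clusters
  d <- as.matrix(stats::dist(x))^2
  diag(d) <- Inf
  size <- rep(1L, n)
  ## hclust bookkeeping: id[i] < 0 for singletons (-row), > 0 for merge index
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        i <- idx[b]; j <- idx[a]   # i < j in creation order
        if (d[i, j] < best_d - 1e-12) {
          best_d <- d[i, j]; best <- c(i, j)
        } else if (d[i, j] <= best_d + 1e-12 &&
                   (i < best[1] || (i == best[1] && j < best[2]))) {
          ## exact tie: lexicographically smallest (i, j) wins
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    pair <- c(id[i], id[j])
    ## hclust row convention: singletons (negative) first, by original index
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best_d / 2      # delta within-cluster SS
    ## Lance-Williams update into slot i; retire slot j
    for (k in idx) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        ((size[i] + size[k]) * d[i, k] + (size[j] + size[k]) * d[j, k] -
           size[k] * d[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  structure(
    list(merge = merge, height = height,
         order = hclust_order(merge),
         labels = rownames(x), method = "ward",
         dist.method = "squared euclidean", call = match.call()),
    class = "hclust"
  )
}

## Leaf ordering by left-to-right traversal of the merge tree.
hclust_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}
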