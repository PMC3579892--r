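#' Two-group cluster index
#'
#' The ratio of the within-cluster sum of squared deviations about the two
#' cluster means to the total sum of squares about the grand mean, summed
#' over all genes. Values near 0 indicate well-separated groups; a split of
#' a homogeneous sample gives values near the null distribution mean. The
#' degenerate case of zero total variation is defined as 0.
#'
#' @param x gene-by-sample matrix restricted to the two groups.
#' @param labels vector with exactly two distinct values, one per column.
#' @return A single number in \[0, 1\].
#' @export
cluster_index <- function(x, labels) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) abort("one label per sample is required")
  groups <- unique(labels)
  if (length(groups) != 2) abort("cluster_index requires exactly two groups")
  if (any(table(labels) < 1)) abort("each group needs at least one sample")
  grand <- rowMeans(x)
  total_ss <- sum((x - grand)^2)
  if (total_ss == 0) return(0)
  within_ss <- 0
  for (g in groups) {
    xg <- x[, labels == g, drop = FALSE]
    within_ss <- within_ss + sum((xg - rowMeans(xg))^2)
  }
  within_ss / total_ss
}

# Minimal cluster index over 2-means with multiple restarts.
min_cluster_index_2means <- function(x, n_starts = 10) {
  km <- suppressWarnings(kmeans(t(x), centers = 2, nstart = n_starts))
  if (km$totss == 0) return(0)
  km$tot.withinss / km$totss
}

#' Monte-Carlo cluster significance for a two-group split
#'
#' Tests whether a two-group split of a high-dimensional sample reflects
#' genuine cluster structure rather than a partition of a single Gaussian.
#' The null is a d-dimensional Gaussian whose covariance eigenvalues are the
#' sample covariance eigenvalues hard-thresholded from below at a background
#' noise variance estimated from the MAD of all matrix entries (scaled by
#' the Gaussian consistency constant). `n_sim` datasets of the observed
#' dimensions are simulated from that null; on each, the minimal cluster
#' index over seeded 2-means (multiple restarts) is recorded, and the
#' add-one estimator p = (1 + #\{null CI <= observed CI\}) / (1 + n_sim) is
#' returned, so p is never exactly zero.
#'
#' @param x gene-by-sample matrix restricted to the two groups (>= 3
#'   samples).
#' @param labels two-group label vector.
#' @param n_sim number of null simulations (>= 100; default 1000).
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @param n_starts 2-means restarts inside the null simulation.
#' @return A one-row tibble: group_a, group_b, cluster_index, p_value,
#'   n_sim.
#' @export
sigclust_pvalue <- function(x, labels, n_sim = 1000, seed = 1L, n_starts = 10) {
  if (!is.matrix(x)) abort("x must be a matrix")
  if (ncol(x) < 3) abort("cluster significance needs at least 3 samples")
  if (n_sim < 100) abort("n_sim must be at least 100")
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("exactly two groups are required")
  obs <- cluster_index(x, labels)
  sigma2 <- mad(as.vector(x))^2  # stats::mad applies the 1.4826 constant
  n <- ncol(x); d <- nrow(x)
  centered <- x - rowMeans(x)
  sv <- svd(centered, nu = 0, nv = 0)$d
  lambda <- c(sv^2 / (n - 1), rep(0, max(0, d - length(sv))))[seq_len(d)]
  if (any(!is.finite(lambda))) abort("non-finite covariance eigenvalues")
  sds <- sqrt(pmax(lambda, sigma2))
  null_ci <- numeric(n_sim)
  with_seed(seed, {
    for (i in seq_len(n_sim)) {
      y <- sds * matrix(rnorm(d * n), nrow = d)
      null_ci[i] <- min_cluster_index_2means(y, n_starts)
    }
  })
  p <- (1 + sum(null_ci <= obs)) / (1 + n_sim)
  tibble::tibble(group_a = groups[1], group_b = groups[2],
                 cluster_index = obs, p_value = p, n_sim = n_sim)
}

#' Pairwise cluster significance with Bonferroni adjustment
#'
#' Runs [sigclust_pvalue()] on every unordered pair of the K subtypes and
#' Bonferroni-adjusts over the K(K-1)/2 tests. Each pair receives an
#' independent child seed derived from `seed`.
#'
#' @param x gene-by-sample matrix.
#' @param labels subtype label per sample (K >= 2 distinct values).
#' @param n_sim null simulations per pair.
#' @param seed integer master seed.
#' @param n_starts 2-means restarts inside the null simulation.
#' @return A tibble with one row per pair: group_a, group_b, cluster_index,
#'   p_value, p_adjusted, n_sim.
#' @export
sigclust_all_pairs <- function(x, labels, n_sim = 1000, seed = 1L,
                               n_starts = 10) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) abort("at least two subtypes are required")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  n_tests <- length(pairs)
  seeds <- child_seeds(seed, vapply(pairs, paste, character(1), collapse = "|"))
  out <- purrr::map2(pairs, seeds, function(pr, s) {
    keep <- labels %in% pr
    sigclust_pvalue(x[, keep, drop = FALSE], labels[keep],
                    n_sim = n_sim, seed = s, n_starts = n_starts)
  })
  out <- dplyr::bind_rows(out)
  out$p_adjusted <- pmin(1, out$p_value * n_tests)
  out
}
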