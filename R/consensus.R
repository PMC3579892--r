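#' Resampled consensus clustering
#'
#' Repeatedly subsamples the cohort (`item_fraction` of the samples, without
#' replacement), hierarchically clusters each subsample with 1 - Pearson
#' correlation distance and average linkage, and cuts the tree at each k in
#' `k_range`. The consensus matrix entry for a sample pair is the fraction
#' of co-draws in which the pair co-clustered. Final per-k labels come from
#' hierarchically clustering 1 - consensus as a distance and cutting at k.
#'
#' @param x preprocessed gene-by-sample matrix (median-centered, top-MAD
#'   genes).
#' @param k_range integer vector of cluster counts, within
#'   `[2, ncol(x) - 1]`.
#' @param n_resamples number of subsamples (default 1000).
#' @param item_fraction sampling proportion of samples per draw (default
#'   0.8).
#' @param linkage hierarchical linkage for both the per-resample trees and
#'   the final consensus tree.
#' @param seed integer seed; the run is bit-reproducible.
#' @return A `consensus_result` with per-k consensus matrices, labels, CDF
#'   areas, delta-areas, PAC and label-tracking diagnostics.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_resamples = 1000,
                              item_fraction = 0.8, linkage = "average",
                              seed = 1L) {
  assert_matrix(x, "expression matrix")
  n <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    abort("k_range must lie within [2, n_samples - 1]")
  full_dist <- as.matrix(pearson_dist(x))  # also validates constant samples
  n_draw <- ceiling(item_fraction * n)
  cocluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(cocluster) <- as.character(k_range)
  codraw <- matrix(0, n, n)
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n_draw)
      codraw[idx, idx] <- codraw[idx, idx] + 1
      tree <- hclust(as.dist(full_dist[idx, idx]), method = linkage)
      for (k in k_range) {
        cl <- cutree(tree, k)
        same <- outer(cl, cl, "==")
        ck <- as.character(k)
        cocluster[[ck]][idx, idx] <- cocluster[[ck]][idx, idx] + same
      }
    }
  })
  if (any(codraw[upper.tri(codraw)] == 0))
    abort("some sample pairs were never co-drawn; increase n_resamples")
  consensus <- lapply(cocluster, function(cc) {
    m <- cc / codraw
    dimnames(m) <- list(colnames(x), colnames(x))
    diag(m) <- 1
    m
  })
  labels <- vapply(seq_along(k_range), function(i) {
    tree <- hclust(as.dist(1 - consensus[[i]]), method = linkage)
    cutree(tree, k_range[i])
  }, integer(n))
  dimnames(labels) <- list(colnames(x), as.character(k_range))
  res <- structure(list(
    k_range = k_range, consensus = consensus, labels = labels,
    diagnostics = consensus_diagnostics(consensus, labels, k_range),
    params = list(n_resamples = n_resamples, item_fraction = item_fraction,
                  linkage = linkage, seed = seed)
  ), class = "consensus_result")
  res
}

consensus_diagnostics <- function(consensus, labels, k_range) {
  areas <- vapply(consensus, function(m) {
    v <- sort(m[upper.tri(m)])
    cdf <- ecdf(v)
    grid <- sort(unique(c(0, v, 1)))
    sum(diff(grid) * cdf(head(grid, -1)))
  }, numeric(1))
  delta <- numeric(length(k_range))
  delta[1] <- areas[1]
  if (length(k_range) > 1)
    delta[-1] <- diff(areas) / head(areas, -1)
  pac <- vapply(consensus, function(m) {
    v <- m[upper.tri(m)]
    mean(v > 0.1 & v < 0.9)
  }, numeric(1))
  changed <- c(vapply(seq_len(length(k_range) - 1), function(i) {
    label_changes(labels[, i], labels[, i + 1])
  }, numeric(1)), NA_real_)
  tibble::tibble(k = k_range, area = unname(areas), delta_area = delta,
                 pac = unname(pac), n_changed_to_next = changed)
}

# Samples changing cluster between the k and k+1 labelings: each k-cluster
# maps to the k+1 cluster it overlaps most, and members landing elsewhere
# (e.g. the minority side of a split) count as changed. Identical
# partitions up to renaming give 0.
label_changes <- function(a, b) {
  tab <- table(a, b)
  mapped <- colnames(tab)[apply(tab, 1, which.max)]
  b_expected <- mapped[match(as.character(a), rownames(tab))]
  sum(as.character(b) != b_expected)
}

#' Recommend a cluster count from consensus diagnostics
#'
#' The delta-area of the consensus CDF measures how much co-clustering
#' stability is gained by allowing one more cluster. The recommended k is
#' the last k before the gain first falls below `threshold` (i.e. k* - 1
#' where k* is the smallest k with delta-area < threshold). Runs in which
#' the consensus matrix at the recommended k is dominated by ambiguous
#' entries (PAC above `pac_threshold`) are flagged unstable: the data show
#' no reliable cluster structure at any examined k.
#'
#' @param result a [consensus_cluster()] result with at least 3 k values.
#' @param threshold relative delta-area below which adding a cluster is
#'   considered uninformative (default 0.05).
#' @param pac_threshold proportion-of-ambiguous-clustering level above which
#'   the recommendation is flagged unstable (default 0.4).
#' @return A list with `recommended_k`, `stable` and the diagnostics tibble.
#' @export
select_k <- function(result, threshold = 0.05, pac_threshold = 0.4) {
  stopifnot(inherits(result, "consensus_result"))
  d <- result$diagnostics
  if (nrow(d) < 3) abort("select_k needs at least 3 values of k")
  below <- which(d$delta_area < threshold & d$k > min(d$k))
  if (length(below) == 0) {
    rec <- max(d$k)
    flat <- FALSE
  } else {
    rec <- d$k[min(below)] - 1L
    flat <- TRUE
  }
  pac_at_rec <- d$pac[d$k == rec]
  stable <- flat && length(pac_at_rec) == 1 && pac_at_rec <= pac_threshold
  list(recommended_k = as.integer(rec), stable = stable, diagnostics = d)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", nrow(x$labels), " samples, k = ",
      paste(range(x$k_range), collapse = ".."), ", ",
      x$params$n_resamples, " resamples at ",
      round(100 * x$params$item_fraction), "%\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' Extract per-k consensus labels
#'
#' @param result a `consensus_result`.
#' @param k one value from the result's `k_range`.
#' @return Named integer vector of cluster labels in 1..k.
#' @export
consensus_labels <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  ck <- as.character(k)
  if (!ck %in% colnames(result$labels)) abort(paste0("k = ", k, " was not examined"))
  setNames(result$labels[, ck], rownames(result$labels))
}
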