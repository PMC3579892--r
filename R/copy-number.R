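#' Marker-level copy-number cohort
#'
#' Couples an ordered marker map (chromosome, position, arm) with a
#' marker-by-sample matrix of log2 copy-number ratios. Markers must be
#' sorted by chromosome and strictly increasing position within chromosome.
#'
#' @param markers tibble with columns `marker_id`, `chrom`, `pos`, `arm`.
#' @param values numeric matrix, one row per marker (NA allowed until
#'   imputation).
#' @return A `cn_cohort` object.
#' @export
cn_cohort <- function(markers, values) {
  need <- c("marker_id", "chrom", "pos", "arm")
  if (!all(need %in% names(markers))) abort("markers need marker_id, chrom, pos, arm")
  if (nrow(markers) != nrow(values)) abort("one value row per marker is required")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      abort(paste0("positions not strictly increasing on ", ch))
  }
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  rownames(values) <- markers$marker_id
  structure(list(markers = tibble::as_tibble(markers), values = values),
            class = "cn_cohort")
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat("<cn_cohort> ", nrow(x$values), " markers x ", ncol(x$values),
      " samples on ", length(unique(x$markers$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' Impute missing markers from the nearest covered probe
#'
#' Every missing value is replaced by the value at the genomically nearest
#' non-missing marker of the same sample on the same chromosome; when two
#' non-missing markers are equidistant the upstream (lower-position) one is
#' used. A chromosome entirely missing for a sample cannot be imputed.
#'
#' @param cohort a `cn_cohort`.
#' @return The cohort with `values` complete.
#' @export
impute_missing_markers <- function(cohort) {
  stopifnot(inherits(cohort, "cn_cohort"))
  x <- cohort$values
  if (!anyNA(x)) return(cohort)
  for (ch in unique(cohort$markers$chrom)) {
    idx <- which(cohort$markers$chrom == ch)
    pos <- cohort$markers$pos[idx]
    for (j in seq_len(ncol(x))) {
      v <- x[idx, j]
      miss <- is.na(v)
      if (!any(miss)) next
      if (all(miss))
        abort(paste0("sample ", colnames(x)[j], " has no non-missing marker on ", ch))
      obs <- which(!miss)
      for (i in which(miss)) {
        dists <- abs(pos[obs] - pos[i])
        # ties resolve upstream because which.min takes the first minimum
        v[i] <- v[obs[which.min(dists)]]
      }
      x[idx, j] <- v
    }
  }
  cohort$values <- x
  cohort
}

#' Smooth outlier markers and median-center each profile
#'
#' Within each chromosome a running median of width `window` tracks the
#' local signal; markers deviating from it by more than `z` times the
#' sample's MAD-based residual scale are shrunk to the running median
#' (single-marker spikes are measurement noise, not aberrations). Each
#' sample's genome-wide profile is then centered to median zero.
#'
#' @param cohort an imputed `cn_cohort`.
#' @param window running-median width (odd, default 5).
#' @param z outlier threshold in residual-scale units (default 3).
#' @return The smoothed, centered cohort.
#' @export
smooth_and_center_profiles <- function(cohort, window = 5, z = 3) {
  stopifnot(inherits(cohort, "cn_cohort"))
  x <- cohort$values
  if (anyNA(x)) abort("impute missing markers before smoothing")
  chrom_idx <- split(seq_len(nrow(x)), cohort$markers$chrom)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    rm_all <- v
    for (idx in chrom_idx) {
      vi <- v[idx]
      rm_all[idx] <- if (length(vi) >= window) {
        runmed(vi, window, endrule = "median")
      } else rep(median(vi), length(vi))
    }
    resid <- v - rm_all
    scale <- mad(resid)
    if (scale > 0) {
      out <- abs(resid) > z * scale
      v[out] <- rm_all[out]
    }
    x[, j] <- v - median(v)
  }
  cohort$values <- x
  cohort
}

# Recursive binary segmentation of one chromosome's values: split at the
# breakpoint maximizing the two-sample t statistic, accepted while the
# t-test p-value is below alpha and both sides keep >= min_seg markers.
segment_vector <- function(v, min_seg = 3, alpha = 0.01) {
  n <- length(v)
  if (n < 2 * min_seg) return(rep(1L, n))
  cs <- cumsum(v); css <- cumsum(v^2)
  ks <- seq(min_seg, n - min_seg)
  n1 <- ks; n2 <- n - ks
  m1 <- cs[ks] / n1; m2 <- (cs[n] - cs[ks]) / n2
  ss1 <- pmax(css[ks] - n1 * m1^2, 0)
  ss2 <- pmax((css[n] - css[ks]) - n2 * m2^2, 0)
  pooled <- (ss1 + ss2) / (n - 2)
  tstat <- ifelse(pooled > 0, (m1 - m2) / sqrt(pooled * (1 / n1 + 1 / n2)), 0)
  best <- which.max(abs(tstat))
  # Bonferroni over the candidate breakpoints: the split statistic is a
  # maximum over |ks| positions, so the naive t p-value badly over-segments.
  p <- min(1, length(ks) * 2 * pt(-abs(tstat[best]), df = n - 2))
  if (!is.finite(p) || p >= alpha) return(rep(1L, n))
  k <- ks[best]
  left <- segment_vector(v[1:k], min_seg, alpha)
  right <- segment_vector(v[(k + 1):n], min_seg, alpha)
  c(left, right + max(left))
}

#' Segment copy-number profiles by recursive binary splitting
#'
#' A plumbing segmenter: within each chromosome, the breakpoint maximizing
#' the two-sample t statistic is accepted recursively while its
#' Bonferroni-adjusted p-value (the split statistic is a maximum over all
#' candidate positions) is below `alpha` and both sides retain at least
#' `min_seg` markers. Segment means are plain means over member markers.
#' Segments partition every chromosome of every sample.
#'
#' @param cohort a smoothed `cn_cohort`.
#' @param min_seg minimum markers per segment (default 3).
#' @param alpha split acceptance level (default 0.01).
#' @return A SEG-style tibble: sample_id, chrom, start, end, n_markers,
#'   seg_mean.
#' @export
segment_profiles <- function(cohort, min_seg = 3, alpha = 0.01) {
  stopifnot(inherits(cohort, "cn_cohort"))
  x <- cohort$values
  rows <- list()
  for (j in seq_len(ncol(x))) {
    for (ch in unique(cohort$markers$chrom)) {
      idx <- which(cohort$markers$chrom == ch)
      seg_id <- segment_vector(x[idx, j], min_seg, alpha)
      for (s in unique(seg_id)) {
        within <- idx[seg_id == s]
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = colnames(x)[j], chrom = ch,
          start = cohort$markers$pos[min(within)],
          end = cohort$markers$pos[max(within)],
          n_markers = length(within),
          seg_mean = mean(x[within, j]))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Expand a segment table back to marker-level segmented values
#'
#' @param seg SEG-style tibble from [segment_profiles()].
#' @param markers marker map tibble of the cohort the segments came from.
#' @return Marker-by-sample matrix of segment means.
#' @export
segmented_marker_values <- function(seg, markers) {
  samples <- unique(seg$sample_id)
  out <- matrix(NA_real_, nrow(markers), length(samples),
                dimnames = list(markers$marker_id, samples))
  for (i in seq_len(nrow(seg))) {
    idx <- which(markers$chrom == seg$chrom[i] &
                 markers$pos >= seg$start[i] & markers$pos <= seg$end[i])
    out[idx, seg$sample_id[i]] <- seg$seg_mean[i]
  }
  if (anyNA(out)) abort("segments do not cover all markers")
  out
}

# Marker-wise cross-sample sums and the extreme statistic for a direction.
peak_statistic <- function(values, direction) {
  sums <- rowSums(values)
  if (direction == "gain") {
    i <- which.max(sums)  # first in genome order on ties
    list(stat = sums[i], marker = i, sums = sums)
  } else {
    i <- which.min(sums)
    list(stat = sums[i], marker = i, sums = sums)
  }
}

cyclic_shift_matrix <- function(x, offsets) {
  n <- nrow(x)
  for (j in seq_len(ncol(x))) {
    o <- offsets[j]
    if (o > 0) x[, j] <- x[c((n - o + 1):n, 1:(n - o)), j]
  }
  x
}

#' Cyclic-shift permutation test for recurrent aberrations
#'
#' The observed statistic is the extreme (max for gains, min for losses)
#' over markers of the cross-sample sum of smoothed, centered values. Each
#' null replicate independently rotates every sample's genome-wide marker
#' vector by a uniform random offset — preserving each profile's serial
#' autocorrelation while destroying cross-sample locus alignment — and
#' records the same extreme. p = (1 + #\{null at least as extreme\}) /
#' (1 + n_perm). The comparison is inclusive, so an all-zero cohort yields
#' p = 1.
#'
#' @param cohort a smoothed, centered `cn_cohort`.
#' @param direction `"gain"` or `"loss"`.
#' @param n_perm number of cyclic-shift replicates (default 250).
#' @param seed integer seed.
#' @return A one-row `peak_call` tibble: direction, peak_marker, chrom,
#'   pos, statistic, p_value, n_perm.
#' @export
cyclic_shift_peak_test <- function(cohort, direction = c("gain", "loss"),
                                   n_perm = 250, seed = 1L) {
  stopifnot(inherits(cohort, "cn_cohort"))
  direction <- match.arg(direction)
  if (n_perm < 1) abort("n_perm must be at least 1")
  x <- cohort$values
  obs <- peak_statistic(x, direction)
  n <- nrow(x)
  null_stats <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      offsets <- sample.int(n, ncol(x), replace = TRUE) - 1L
      xs <- cyclic_shift_matrix(x, offsets)
      null_stats[b] <- peak_statistic(xs, direction)$stat
    }
  })
  extreme <- if (direction == "gain") null_stats >= obs$stat else null_stats <= obs$stat
  p <- (1 + sum(extreme)) / (1 + n_perm)
  tibble::tibble(direction = direction,
                 peak_marker = cohort$markers$marker_id[obs$marker],
                 chrom = cohort$markers$chrom[obs$marker],
                 pos = cohort$markers$pos[obs$marker],
                 statistic = unname(obs$stat), p_value = p, n_perm = n_perm)
}

#' Bootstrap confidence interval for a peak location
#'
#' Resamples the cohort's samples with replacement `n_boot` times, records
#' the peak marker of each bootstrap cohort within the observed peak's
#' chromosome, and returns the genome-ordered interval between the
#' (1 - level)/2 and 1 - (1 - level)/2 quantiles of the bootstrap peak
#' positions. The interval always contains the observed peak.
#'
#' @param cohort a smoothed, centered `cn_cohort`.
#' @param direction `"gain"` or `"loss"`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return A one-row tibble: peak_marker, ci_left, ci_right (marker ids),
#'   ci_left_pos, ci_right_pos.
#' @export
peak_confidence_interval <- function(cohort, direction = c("gain", "loss"),
                                     level = 0.95, n_boot = 500, seed = 1L) {
  stopifnot(inherits(cohort, "cn_cohort"))
  direction <- match.arg(direction)
  x <- cohort$values
  obs <- peak_statistic(x, direction)
  chrom <- cohort$markers$chrom[obs$marker]
  on_chrom <- which(cohort$markers$chrom == chrom)
  xc <- x[on_chrom, , drop = FALSE]
  boot_peaks <- integer(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(xc), replace = TRUE)
      boot_peaks[b] <- peak_statistic(xc[, cols, drop = FALSE], direction)$marker
    }
  })
  qs <- quantile(boot_peaks, c((1 - level) / 2, 1 - (1 - level) / 2), type = 1)
  obs_local <- match(obs$marker, on_chrom)
  left <- on_chrom[min(qs[1], obs_local)]
  right <- on_chrom[max(qs[2], obs_local)]
  tibble::tibble(peak_marker = cohort$markers$marker_id[obs$marker],
                 ci_left = cohort$markers$marker_id[left],
                 ci_right = cohort$markers$marker_id[right],
                 ci_left_pos = cohort$markers$pos[left],
                 ci_right_pos = cohort$markers$pos[right])
}

# Remove a detected peak's signal: in every carrier sample (value at the
# peak above 0 for gains / below for losses), the contiguous run around the
# peak on which the sample stays above (below) background is reset to the
# sample's chromosome median.
peel_peak <- function(cohort, marker_idx, direction) {
  x <- cohort$values
  chrom <- cohort$markers$chrom[marker_idx]
  on_chrom <- which(cohort$markers$chrom == chrom)
  local <- match(marker_idx, on_chrom)
  for (j in seq_len(ncol(x))) {
    v <- x[on_chrom, j]
    carrier <- if (direction == "gain") v[local] > 0 else v[local] < 0
    if (!carrier) next
    above <- if (direction == "gain") v > 0 else v < 0
    lo <- local; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- local; while (hi < length(v) && above[hi + 1]) hi <- hi + 1
    v[lo:hi] <- median(x[on_chrom, j])
    x[on_chrom, j] <- v
  }
  cohort$values <- x
  cohort
}

#' Iterative peak detection with peeling
#'
#' Runs the cyclic-shift test, and after each significant peak removes its
#' signal (carrier samples' contiguous above-background run around the peak
#' is reset to the sample's chromosome median) before re-testing, so
#' secondary independent peaks can surface. Stops at `n_peaks` peaks or the
#' first p >= alpha. Each round also reports the bootstrap confidence
#' interval of its peak.
#'
#' @param cohort a smoothed, centered `cn_cohort`.
#' @param direction `"gain"` or `"loss"`.
#' @param n_peaks maximum peaks to report (default 5).
#' @param alpha significance cutoff per round (default 0.05).
#' @param n_perm cyclic shifts per round.
#' @param n_boot bootstrap replicates for each CI.
#' @param level CI level.
#' @param seed integer master seed (child seeds per round).
#' @return A `peak_call` tibble, one row per significant peak in discovery
#'   order, with columns from both the test and the CI.
#' @export
peel_and_repeat <- function(cohort, direction = c("gain", "loss"),
                            n_peaks = 5, alpha = 0.05, n_perm = 250,
                            n_boot = 500, level = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "cn_cohort"))
  direction <- match.arg(direction)
  seeds <- child_seeds(seed, paste0("round", seq_len(2 * n_peaks)))
  out <- list()
  for (r in seq_len(n_peaks)) {
    call <- cyclic_shift_peak_test(cohort, direction, n_perm = n_perm,
                                   seed = seeds[[2 * r - 1]])
    if (call$p_value >= alpha) break
    ci <- peak_confidence_interval(cohort, direction, level = level,
                                   n_boot = n_boot, seed = seeds[[2 * r]])
    out[[r]] <- dplyr::bind_cols(call, ci[, c("ci_left", "ci_right",
                                              "ci_left_pos", "ci_right_pos")])
    marker_idx <- match(call$peak_marker, cohort$markers$marker_id)
    cohort <- peel_peak(cohort, marker_idx, direction)
  }
  if (length(out) == 0) {
    return(tibble::tibble(direction = character(), peak_marker = character(),
                          chrom = character(), pos = numeric(),
                          statistic = numeric(), p_value = numeric(),
                          n_perm = integer(), ci_left = character(),
                          ci_right = character(), ci_left_pos = numeric(),
                          ci_right_pos = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Gene-level segmented copy number
#'
#' The mean of the per-sample segmented values at markers lying inside the
#' gene plus the nearest flanking marker on each side ("immediately
#' adjacent"), all weighted equally.
#'
#' @param seg_values marker-by-sample matrix from
#'   [segmented_marker_values()].
#' @param markers cohort marker map.
#' @param gene one-row list/tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param flank number of adjacent markers per side (default 1).
#' @param max_gap error if no marker lies within this distance of the gene
#'   (default 1e6 bp).
#' @return Named per-sample numeric vector.
#' @export
gene_level_copy_number <- function(seg_values, markers, gene, flank = 1,
                                   max_gap = 1e6) {
  if (gene$start >= gene$end) abort("gene start must precede end")
  on_chrom <- which(markers$chrom == gene$chrom)
  if (length(on_chrom) == 0) abort(paste0("no markers on ", gene$chrom))
  pos <- markers$pos[on_chrom]
  inside <- on_chrom[pos >= gene$start & pos <= gene$end]
  left <- on_chrom[pos < gene$start]
  right <- on_chrom[pos > gene$end]
  use <- c(if (flank > 0 && length(left)) tail(left, flank),
           inside,
           if (flank > 0 && length(right)) head(right, flank))
  if (length(use) == 0 ||
      min(abs(c(markers$pos[use] - gene$start, markers$pos[use] - gene$end))) > max_gap)
    abort(paste0("no markers within ", max_gap, " bp of gene ", gene$gene_id))
  colMeans(seg_values[use, , drop = FALSE])
}

#' Call a gene-level gain/loss event
#'
#' Gain if the gene-level value exceeds `+threshold`, loss if below
#' `-threshold` (about two SDs of segmented values at the default 0.35);
#' boundary values are neutral (strict inequalities).
#'
#' @param value numeric vector of gene-level segmented copy numbers.
#' @param threshold call threshold in log2 units (default 0.35).
#' @return Character vector: `"gain"`, `"neutral"` or `"loss"`.
#' @export
call_gene_event <- function(value, threshold = 0.35) {
  if (any(!is.finite(value))) abort("gene-level values must be finite")
  ifelse(value > threshold, "gain", ifelse(value < -threshold, "loss", "neutral"))
}

#' Chromosomal instability index
#'
#' Per sample: the median over chromosome arms of the arm-wise median
#' absolute smoothed segmented value. Homogeneous (all-zero) genomes score
#' 0; the index scales linearly with the magnitude of the profile.
#'
#' @param values marker-by-sample matrix of smoothed segmented values.
#' @param arm_map character vector assigning each marker row to an arm.
#' @return A tibble: sample_id, cin.
#' @export
chromosomal_instability_index <- function(values, arm_map) {
  if (length(arm_map) != nrow(values)) abort("arm_map must cover every marker")
  arms <- split(seq_len(nrow(values)), arm_map)
  empty <- lengths(arms) == 0
  if (any(empty)) {
    warn(paste0("excluding empty arm(s): ", paste(names(arms)[empty], collapse = ", ")))
    arms <- arms[!empty]
  }
  cin <- vapply(seq_len(ncol(values)), function(j) {
    arm_med <- vapply(arms, function(idx) median(abs(values[idx, j])), numeric(1))
    median(arm_med)
  }, numeric(1))
  tibble::tibble(sample_id = colnames(values) %||% as.character(seq_along(cin)),
                 cin = cin)
}

#' Kruskal-Wallis association of a copy-number region with subtype
#'
#' Averages each sample's smoothed centered values over the region's
#' markers and tests the per-sample means across subtypes with the
#' Kruskal-Wallis rank test. An optional Bonferroni adjustment over the
#' number of regions examined is applied when `n_regions > 1`.
#'
#' @param cohort a smoothed, centered `cn_cohort`.
#' @param labels subtype label per sample (>= 2 subtypes).
#' @param region marker-index vector, or list/tibble row with `chrom`,
#'   `start`, `end`.
#' @param n_regions Bonferroni denominator (default 1 = unadjusted).
#' @return A one-row tibble: statistic, df, p_value, p_adjusted, n.
#' @export
region_subtype_association <- function(cohort, labels, region, n_regions = 1) {
  stopifnot(inherits(cohort, "cn_cohort"))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) abort("at least two subtypes are required")
  idx <- if (is.numeric(region)) as.integer(region) else {
    which(cohort$markers$chrom == region$chrom &
          cohort$markers$pos >= region$start & cohort$markers$pos <= region$end)
  }
  if (length(idx) == 0) abort("region covers no markers")
  means <- colMeans(cohort$values[idx, , drop = FALSE])
  kw <- kruskal_wallis(split(means, labels))
  kw$p_adjusted <- pmin(1, kw$p_value * n_regions)
  kw$n <- length(means)
  kw
}
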