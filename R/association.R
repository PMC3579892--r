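#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact p-value by the network algorithm: the probability mass
#' of all tables with the observed margins whose hypergeometric probability
#' does not exceed that of the observed table. Tables too large for exact
#' enumeration raise an error directing to [fisher_monte_carlo()].
#'
#' @param counts non-negative integer matrix with at least 2 rows and 2
#'   columns of positive margin.
#' @param workspace network-algorithm workspace (default 2e7).
#' @return A one-row tibble: method, p_value.
#' @export
fisher_exact_rxc <- function(counts, workspace = 2e7) {
  counts <- validate_table(counts)
  p <- tryCatch(
    fisher.test(counts, workspace = workspace)$p.value,
    error = function(e) {
      abort(paste0("exact enumeration infeasible for this table (",
                   conditionMessage(e),
                   "); use fisher_monte_carlo() instead"))
    })
  tibble::tibble(method = "fisher_exact", p_value = p)
}

#' Monte-Carlo Fisher's exact test
#'
#' Estimates the two-sided Fisher p-value by sampling margin-fixed tables
#' and applying the add-one estimator p = (1 + #\{table prob <= observed\})
#' / (1 + n_sim). The binomial Monte-Carlo standard error is reported.
#'
#' @param counts contingency table as in [fisher_exact_rxc()].
#' @param n_sim simulated tables (>= 1000; default 1e5).
#' @param seed integer seed.
#' @return A one-row tibble: method, p_value, mc_se, n_sim.
#' @export
fisher_monte_carlo <- function(counts, n_sim = 1e5, seed = 1L) {
  counts <- validate_table(counts)
  if (n_sim < 1000) abort("n_sim must be at least 1000")
  p <- with_seed(seed,
    fisher.test(counts, simulate.p.value = TRUE, B = n_sim)$p.value)
  tibble::tibble(method = "fisher_monte_carlo", p_value = p,
                 mc_se = sqrt(p * (1 - p) / n_sim), n_sim = n_sim)
}

validate_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    abort("table needs at least 2 rows and 2 columns with positive margins")
  counts
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank statistic H referred to a chi-squared distribution
#' with (#groups - 1) degrees of freedom. Invariant to any strictly
#' increasing transformation of the pooled values. When every value is
#' identical the statistic is defined as 0 with p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups, total n >=
#'   3).
#' @return A one-row tibble: statistic, df, p_value.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("at least two groups are required")
  if (any(lengths(groups) == 0)) abort("every group must be non-empty")
  if (sum(lengths(groups)) < 3) abort("total sample size must be at least 3")
  pooled <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1
  if (length(unique(pooled)) == 1)
    return(tibble::tibble(statistic = 0, df = df, p_value = 1))
  kt <- kruskal.test(groups)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' SAM-style two-class permutation differential expression
#'
#' For each gene, a moderated difference statistic d = (mean_1 - mean_2) /
#' (pooled SE + s0) is computed, with the fudge factor s0 defaulting to the
#' median per-gene pooled SE. The null distribution of d comes from label
#' permutations. Calling compares the ordered observed statistics with
#' their expected order statistics under the permutation null: for a band
#' half-width delta, the upper (lower) cut is the smallest (largest)
#' observed d whose deviation from its expected order statistic reaches
#' +delta (-delta), and genes beyond the cuts are called. The median false
#' discovery rate of a band is the median over permutations of the null
#' count beyond the cuts divided by the number called; the smallest delta
#' whose median FDR stays at or below `fdr_threshold` defines the called
#' set.
#'
#' @param x gene-by-sample matrix.
#' @param labels two-class label per sample (first sorted level is class
#'   1); each class needs >= 2 samples.
#' @param n_perm label permutations (default 1000).
#' @param fdr_threshold median-FDR ceiling for the called set (default
#'   0.01).
#' @param s0 optional fudge-factor override.
#' @param seed integer seed.
#' @return A `sam_result`: per-gene tibble (gene_id, d, called) plus
#'   cutoff, median FDR and counts, accessible via [generics::tidy()] /
#'   [generics::glance()].
#' @export
sam_two_class <- function(x, labels, n_perm = 1000, fdr_threshold = 0.01,
                          s0 = NULL, seed = 1L) {
  assert_matrix(x, "expression matrix")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("exactly two classes are required")
  if (any(table(labels) < 2)) abort("each class needs at least two samples")
  d_fun <- function(lab) {
    i1 <- lab == classes[1]; i2 <- !i1
    n1 <- sum(i1); n2 <- sum(i2)
    m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
    ss <- rowSums((x[, i1, drop = FALSE] - m1)^2) +
          rowSums((x[, i2, drop = FALSE] - m2)^2)
    se <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
    list(num = m1 - m2, se = se)
  }
  obs <- d_fun(labels)
  if (is.null(s0)) s0 <- median(obs$se)
  d <- obs$num / (obs$se + s0)
  n_genes <- nrow(x)
  null_sorted <- matrix(0, n_genes, n_perm)        # each column sorted ascending
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      pb <- d_fun(perm)
      null_sorted[, b] <- sort(pb$num / (pb$se + s0))
    }
  })
  d_sorted <- sort(d)
  d_expected <- rowMeans(null_sorted)              # expected order statistics
  dev <- d_sorted - d_expected
  mid <- which.min(abs(d_sorted - median(d_sorted)))
  upper <- seq(mid, n_genes); lower <- seq(1, mid)
  deltas <- sort(unique(c(dev[upper][dev[upper] > 0],
                          -dev[lower][dev[lower] < 0])))
  if (length(deltas) > 300)                        # band grid, finest first
    deltas <- unique(quantile(deltas, seq(0, 1, length.out = 300), type = 1))
  band <- function(delta) {
    iu <- upper[dev[upper] >= delta]
    il <- lower[dev[lower] <= -delta]
    list(cutup = if (length(iu)) d_sorted[min(iu)] else Inf,
         cutlow = if (length(il)) d_sorted[max(il)] else -Inf)
  }
  count_beyond <- function(cutup, cutlow) {
    # per permutation column (sorted), nulls >= cutup plus nulls <= cutlow
    vapply(seq_len(n_perm), function(b) {
      col <- null_sorted[, b]
      (n_genes - findInterval(cutup, col, left.open = TRUE)) +
        findInterval(cutlow, col)
    }, numeric(1))
  }
  pick <- NULL
  for (delta in deltas) {                          # smallest qualifying delta
    bd <- band(delta)
    n_called <- sum(d >= bd$cutup) + sum(d <= bd$cutlow)
    if (n_called == 0) break
    fdr <- median(count_beyond(bd$cutup, bd$cutlow)) / n_called
    if (fdr <= fdr_threshold) {
      pick <- list(delta = delta, cutup = bd$cutup, cutlow = bd$cutlow,
                   fdr = fdr, n_called = n_called)
      break
    }
  }
  if (is.null(pick)) {
    called <- rep(FALSE, n_genes)
    pick <- list(delta = Inf, cutup = Inf, cutlow = -Inf, fdr = 0, n_called = 0)
  } else {
    called <- d >= pick$cutup | d <= pick$cutlow
  }
  structure(list(
    genes = tibble::tibble(gene_id = rownames(x), d = unname(d), called = called),
    cutoff = pick$delta, cutup = pick$cutup, cutlow = pick$cutlow,
    median_fdr = pick$fdr, n_called = pick$n_called,
    s0 = s0, n_perm = n_perm, fdr_threshold = fdr_threshold
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("<sam_result> ", nrow(x$genes), " genes, ", x$n_called,
      " called at |d| >= ", signif(x$cutoff, 4), " (median FDR ",
      signif(x$median_fdr, 3), " <= ", x$fdr_threshold, ", ", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group and the log-rank chi-squared
#' statistic across groups with (#groups - 1) degrees of freedom. Data with
#' no observed events cannot be compared and raise a "no events" error.
#'
#' @param data data frame with one row per subject.
#' @param time,event,group column names for follow-up time (months), event
#'   flag (1 = death/recurrence, 0 = censored) and the grouping variable.
#' @return A `km_logrank` object; `tidy()` gives the per-group survival
#'   curve tibble and `glance()` the statistic, df and p-value.
#' @export
km_logrank <- function(data, time = "rfs_months", event = "event",
                       group = "subtype") {
  if (!all(c(time, event, group) %in% names(data)))
    abort("time, event and group columns must exist in data")
  t <- data[[time]]; e <- data[[event]]; g <- as.character(data[[group]])
  if (any(t < 0)) abort("follow-up times must be non-negative")
  if (!all(e %in% c(0, 1))) abort("event flags must be 0 or 1")
  if (length(unique(g)) < 2) abort("at least two groups are required")
  if (sum(e) == 0) abort("no events: the log-rank test is undefined")
  df_surv <- data.frame(t = t, e = e, g = g)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df_surv)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df_surv)
  df <- length(sd$n) - 1
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  structure(list(fit = fit, statistic = unname(sd$chisq), df = df,
                 p_value = p, groups = sort(unique(g))),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("<km_logrank> ", length(x$groups), " groups; chi-squared = ",
      signif(x$statistic, 4), " on ", x$df, " df, p = ",
      signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Build a contingency table of subtype against a clinical covariate
#'
#' Rows with a missing covariate value are excluded (never imputed), which
#' is why published category counts need not sum to the cohort size.
#'
#' @param clinical clinical tibble.
#' @param covariate covariate column name.
#' @param subtype subtype column name.
#' @return An integer matrix (covariate categories x subtypes).
#' @export
subtype_contingency <- function(clinical, covariate, subtype = "subtype") {
  keep <- !is.na(clinical[[covariate]]) & !is.na(clinical[[subtype]])
  as.matrix(table(clinical[[covariate]][keep], clinical[[subtype]][keep]))
}
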