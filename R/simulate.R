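#' Simulate a subtyped gene-expression cohort
#'
#' Draws a gene-by-sample log2 expression matrix in which each subtype is a
#' gene-wise mean shift over independent Gaussian noise: every informative
#' gene carries a `+effect_size` shift in exactly one subtype and pure noise
#' elsewhere. Subtype labels are balanced up to rounding. The generator is a
#' pure function of the config (identical seed, identical output).
#'
#' @param config a [sim_config()].
#' @return A list with `matrix` (genes x samples), `labels` (integer subtype
#'   per sample, named by sample id), and `informative_genes` (tibble of
#'   gene_id, subtype).
#' @export
simulate_subtyped_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(config$seed, c("expression", "cn", "clinical"))
  n <- config$n_samples; g <- config$n_genes; k <- config$n_subtypes
  m <- config$n_informative_genes_per_subtype
  gene_ids <- sprintf("g%05d", seq_len(g))
  sample_ids <- sprintf("s%03d", seq_len(n))
  labels <- setNames(rep(seq_len(k), length.out = n), sample_ids)
  with_seed(seeds[["expression"]], {
    info_idx <- sample.int(g, m * k)
    info_class <- rep(seq_len(k), each = m)
    x <- matrix(rnorm(g * n, mean = 0, sd = config$noise_sd), nrow = g,
                dimnames = list(gene_ids, sample_ids))
    for (c in seq_len(k)) {
      rows <- info_idx[info_class == c]
      cols <- which(labels == c)
      x[rows, cols] <- x[rows, cols] + config$effect_size
    }
  })
  list(
    matrix = x,
    labels = labels,
    informative_genes = tibble::tibble(gene_id = gene_ids[info_idx],
                                       subtype = info_class)
  )
}

#' Simulate a marker-level copy-number cohort with planted aberrations
#'
#' Builds the marker map from the config genome (equally spaced markers per
#' chromosome), then for each planted event draws carriers at
#' `carrier_fraction` within the affected subtypes and adds the event
#' amplitude over its covered markers; independent Gaussian marker noise is
#' added on top. Ground truth (carriers and true marker intervals) is
#' returned alongside the data.
#'
#' @param config a [sim_config()].
#' @param labels integer subtype labels, one per sample (length defines the
#'   number of CN samples, which may differ from the expression cohort).
#' @return A list with `cohort` (a [cn_cohort()]) and `truth` (tibble of
#'   event, direction, chrom, start, end, amplitude, first/last covered
#'   marker index, carriers list column).
#' @export
simulate_copy_number_cohort <- function(config, labels) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(config$seed, c("expression", "cn", "clinical"))
  genome <- config$genome
  markers <- genome_markers(genome)
  n <- length(labels)
  sample_ids <- names(labels) %||% sprintf("s%03d", seq_len(n))
  ev <- config$cn_events
  if (!is.null(ev) && nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      row <- genome[genome$chrom == ev$chrom[i], ]
      if (nrow(row) == 0 || ev$start[i] < 0 || ev$end[i] > row$length)
        abort(paste0("event ", i, " coordinates fall outside the genome"))
    }
  }
  truth <- NULL
  with_seed(seeds[["cn"]], {
    x <- matrix(rnorm(nrow(markers) * n, sd = config$cn_noise_sd),
                nrow = nrow(markers),
                dimnames = list(markers$marker_id, sample_ids))
    if (!is.null(ev) && nrow(ev) > 0) {
      rows <- vector("list", nrow(ev))
      for (i in seq_len(nrow(ev))) {
        covered <- which(markers$chrom == ev$chrom[i] &
                         markers$pos >= ev$start[i] & markers$pos <= ev$end[i])
        eligible <- if (is.null(ev$subtypes[[i]])) seq_len(n) else
          which(labels %in% ev$subtypes[[i]])
        carriers <- eligible[runif(length(eligible)) < ev$carrier_fraction[i]]
        if (length(covered) > 0 && length(carriers) > 0)
          x[covered, carriers] <- x[covered, carriers] + ev$amplitude[i]
        rows[[i]] <- tibble::tibble(
          event = i, direction = ev$direction[i], chrom = ev$chrom[i],
          start = ev$start[i], end = ev$end[i], amplitude = ev$amplitude[i],
          first_marker = if (length(covered)) min(covered) else NA_integer_,
          last_marker = if (length(covered)) max(covered) else NA_integer_,
          carriers = list(sample_ids[carriers])
        )
      }
      truth <- dplyr::bind_rows(rows)
    }
  })
  list(cohort = cn_cohort(markers, x), truth = truth)
}

# Deterministic marker map: equally spaced positions within each chromosome.
genome_markers <- function(genome) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    nm <- genome$n_markers[i]
    pos <- round(seq(genome$length[i] / (nm + 1), genome$length[i] * nm / (nm + 1),
                     length.out = nm))
    tibble::tibble(chrom = genome$chrom[i], pos = pos,
                   arm = paste0(genome$chrom[i],
                                ifelse(pos <= genome$arm_boundary[i], "p", "q")))
  })
  out <- dplyr::bind_rows(rows)
  out$marker_id <- sprintf("m%05d", seq_len(nrow(out)))
  out[, c("marker_id", "chrom", "pos", "arm")]
}

#' Simulate subtype-linked clinical covariates and survival outcomes
#'
#' Categorical covariates are drawn from the config's subtype-conditional
#' category probabilities. Recurrence-free survival times are exponential
#' with a per-subtype hazard (events/month); censoring is independent: with
#' probability `censoring_rate` a subject is censored at a uniform time
#' before its event, otherwise the event is observed (flag 1 = death or
#' recurrence, 0 = censored).
#'
#' @param config a [sim_config()].
#' @param labels integer subtype labels per sample.
#' @return A tibble with sample_id, subtype, one column per covariate,
#'   `rfs_months` and `event`.
#' @export
simulate_clinical_outcomes <- function(config, labels) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(config$seed, c("expression", "cn", "clinical"))
  n <- length(labels)
  sample_ids <- names(labels) %||% sprintf("s%03d", seq_len(n))
  hz <- config$survival$hazard
  if (length(hz) < config$n_subtypes || anyNA(hz[unique(labels)]))
    abort("missing hazard rate for at least one subtype")
  cens <- config$survival$censoring_rate
  with_seed(seeds[["clinical"]], {
    covs <- lapply(config$clinical_effects, function(pr) {
      cats <- rownames(pr)
      vapply(labels, function(l) sample(cats, 1, prob = pr[, l]), character(1))
    })
    event_time <- rexp(n, rate = hz[labels])
    censored <- runif(n) < cens
    time <- ifelse(censored, runif(n) * event_time, event_time)
    out <- tibble::tibble(sample_id = sample_ids, subtype = as.integer(labels))
    for (nm in names(covs)) out[[nm]] <- unname(covs[[nm]])
    out$rfs_months <- time
    out$event <- as.integer(!censored)
  })
  out
}
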