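#' Default synthetic genome for copy-number simulation
#'
#' Five chromosomes with equally spaced markers; the arm boundary splits each
#' chromosome into a p and a q arm. Marker positions are deterministic given
#' the genome, so identical configs always map events to identical markers.
#'
#' @param n_chrom number of chromosomes.
#' @param n_markers markers per chromosome.
#' @param length_bp chromosome length in base pairs.
#' @return A tibble with columns `chrom`, `arm_boundary`, `n_markers`, `length`.
#' @export
default_genome <- function(n_chrom = 5, n_markers = 200, length_bp = 2e8) {
  tibble::tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    arm_boundary = round(length_bp * 0.45),
    n_markers = as.integer(n_markers),
    length = as.numeric(length_bp)
  )
}

#' Simulation configuration for synthetic subtype cohorts
#'
#' Bundles every parameter of the synthetic cohort: expression dimensions and
#' planted subtype structure, the copy-number genome and planted gain/loss
#' events, subtype-conditional clinical covariates, and per-subtype survival
#' hazards. The defaults emulate a bulk tumor expression cohort of 138
#' samples by 15597 genes carrying 4 subtypes as gene-wise mean shifts over
#' Gaussian noise, and a 107-sample marker-level copy-number cohort.
#'
#' @param n_samples,n_genes expression cohort dimensions.
#' @param n_subtypes number of planted subtypes (K >= 2).
#' @param n_informative_genes_per_subtype genes carrying a mean shift in
#'   exactly one subtype.
#' @param effect_size mean shift in log2 units for informative genes.
#' @param noise_sd Gaussian noise standard deviation in log2 units.
#' @param genome tibble as produced by [default_genome()].
#' @param cn_events tibble with columns `direction` ("gain"/"loss"), `chrom`,
#'   `start`, `end`, `amplitude` (log2 units, positive for gains, negative
#'   for losses), `carrier_fraction` in \[0,1\], and `subtypes` (list column
#'   of affected subtype integers, or NULL meaning all).
#' @param cn_noise_sd marker-level noise standard deviation in log2 units.
#' @param clinical_effects named list; each element is a category-by-subtype
#'   probability matrix whose columns sum to 1.
#' @param survival list with `hazard` (events/month, one rate per subtype)
#'   and `censoring_rate` in \[0,1\].
#' @param seed integer master seed; expanded into independent child seeds for
#'   the expression, copy-number and clinical generators.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 138,
                       n_genes = 15597,
                       n_subtypes = 4,
                       n_informative_genes_per_subtype = 50,
                       effect_size = 2,
                       noise_sd = 1,
                       genome = default_genome(),
                       cn_events = default_cn_events(),
                       cn_noise_sd = 0.2,
                       clinical_effects = default_clinical_effects(n_subtypes),
                       survival = list(hazard = rep(0.02, n_subtypes),
                                       censoring_rate = 0.3),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_subtypes = as.integer(n_subtypes),
    n_informative_genes_per_subtype = as.integer(n_informative_genes_per_subtype),
    effect_size = effect_size, noise_sd = noise_sd,
    genome = genome, cn_events = cn_events, cn_noise_sd = cn_noise_sd,
    clinical_effects = clinical_effects, survival = survival,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_samples, cfg$n_genes, cfg$n_subtypes,
              cfg$n_informative_genes_per_subtype)
  if (any(counts <= 0)) abort("all counts in a sim_config must be positive")
  if (cfg$n_subtypes < 2) abort("n_subtypes must be at least 2")
  if (cfg$n_informative_genes_per_subtype * cfg$n_subtypes > cfg$n_genes)
    abort("invalid configuration: informative genes per subtype x subtypes exceeds n_genes")
  if (cfg$noise_sd < 0 || cfg$cn_noise_sd < 0) abort("noise SDs must be non-negative")
  ev <- cfg$cn_events
  if (!is.null(ev) && nrow(ev) > 0) {
    if (any(!ev$direction %in% c("gain", "loss")))
      abort("cn_events direction must be 'gain' or 'loss'")
    if (any(ev$carrier_fraction < 0 | ev$carrier_fraction > 1))
      abort("carrier_fraction must lie in [0, 1]")
    if (any(ev$amplitude[ev$direction == "gain"] <= 0) ||
        any(ev$amplitude[ev$direction == "loss"] >= 0))
      abort("gain amplitudes must be positive and loss amplitudes negative")
  }
  for (nm in names(cfg$clinical_effects)) {
    pr <- cfg$clinical_effects[[nm]]
    if (ncol(pr) != cfg$n_subtypes)
      abort(paste0("clinical effect '", nm, "' needs one column per subtype"))
    if (any(abs(colSums(pr) - 1) > 1e-8))
      abort(paste0("clinical effect '", nm, "' probabilities must sum to 1 per subtype"))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes x ", x$n_samples, " samples, K = ",
      x$n_subtypes, "\n  effect ", x$effect_size, " over noise sd ", x$noise_sd,
      "; ", nrow(x$genome), " chromosomes, ",
      if (is.null(x$cn_events)) 0 else nrow(x$cn_events),
      " planted CN events; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Default planted copy-number events
#'
#' One moderately frequent gain and one loss on separate chromosomes; the
#' gain mirrors a 40-percent-carrier amplicon of amplitude 0.6 log2 units.
#'
#' @return A tibble of events suitable for [sim_config()].
#' @export
default_cn_events <- function() {
  tibble::tibble(
    direction = c("gain", "loss"),
    chrom = c("chr2", "chr4"),
    start = c(8e7, 5e7),
    end = c(1.3e8, 1.0e8),
    amplitude = c(0.6, -0.6),
    carrier_fraction = c(0.4, 0.4),
    subtypes = list(NULL, NULL)
  )
}

#' Default subtype-conditional clinical covariate distributions
#'
#' Two categorical covariates: `site` (four anatomic categories with
#' subtype-skewed usage) and `hpv` (enriched in one subtype), mirroring the
#' kind of subtype/covariate association the analysis is meant to detect.
#'
#' @param k number of subtypes.
#' @return Named list of category-by-subtype probability matrices.
#' @export
default_clinical_effects <- function(k = 4) {
  site <- matrix(1 / 4, nrow = 4, ncol = k,
                 dimnames = list(c("larynx", "oral_cavity", "oropharynx",
                                   "hypopharynx"), NULL))
  if (k >= 2) {
    site[, 1] <- c(0.15, 0.55, 0.15, 0.15)
    site[, 2] <- c(0.25, 0.35, 0.25, 0.15)
  }
  if (k >= 3) site[, 3] <- c(0.1, 0.1, 0.6, 0.2)
  hpv <- matrix(rep(c(0.9, 0.1), k), nrow = 2,
                dimnames = list(c("negative", "positive"), NULL))
  if (k >= 3) hpv[, 3] <- c(0.6, 0.4)
  list(site = site, hpv = hpv)
}
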