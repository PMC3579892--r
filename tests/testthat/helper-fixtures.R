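# Shared in-code fixtures: everything is generated at test time.

# Small expression cohort with planted subtypes.
small_expr <- function(n_samples = 60, n_genes = 500, k = 4,
                       n_info = 50, effect = 2, noise = 1, seed = 1) {
  cfg <- sim_config(n_samples = n_samples, n_genes = n_genes, n_subtypes = k,
                    n_informative_genes_per_subtype = n_info,
                    effect_size = effect, noise_sd = noise, seed = seed)
  simulate_subtyped_expression(cfg)
}

# Marker cohort on two chromosomes with pure Gaussian noise.
noise_cohort <- function(n_markers = 400, n_samples = 40, noise_sd = 0.2,
                         seed = 1) {
  stopifnot(n_markers %% 4 == 0)
  markers <- tibble::tibble(
    marker_id = sprintf("m%04d", seq_len(n_markers)),
    chrom = rep(c("chr1", "chr2"), each = n_markers / 2),
    pos = rep(round(seq(1e6, 2e8, length.out = n_markers / 2)), 2),
    arm = rep(c("chr1p", "chr1q", "chr2p", "chr2q"), each = n_markers / 4))
  set.seed(seed)
  vals <- matrix(rnorm(n_markers * n_samples, sd = noise_sd), n_markers,
                 dimnames = list(markers$marker_id,
                                 sprintf("s%03d", seq_len(n_samples))))
  cn_cohort(markers, vals)
}

# Add a rectangular event to a cohort in place.
plant_event <- function(cohort, marker_range, samples, amplitude) {
  cohort$values[marker_range, samples] <-
    cohort$values[marker_range, samples] + amplitude
  cohort
}

expr_matrix <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a
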