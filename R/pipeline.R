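#' Run the expression subtype discovery workflow
#'
#' Orchestrates preprocessing (gene median centering, top-MAD gene
#' selection), resampled consensus clustering with model selection,
#' pairwise Monte-Carlo cluster significance, silhouette core-sample
#' selection and balanced nearest-centroid classifier training. Every
#' stochastic stage receives a child seed derived from `seed`, so a config
#' plus seed reproduces the run bit-for-bit. When `outdir` is given, all
#' artifacts plus a JSON manifest are written there; inputs are never
#' mutated on disk.
#'
#' @param x raw gene-by-sample log2 expression matrix.
#' @param top_n_genes variable genes to keep (default 2500).
#' @param k_range cluster counts to examine.
#' @param n_resamples,item_fraction consensus clustering parameters.
#' @param n_sim cluster-significance simulations per pair.
#' @param genes_per_class classifier gene-count grid (scalar to skip the CV
#'   search).
#' @param cv_folds classifier cross-validation folds.
#' @param seed integer master seed.
#' @param outdir optional output directory.
#' @return A list: `prepped` matrix, `consensus`, `k_selection`, `labels`
#'   (at the recommended k), `significance` tibble, `silhouette` tibble,
#'   `model`, `manifest`.
#' @export
run_discovery <- function(x, top_n_genes = 2500, k_range = 2:6,
                          n_resamples = 1000, item_fraction = 0.8,
                          n_sim = 1000,
                          genes_per_class = c(50, 100, 150, 210, 300),
                          cv_folds = 5, seed = 1L, outdir = NULL) {
  assert_matrix(x, "expression matrix")
  seeds <- child_seeds(seed, c("consensus", "sigclust", "classifier"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
  }
  prepped <- stage("prep", {
    select_top_variable_genes(median_center_genes(x),
                              min(top_n_genes, nrow(x)))
  })
  consensus <- stage("consensus_cluster", {
    consensus_cluster(prepped, k_range = k_range, n_resamples = n_resamples,
                      item_fraction = item_fraction, seed = seeds[["consensus"]])
  })
  k_sel <- stage("select_k", select_k(consensus))
  labels <- consensus_labels(consensus, k_sel$recommended_k)
  significance <- stage("sigclust_all_pairs", {
    sigclust_all_pairs(prepped, labels, n_sim = n_sim, seed = seeds[["sigclust"]])
  })
  sil <- stage("silhouette_core_samples", silhouette_core_samples(prepped, labels))
  core <- sil$core
  model <- stage("train_nearest_centroid_classifier", {
    train_nearest_centroid_classifier(prepped[, core, drop = FALSE],
                                      labels[core],
                                      genes_per_class = genes_per_class,
                                      cv_folds = cv_folds,
                                      seed = seeds[["classifier"]])
  })
  manifest <- list(
    workflow = "discovery",
    package_version = as.character(utils::packageVersion("subtypeforge")),
    seed = seed,
    params = list(top_n_genes = top_n_genes, k_range = k_range,
                  n_resamples = n_resamples, item_fraction = item_fraction,
                  n_sim = n_sim, genes_per_class = genes_per_class,
                  cv_folds = cv_folds),
    input = list(n_genes = nrow(x), n_samples = ncol(x),
                 checksum = input_checksum(x)),
    recommended_k = k_sel$recommended_k, stable = k_sel$stable,
    n_core = sum(core)
  )
  res <- list(prepped = prepped, consensus = consensus, k_selection = k_sel,
              labels = labels, significance = significance, silhouette = sil,
              model = model, manifest = manifest)
  if (!is.null(outdir)) write_discovery_artifacts(res, outdir)
  res
}

#' Run the copy-number characterization workflow
#'
#' Orchestrates missing-marker imputation, smoothing and median centering,
#' iterative peel-and-repeat peak detection with bootstrap confidence
#' intervals in both directions, segmentation, gene-level event calling,
#' the chromosomal instability index, and Kruskal-Wallis association of
#' each significant peak's confidence region with the subtype labels.
#'
#' @param cohort a `cn_cohort` (raw marker-level values).
#' @param labels subtype labels for the cohort's samples (used for region
#'   association; samples absent from `labels` are skipped there).
#' @param genes optional tibble of gene regions (gene_id, chrom, start,
#'   end) for gene-level calls.
#' @param n_peaks,alpha,n_perm,n_boot,level peak detection parameters.
#' @param threshold gene-level gain/loss call threshold (default 0.35).
#' @param seed integer master seed.
#' @param outdir optional output directory.
#' @return A list: `cohort` (smoothed, centered), `peaks`, `segments`,
#'   `gene_calls`, `cin`, `region_associations`, `manifest`.
#' @export
run_cn_analysis <- function(cohort, labels = NULL, genes = NULL,
                            n_peaks = 5, alpha = 0.05, n_perm = 250,
                            n_boot = 500, level = 0.95, threshold = 0.35,
                            seed = 1L, outdir = NULL) {
  stopifnot(inherits(cohort, "cn_cohort"))
  seeds <- child_seeds(seed, c("gain", "loss"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
  }
  smoothed <- stage("smooth_and_center", {
    smooth_and_center_profiles(impute_missing_markers(cohort))
  })
  peaks <- stage("peel_and_repeat", {
    dplyr::bind_rows(
      peel_and_repeat(smoothed, "gain", n_peaks = n_peaks, alpha = alpha,
                      n_perm = n_perm, n_boot = n_boot, level = level,
                      seed = seeds[["gain"]]),
      peel_and_repeat(smoothed, "loss", n_peaks = n_peaks, alpha = alpha,
                      n_perm = n_perm, n_boot = n_boot, level = level,
                      seed = seeds[["loss"]]))
  })
  segments <- stage("segment_profiles", segment_profiles(smoothed))
  seg_values <- segmented_marker_values(segments, smoothed$markers)
  gene_calls <- NULL
  if (!is.null(genes) && nrow(genes) > 0) {
    gene_calls <- stage("gene_calls", {
      rows <- lapply(seq_len(nrow(genes)), function(i) {
        vals <- gene_level_copy_number(seg_values, smoothed$markers, genes[i, ])
        tibble::tibble(gene_id = genes$gene_id[i],
                       sample_id = names(vals), value = unname(vals),
                       call = call_gene_event(vals, threshold))
      })
      dplyr::bind_rows(rows)
    })
  }
  cin <- stage("cin", {
    chromosomal_instability_index(seg_values, smoothed$markers$arm)
  })
  region_assoc <- NULL
  if (!is.null(labels) && nrow(peaks) > 0) {
    shared <- intersect(colnames(smoothed$values), names(labels))
    region_assoc <- stage("region_association", {
      sub <- smoothed
      sub$values <- sub$values[, shared, drop = FALSE]
      rows <- lapply(seq_len(nrow(peaks)), function(i) {
        region <- list(chrom = peaks$chrom[i], start = peaks$ci_left_pos[i],
                       end = peaks$ci_right_pos[i])
        out <- region_subtype_association(sub, labels[shared], region,
                                          n_regions = nrow(peaks))
        dplyr::bind_cols(peaks[i, c("direction", "peak_marker", "chrom")], out)
      })
      dplyr::bind_rows(rows)
    })
  }
  manifest <- list(
    workflow = "copy_number",
    package_version = as.character(utils::packageVersion("subtypeforge")),
    seed = seed,
    params = list(n_peaks = n_peaks, alpha = alpha, n_perm = n_perm,
                  n_boot = n_boot, level = level, threshold = threshold),
    input = list(n_markers = nrow(cohort$values),
                 n_samples = ncol(cohort$values),
                 checksum = input_checksum(cohort$values)),
    n_significant_peaks = nrow(peaks)
  )
  res <- list(cohort = smoothed, peaks = peaks, segments = segments,
              gene_calls = gene_calls, cin = cin,
              region_associations = region_assoc, manifest = manifest)
  if (!is.null(outdir)) write_cn_artifacts(res, outdir)
  res
}

# Cheap deterministic content fingerprint for run manifests.
input_checksum <- function(x) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  paste0(nrow(x), "x", ncol(x), ":",
         format(sum(v), digits = 15), ":", format(sum(v^2), digits = 15))
}

write_discovery_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_labels(res$labels, file.path(outdir, "labels.tsv"))
  readr::write_tsv(res$significance, file.path(outdir, "significance.tsv"))
  readr::write_tsv(res$silhouette, file.path(outdir, "silhouette.tsv"))
  readr::write_tsv(res$consensus$diagnostics, file.path(outdir, "consensus_diagnostics.tsv"))
  for (k in res$consensus$k_range) {
    m <- res$consensus$consensus[[as.character(k)]]
    readr::write_tsv(tibble::as_tibble(m, rownames = "sample_id"),
                     file.path(outdir, paste0("consensus_k", k, ".tsv")))
  }
  write_subtype_model(res$model, file.path(outdir, "model.json"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}

write_cn_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$peaks, file.path(outdir, "peaks.tsv"))
  readr::write_tsv(res$segments, file.path(outdir, "segments.tsv"))
  readr::write_tsv(res$cin, file.path(outdir, "cin.tsv"))
  if (!is.null(res$gene_calls))
    readr::write_tsv(res$gene_calls, file.path(outdir, "gene_calls.tsv"))
  if (!is.null(res$region_associations))
    readr::write_tsv(res$region_associations,
                     file.path(outdir, "region_associations.tsv"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}
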