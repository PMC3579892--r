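# On-disk formats: plain TSV throughout, 1-based inclusive coordinates
# (SEG convention); JSON for models and run manifests.

#' Read / write sample subtype labels
#'
#' Two-column TSV: sample_id, subtype.
#'
#' @param path TSV path.
#' @return Named vector of labels (read) or the path (write), invisibly.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), subtype = readr::col_character()))
  setNames(df$subtype, df$sample_id)
}

#' @rdname read_labels
#' @param labels named label vector.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble::tibble(sample_id = names(labels),
                                  subtype = as.character(labels)), path)
  invisible(path)
}

#' Read / write a marker-level copy-number cohort
#'
#' Marker TSV with columns chrom, pos, arm, then one column per sample.
#'
#' @param path TSV path.
#' @return A `cn_cohort` (read) or the path (write), invisibly.
#' @export
read_cn_cohort <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    arm = readr::col_character(), .default = readr::col_double()))
  sample_cols <- setdiff(names(df), c("chrom", "pos", "arm"))
  markers <- tibble::tibble(marker_id = sprintf("m%05d", seq_len(nrow(df))),
                            chrom = df$chrom, pos = df$pos, arm = df$arm)
  values <- as.matrix(df[, sample_cols])
  cn_cohort(markers, values)
}

#' @rdname read_cn_cohort
#' @param cohort a `cn_cohort`.
#' @export
write_cn_cohort <- function(cohort, path) {
  df <- dplyr::bind_cols(cohort$markers[, c("chrom", "pos", "arm")],
                         tibble::as_tibble(cohort$values))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write a clinical table
#'
#' TSV with sample_id, subtype, covariate columns, rfs_months and event.
#' Missing categorical values stay NA; they are excluded per test, never
#' imputed.
#'
#' @param path TSV path.
#' @return A tibble (read) or the path (write), invisibly.
#' @export
read_clinical <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    rfs_months = readr::col_double(), event = readr::col_integer(),
    .default = readr::col_character()))
}

#' @rdname read_clinical
#' @param clinical clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Read BED-style gene or arm annotations
#'
#' TSV with columns name, chrom, start, end (1-based inclusive).
#'
#' @param path TSV path.
#' @return A tibble with those columns.
#' @export
read_regions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double()))
}

#' Serialize / restore a trained subtype model as JSON
#'
#' @param model a `subtype_model`.
#' @param path JSON path.
#' @return The path (write) or a `subtype_model` (read), invisibly.
#' @export
write_subtype_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  payload <- list(
    classes = model$classes,
    genes = model$genes,
    genes_per_class = model$genes_per_class,
    centroids = list(gene_id = rownames(model$centroids),
                     class = colnames(model$centroids),
                     values = lapply(seq_len(ncol(model$centroids)),
                                     function(j) model$centroids[, j])),
    train_gene_mean = as.list(model$train_gene_mean),
    train_gene_sd = as.list(model$train_gene_sd),
    distance_metric = model$distance_metric
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_subtype_model
#' @export
read_subtype_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- p$centroids$values
  centroids <- if (is.matrix(vals)) t(vals) else do.call(cbind, lapply(vals, unlist))
  dimnames(centroids) <- list(p$centroids$gene_id, p$centroids$class)
  structure(list(
    classes = p$classes,
    genes = tibble::as_tibble(p$genes),
    genes_per_class = p$genes_per_class,
    centroids = centroids,
    train_gene_mean = unlist(p$train_gene_mean),
    train_gene_sd = unlist(p$train_gene_sd),
    distance_metric = p$distance_metric,
    cv = NULL
  ), class = "subtype_model")
}
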