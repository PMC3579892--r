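#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Validation is strict: ragged rows, duplicated gene ids and non-numeric
#' cells are rejected with the offending row/column named. Blank cells are
#' rejected unless `impute = TRUE`, in which case they are filled with the
#' gene's median over the non-missing samples.
#'
#' @param path TSV file path.
#' @param impute replace missing cells by the per-gene median instead of
#'   erroring.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, impute = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("expression file needs a header and at least one gene row")
  # sentinel keeps trailing empty fields, which strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  header <- fields[[1]]
  sample_ids <- header[-1]
  ncol_expected <- length(header)
  widths <- lengths(fields[-1])
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1] + 1L
    abort(paste0("ragged row ", bad, ": expected ", ncol_expected,
                 " fields, found ", widths[bad - 1L]))
  }
  gene_ids <- vapply(fields[-1], `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    abort(paste0("duplicated gene id(s): ",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  raw <- t(vapply(fields[-1], function(f) f[-1], character(length(sample_ids))))
  blank <- raw == "" | toupper(raw) == "NA"
  x <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad_cell <- !blank & is.na(x)
  if (any(bad_cell)) {
    idx <- which(bad_cell, arr.ind = TRUE)[1, ]
    abort(paste0("non-numeric value '", raw[bad_cell][1], "' at gene ",
                 gene_ids[idx[1]], ", sample ", sample_ids[idx[2]]))
  }
  if (any(blank)) {
    if (!impute) {
      idx <- which(blank, arr.ind = TRUE)[1, ]
      abort(paste0("missing value at gene ", gene_ids[idx[1]], ", sample ",
                   sample_ids[idx[2]], "; set impute = TRUE to fill with the gene median"))
    }
    for (i in which(rowSums(blank) > 0)) {
      med <- median(x[i, ], na.rm = TRUE)
      if (is.na(med)) abort(paste0("gene ", gene_ids[i], " is entirely missing"))
      x[i, is.na(x[i, ])] <- med
    }
  }
  dimnames(x) <- list(gene_ids, sample_ids)
  x
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  assert_matrix(x, "expression matrix")
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Center every gene at median zero
#'
#' Subtracts each gene's median across samples, the standard pre-clustering
#' normalization for log2 expression. Idempotent, and commutes with any
#' permutation of the sample columns.
#'
#' @param x gene-by-sample numeric matrix.
#' @return Matrix of the same dimensions with every row median exactly 0.
#' @export
median_center_genes <- function(x) {
  assert_matrix(x, "expression matrix")
  x - apply(x, 1, median)
}

#' Per-gene median absolute deviation
#'
#' Unscaled MAD (no Gaussian consistency factor): the median over samples of
#' absolute deviations from the gene's median. Only the ranking matters for
#' variable-gene selection, and any rescaling is rank-invariant.
#'
#' @param x gene-by-sample numeric matrix with at least two samples.
#' @return Named numeric vector of non-negative scores, one per gene.
#' @export
gene_mad <- function(x) {
  assert_matrix(x, "expression matrix")
  if (ncol(x) < 2) abort("MAD needs at least two samples")
  apply(x, 1, function(r) median(abs(r - median(r))))
}

#' Restrict a matrix to its most variable genes
#'
#' Keeps the `n` genes with largest (unscaled) MAD, preserving the original
#' gene order within the selection. Ties at the cutoff are broken by
#' gene-id lexicographic order so the selection is deterministic.
#'
#' @param x gene-by-sample numeric matrix.
#' @param n number of genes to keep (default 2500).
#' @return The matrix restricted to the selected genes.
#' @export
select_top_variable_genes <- function(x, n = 2500) {
  assert_matrix(x, "expression matrix")
  if (n > nrow(x)) abort(paste0("n = ", n, " exceeds the ", nrow(x), " genes available"))
  scores <- gene_mad(x)
  ord <- order(-scores, rownames(x))
  keep <- sort(ord[seq_len(n)])
  x[keep, , drop = FALSE]
}
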