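#' Silhouette widths and core-sample selection
#'
#' For each sample, a(i) is the mean 1 - Pearson distance to the other
#' members of its own subtype and b(i) the smallest mean distance to any
#' other subtype; the silhouette width is (b - a) / max(a, b). Samples with
#' positive width sit closer to their own subtype than to any other and form
#' the "core" used for classifier training.
#'
#' @param x gene-by-sample matrix.
#' @param labels subtype label per sample; every subtype needs >= 2 samples.
#' @return A tibble: sample_id, subtype, sil_width, core.
#' @export
silhouette_core_samples <- function(x, labels) {
  assert_matrix(x, "expression matrix")
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) abort("one label per sample is required")
  sizes <- table(labels)
  if (length(sizes) < 2) abort("at least two subtypes are required")
  if (any(sizes < 2))
    abort(paste0("subtype(s) of size 1: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "),
                 "; intra-class distance is undefined"))
  D <- as.matrix(pearson_dist(x))
  groups <- names(sizes)
  widths <- vapply(seq_len(ncol(x)), function(i) {
    own <- labels[i]
    a <- mean(D[i, labels == own & seq_along(labels) != i])
    b <- min(vapply(setdiff(groups, own),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  tibble::tibble(sample_id = colnames(x), subtype = labels,
                 sil_width = widths, core = widths > 0)
}

# Per-gene class-vs-overall moderated scores on a training matrix.
# t_gc = (mean_c - mean_overall) / (pooled within-class SD + s0).
classifier_scores <- function(x, labels) {
  classes <- sort(unique(labels))
  n <- ncol(x); k <- length(classes)
  overall <- rowMeans(x)
  class_means <- vapply(classes, function(c) rowMeans(x[, labels == c, drop = FALSE]),
                        numeric(nrow(x)))
  within_ss <- rowSums(vapply(classes, function(c) {
    xc <- x[, labels == c, drop = FALSE]
    rowSums((xc - rowMeans(xc))^2)
  }, numeric(nrow(x))))
  pooled_sd <- sqrt(within_ss / (n - k))
  if (all(pooled_sd == 0)) abort("degenerate data: pooled within-class SD is zero for every gene")
  s0 <- median(pooled_sd)
  t_mat <- (class_means - overall) / (pooled_sd + s0)
  dimnames(t_mat) <- list(rownames(x), classes)
  t_mat
}

# Disjoint per-class gene lists: each gene belongs to the class maximizing
# its |t| score, and each class keeps its top genes_per_class by |t|.
select_classifier_genes <- function(t_mat, genes_per_class) {
  assigned <- colnames(t_mat)[max.col(abs(t_mat), ties.method = "first")]
  rows <- lapply(colnames(t_mat), function(c) {
    in_c <- which(assigned == c)
    if (length(in_c) < genes_per_class)
      abort(paste0("class ", c, " has only ", length(in_c),
                   " assigned genes; cannot select ", genes_per_class))
    sc <- abs(t_mat[in_c, c])
    pick <- in_c[order(-sc, rownames(t_mat)[in_c])][seq_len(genes_per_class)]
    tibble::tibble(gene_id = rownames(t_mat)[pick], class = c,
                   score = t_mat[pick, c])
  })
  dplyr::bind_rows(rows)
}

#' Train a balanced nearest-centroid subtype classifier
#'
#' On the core samples, scores every gene against every class with a
#' moderated class-versus-overall t statistic (offset s0 = median pooled
#' within-class SD), assigns each gene to the class maximizing its absolute
#' score (which makes the per-class lists disjoint by construction), and
#' keeps the top `genes_per_class` genes per class. When a grid of
#' `genes_per_class` values is supplied, seeded stratified cross-validation
#' picks the value minimizing the CV misclassification rate. Class centroids
#' are per-class per-gene medians; per-gene training means and SDs are
#' stored for harmonizing external cohorts.
#'
#' @param x gene-by-sample matrix of core samples.
#' @param labels subtype label per core sample.
#' @param genes_per_class single value or grid (default
#'   `c(50, 100, 150, 210, 300)`).
#' @param cv_folds stratified folds (default 5); every class needs at least
#'   `cv_folds` core samples when a grid is searched.
#' @param seed integer seed for fold assignment.
#' @return A `subtype_model`: classes, classifier gene tibble, centroid
#'   matrix, per-gene training mean/SD, the CV error table.
#' @export
train_nearest_centroid_classifier <- function(x, labels,
                                              genes_per_class = c(50, 100, 150, 210, 300),
                                              cv_folds = 5, seed = 1L) {
  assert_matrix(x, "expression matrix")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  cv_table <- NULL
  if (length(genes_per_class) > 1) {
    if (any(table(labels) < cv_folds))
      abort("every class needs at least cv_folds core samples for grid search")
    folds <- stratified_folds(labels, cv_folds, seed)
    errs <- vapply(genes_per_class, function(m) {
      fold_err <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        t_mat <- classifier_scores(x[, tr, drop = FALSE], labels[tr])
        genes <- select_classifier_genes(t_mat, m)
        centroids <- build_subtype_centroids(x[genes$gene_id, tr, drop = FALSE],
                                             labels[tr])
        pred <- nearest_centroid(x[genes$gene_id, !tr, drop = FALSE], centroids)
        mean(pred$subtype != labels[!tr])
      }, numeric(1))
      mean(fold_err)
    }, numeric(1))
    cv_table <- tibble::tibble(genes_per_class = genes_per_class, cv_error = errs)
    genes_per_class <- genes_per_class[which.min(errs)]
  }
  t_mat <- classifier_scores(x, labels)
  genes <- select_classifier_genes(t_mat, genes_per_class)
  centroids <- build_subtype_centroids(x[genes$gene_id, , drop = FALSE], labels)
  gene_sd <- apply(x[genes$gene_id, , drop = FALSE], 1, sd)
  if (any(gene_sd == 0)) abort("classifier gene with zero training SD")
  model <- structure(list(
    classes = classes,
    genes = genes,
    genes_per_class = genes_per_class,
    centroids = centroids,
    train_gene_mean = rowMeans(x[genes$gene_id, , drop = FALSE]),
    train_gene_sd = gene_sd,
    distance_metric = "pearson",
    cv = cv_table
  ), class = "subtype_model")
  model
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (c in unique(labels)) {
      idx <- which(labels == c)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Median class centroids
#'
#' Entry (g, c) is the median expression of gene g over the samples labelled
#' c. A single-sample class contributes its own vector.
#'
#' @param x gene-by-sample matrix.
#' @param labels class label per sample; every class must be non-empty.
#' @return Gene-by-class numeric matrix.
#' @export
build_subtype_centroids <- function(x, labels) {
  if (!is.matrix(x)) abort("x must be a matrix")
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) abort("one label per sample is required")
  if (anyNA(labels)) abort("labels contain missing values; every class must be non-empty")
  classes <- sort(unique(labels))
  out <- vapply(classes, function(c) {
    apply(x[, labels == c, drop = FALSE], 1, median)
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), classes))
  out
}

# Nearest-centroid assignment by 1 - Pearson over the centroid genes,
# pairwise-complete; ties broken by class order.
nearest_centroid <- function(x, centroids) {
  dists <- vapply(seq_len(ncol(x)), function(i) {
    suppressWarnings(1 - cor(x[, i], centroids, use = "pairwise.complete.obs"))
  }, numeric(ncol(centroids)))
  dists <- matrix(dists, nrow = ncol(centroids),
                  dimnames = list(colnames(centroids), colnames(x)))
  idx <- apply(dists, 2, which.min)
  out <- tibble::tibble(sample_id = colnames(x),
                        subtype = colnames(centroids)[idx])
  dd <- tibble::as_tibble(t(dists))
  names(dd) <- paste0("dist_", colnames(centroids))
  dplyr::bind_cols(out, dd)
}

#' Predict subtypes with a trained centroid model
#'
#' Each sample is assigned the class whose centroid has the smallest
#' 1 - Pearson distance over the classifier genes present in the input;
#' missing genes are dropped pairwise. Prediction refuses to run when fewer
#' than half of the classifier genes are present.
#'
#' @param model a `subtype_model`.
#' @param x gene-by-sample matrix (log2 scale, any superset/subset of
#'   genes).
#' @param min_coverage minimum fraction of classifier genes required
#'   (default 0.5).
#' @return A tibble: sample_id, subtype, one distance column per class;
#'   the classifier-gene coverage is attached as attribute `"coverage"`.
#' @export
predict_subtypes <- function(model, x, min_coverage = 0.5) {
  stopifnot(inherits(model, "subtype_model"))
  if (!is.matrix(x)) abort("x must be a matrix")
  genes <- intersect(model$genes$gene_id, rownames(x))
  coverage <- length(genes) / nrow(model$centroids)
  if (coverage < min_coverage)
    abort(paste0("only ", round(100 * coverage, 1),
                 "% of classifier genes present (floor ",
                 round(100 * min_coverage), "%)"))
  out <- nearest_centroid(x[genes, , drop = FALSE],
                          model$centroids[genes, , drop = FALSE])
  attr(out, "coverage") <- coverage
  out
}

#' Cross-study centroid validation
#'
#' Restricts two labelled cohorts to their shared genes, median-centers each
#' cohort separately, computes median subtype centroids per study, and
#' reports the 1 - Pearson distance between every pair of study-A and
#' study-B centroids. Concordant subtypes across studies show up as the
#' row/column minima on the diagonal.
#'
#' @param x_a,x_b gene-by-sample matrices from the two studies.
#' @param labels_a,labels_b subtype labels per study.
#' @param min_genes floor on the gene-id intersection (default 100).
#' @return A `centroid_distance` matrix (rows = study-A subtypes, columns =
#'   study-B subtypes, entries in \[0, 2\]).
#' @export
cross_study_validate <- function(x_a, labels_a, x_b, labels_b,
                                 min_genes = 100) {
  genes <- intersect(rownames(x_a), rownames(x_b))
  if (length(genes) < min_genes)
    abort(paste0("only ", length(genes), " shared genes (floor ", min_genes, ")"))
  ca <- build_subtype_centroids(median_center_genes(x_a[genes, , drop = FALSE]),
                                labels_a)
  cb <- build_subtype_centroids(median_center_genes(x_b[genes, , drop = FALSE]),
                                labels_b)
  d <- 1 - cor(ca, cb)
  structure(d, class = c("centroid_distance", class(d)))
}

#' Harmonize an external cohort to the classifier's training scale
#'
#' Z-scores each classifier gene in the external matrix and rescales it to
#' the per-gene mean and SD stored in the model, so the harmonized matrix
#' reproduces the training location/scale exactly. Zero-variance external
#' genes cannot be rescaled and are dropped with a warning.
#'
#' @param model a `subtype_model`.
#' @param x external gene-by-sample matrix.
#' @return Harmonized matrix restricted to usable classifier genes, with
#'   dropped genes listed in attribute `"dropped"`.
#' @export
harmonize_external <- function(model, x) {
  stopifnot(inherits(model, "subtype_model"))
  genes <- intersect(model$genes$gene_id, rownames(x))
  if (length(genes) == 0) abort("no classifier genes present in the external matrix")
  xg <- x[genes, , drop = FALSE]
  sds <- apply(xg, 1, sd)
  dropped <- genes[sds == 0]
  if (length(dropped) > 0) {
    warn(paste0("dropping zero-variance external gene(s): ",
                paste(dropped, collapse = ", ")))
    xg <- xg[sds > 0, , drop = FALSE]
    genes <- rownames(xg)
    sds <- sds[sds > 0]
  }
  z <- (xg - rowMeans(xg)) / sds
  out <- z * model$train_gene_sd[genes] + model$train_gene_mean[genes]
  attr(out, "dropped") <- dropped
  out
}

#' Standardize-and-predict transfer for sequencing-style cohorts
#'
#' For external data on a different measurement scale (e.g. log RPKM), both
#' the model centroids and the external matrix are median-centered and
#' unit-scaled per gene before nearest-centroid assignment, so labels are
#' invariant to per-gene location and scale in the external data. Constant
#' external genes are dropped with a warning.
#'
#' @param model a `subtype_model`.
#' @param x external gene-by-sample log-scale matrix with no missing
#'   values.
#' @param min_coverage minimum fraction of classifier genes required.
#' @return A tibble as in [predict_subtypes()].
#' @export
standardize_and_predict <- function(model, x, min_coverage = 0.5) {
  stopifnot(inherits(model, "subtype_model"))
  genes <- intersect(model$genes$gene_id, rownames(x))
  xg <- x[genes, , drop = FALSE]
  sds <- apply(xg, 1, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant external gene(s): ",
                paste(genes[sds == 0], collapse = ", ")))
    xg <- xg[sds > 0, , drop = FALSE]
    genes <- rownames(xg)
  }
  coverage <- length(genes) / nrow(model$centroids)
  if (coverage < min_coverage)
    abort(paste0("only ", round(100 * coverage, 1),
                 "% of classifier genes usable (floor ",
                 round(100 * min_coverage), "%)"))
  std <- function(m) {
    s <- apply(m, 1, sd)
    keep <- s > 0
    (m[keep, , drop = FALSE] - apply(m[keep, , drop = FALSE], 1, median)) / s[keep]
  }
  cen <- std(model$centroids[genes, , drop = FALSE])
  ext <- std(xg[rownames(cen), , drop = FALSE])
  common <- intersect(rownames(cen), rownames(ext))
  nearest_centroid(ext[common, , drop = FALSE], cen[common, , drop = FALSE])
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("<subtype_model> ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ",
      nrow(x$genes), " classifier genes (", x$genes_per_class,
      " per class), metric 1 - Pearson\n", sep = "")
  if (!is.null(x$cv)) {
    cat("cross-validation:\n")
    print(x$cv)
  }
  invisible(x)
}
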