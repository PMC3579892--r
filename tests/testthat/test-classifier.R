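test_that("silhouette widths separate well-placed from misassigned samples", {
  sim <- small_expr(n_samples = 40, n_genes = 200, k = 2, n_info = 50,
                    effect = 3, seed = 31)
  sil <- silhouette_core_samples(sim$matrix, sim$labels)
  expect_true(all(sil$sil_width > 0))
  expect_true(all(sil$core))
  expect_true(all(sil$sil_width >= -1 & sil$sil_width <= 1))

  wrong <- sim$labels
  wrong[1] <- ifelse(wrong[1] == 1, 2, 1)            # deliberately mislabel
  sil2 <- silhouette_core_samples(sim$matrix, wrong)
  expect_lt(sil2$sil_width[1], 0)
  expect_false(sil2$core[1])

  bad <- sim$labels; bad[1] <- 99
  expect_error(silhouette_core_samples(sim$matrix, bad), "size 1.*99")
})

test_that("classifier training yields balanced disjoint gene lists", {
  sim <- small_expr(n_samples = 60, n_genes = 600, k = 4, n_info = 50,
                    effect = 2, seed = 32)
  x <- median_center_genes(sim$matrix)
  mod <- train_nearest_centroid_classifier(x, sim$labels, genes_per_class = 30,
                                           seed = 1)
  expect_equal(nrow(mod$genes), 120L)
  counts <- table(mod$genes$class)
  expect_true(all(counts == 30))
  expect_equal(anyDuplicated(mod$genes$gene_id), 0L)  # partition => disjoint

  # planted markers dominate the selection and CV error is tiny
  mod_cv <- train_nearest_centroid_classifier(x, sim$labels,
                                              genes_per_class = c(20, 50),
                                              cv_folds = 5, seed = 2)
  planted <- split(sim$informative_genes$gene_id, sim$informative_genes$subtype)
  frac_planted <- vapply(mod_cv$classes, function(c) {
    sel <- mod_cv$genes$gene_id[mod_cv$genes$class == c]
    mean(sel %in% planted[[c]])
  }, numeric(1))
  expect_true(all(frac_planted >= 0.8))
  expect_lte(min(mod_cv$cv$cv_error), 0.05)

  # resubstitution error does not exceed the cross-validation error
  resub <- mean(predict_subtypes(mod_cv, x)$subtype != as.character(sim$labels))
  expect_lte(resub, min(mod_cv$cv$cv_error) + 1e-12)

  # every gene constant within both classes: pooled within-class SD is zero
  v1 <- rnorm(5); v2 <- rnorm(5)
  const <- expr_matrix(cbind(matrix(v1, 5, 6), matrix(v2, 5, 6)))
  expect_error(train_nearest_centroid_classifier(const, rep(c("a", "b"), each = 6),
                                                 genes_per_class = 1, seed = 1),
               "degenerate")
})

test_that("prediction is self-consistent and respects the coverage floor", {
  set.seed(33)
  centroids <- expr_matrix(matrix(rnorm(80), 40, 2), samples = c("A", "B"))
  model <- structure(list(
    classes = c("A", "B"),
    genes = tibble::tibble(gene_id = rownames(centroids),
                           class = rep(c("A", "B"), each = 20), score = 1),
    genes_per_class = 20, centroids = centroids,
    train_gene_mean = setNames(rep(0, 40), rownames(centroids)),
    train_gene_sd = setNames(rep(1, 40), rownames(centroids)),
    distance_metric = "pearson", cv = NULL), class = "subtype_model")

  self <- predict_subtypes(model, centroids)
  expect_equal(self$subtype, c("A", "B"))
  expect_equal(self$dist_A[1], 0, tolerance = 1e-12)
  expect_equal(self$dist_B[2], 0, tolerance = 1e-12)

  # exact negation of centroid A, with B orthogonal to A: anti-correlation
  a <- centroids[, "A"]
  b <- centroids[, "B"] - a * sum(a * centroids[, "B"]) / sum(a^2)
  model$centroids[, "B"] <- b
  neg <- expr_matrix(matrix(-a, ncol = 1), genes = rownames(centroids))
  pr <- predict_subtypes(model, neg)
  expect_equal(pr$subtype, "B")
  expect_equal(pr$dist_A, 2, tolerance = 1e-12)

  few <- centroids[1:10, , drop = FALSE]               # 25% coverage
  expect_error(predict_subtypes(model, few), "50%")
})

test_that("held-out synthetic samples are classified accurately", {
  sim <- small_expr(n_samples = 120, n_genes = 500, k = 4, n_info = 50,
                    effect = 2, seed = 34)
  x <- median_center_genes(sim$matrix)
  train <- seq_len(80); test <- 81:120
  mod <- train_nearest_centroid_classifier(x[, train], sim$labels[train],
                                           genes_per_class = 50, seed = 3)
  pred <- predict_subtypes(mod, x[, test])
  expect_gte(mean(pred$subtype == as.character(sim$labels[test])), 0.9)
})

test_that("median centroids follow median arithmetic", {
  x <- expr_matrix(matrix(c(1, 2, 9, 5), 1, 4))
  cen <- build_subtype_centroids(x, c("a", "a", "a", "b"))
  expect_equal(unname(cen[1, ]), c(2, 5))              # median{1,2,9}; singleton
  # duplicating the median sample leaves the centroid unchanged
  x2 <- expr_matrix(matrix(c(1, 2, 9, 2, 5), 1, 5))
  cen2 <- build_subtype_centroids(x2, c("a", "a", "a", "a", "b"))
  expect_equal(cen2[1, "a"], cen[1, "a"])
  expect_error(build_subtype_centroids(x, c("a", "a", "a", NA)), "missing")
})

test_that("cross-study centroid distances behave as a validation metric", {
  sim <- small_expr(n_samples = 80, n_genes = 300, k = 4, n_info = 40,
                    effect = 2, seed = 35)
  d_self <- cross_study_validate(sim$matrix, sim$labels,
                                 sim$matrix, sim$labels)
  expect_equal(unname(diag(unclass(d_self))), rep(0, 4), tolerance = 1e-12)
  expect_true(all(d_self >= 0 & d_self <= 2))

  # stratified split so both halves contain every subtype
  half_a <- unlist(lapply(split(seq_len(80), sim$labels),
                          function(s) s[seq_len(length(s) / 2)]))
  half_b <- setdiff(seq_len(80), half_a)
  d_ab <- cross_study_validate(sim$matrix[, half_a], sim$labels[half_a],
                               sim$matrix[, half_b], sim$labels[half_b])
  d_ba <- cross_study_validate(sim$matrix[, half_b], sim$labels[half_b],
                               sim$matrix[, half_a], sim$labels[half_a])
  expect_equal(unclass(d_ab), t(unclass(d_ba)))        # role symmetry
  expect_error(cross_study_validate(sim$matrix[1:20, ], sim$labels,
                                    sim$matrix[1:20, ], sim$labels),
               "shared genes")
  long <- tidy(d_ab)
  expect_equal(nrow(long), 16L)
})

test_that("harmonization reproduces stored training moments exactly", {
  sim <- small_expr(n_samples = 60, n_genes = 300, k = 4, n_info = 30,
                    effect = 2, seed = 36)
  x <- median_center_genes(sim$matrix)
  mod <- train_nearest_centroid_classifier(x, sim$labels, genes_per_class = 25,
                                           seed = 4)
  h_self <- harmonize_external(mod, x)
  attr(h_self, "dropped") <- NULL
  expect_equal(h_self, x[rownames(h_self), ], tolerance = 1e-9)

  set.seed(1)
  ext <- x * 2.5 - 4 + matrix(rnorm(length(x), sd = 0.01), nrow(x))
  dimnames(ext) <- dimnames(x)
  h <- harmonize_external(mod, ext)
  expect_lt(max(abs(rowMeans(h) - mod$train_gene_mean[rownames(h)])), 1e-9)
  expect_lt(max(abs(apply(h, 1, sd) - mod$train_gene_sd[rownames(h)])), 1e-9)

  ext2 <- ext
  ext2[mod$genes$gene_id[1], ] <- 7                    # constant gene
  expect_warning(h2 <- harmonize_external(mod, ext2), "zero-variance")
  expect_false(mod$genes$gene_id[1] %in% rownames(h2))
})

test_that("standardize-and-predict is scale invariant and reproduces labels", {
  sim <- small_expr(n_samples = 60, n_genes = 300, k = 4, n_info = 30,
                    effect = 2, seed = 37)
  x <- median_center_genes(sim$matrix)
  mod <- train_nearest_centroid_classifier(x, sim$labels, genes_per_class = 25,
                                           seed = 5)
  sil <- silhouette_core_samples(x, sim$labels)

  p1 <- standardize_and_predict(mod, x)
  agree <- p1$subtype[sil$core] == as.character(sim$labels[sil$core])
  expect_gte(mean(agree), 0.95)                        # self-transfer

  scaled <- x
  scaled[mod$genes$gene_id[1], ] <- scaled[mod$genes$gene_id[1], ] * 10
  p2 <- standardize_and_predict(mod, scaled)
  expect_equal(p1$subtype, p2$subtype)                 # per-gene standardization

  const <- x
  const[mod$genes$gene_id[2], ] <- 1
  expect_warning(standardize_and_predict(mod, const), "constant")
})
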