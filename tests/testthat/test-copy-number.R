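test_that("missing markers are filled from the nearest probe, ties upstream", {
  markers <- tibble::tibble(marker_id = paste0("m", 1:5), chrom = "chr1",
                            pos = 1:5, arm = "chr1p")
  vals <- matrix(c(NA, 0.3, NA, NA, 0.9), 5, 1,
                 dimnames = list(markers$marker_id, "s1"))
  co <- impute_missing_markers(cn_cohort(markers, vals))
  expect_equal(unname(co$values[, 1]), c(0.3, 0.3, 0.3, 0.9, 0.9))

  full <- cn_cohort(markers, matrix(1:5, 5, 1))
  expect_identical(impute_missing_markers(full)$values, full$values)

  lead <- cn_cohort(markers, matrix(c(NA, NA, 0.5, 0.6, 0.7), 5, 1))
  expect_equal(unname(impute_missing_markers(lead)$values[1:2, 1]), c(0.5, 0.5))

  gone <- cn_cohort(markers, matrix(NA_real_, 5, 1))
  expect_error(impute_missing_markers(gone), "no non-missing marker")
})

test_that("smoothing shrinks spikes and centering zeroes every profile", {
  co <- noise_cohort(100, 4, noise_sd = 0)
  co$values[] <- 0.2
  sm <- smooth_and_center_profiles(co)
  expect_true(all(sm$values == 0))

  co2 <- noise_cohort(100, 4, noise_sd = 0.05, seed = 3)
  co2$values[37, 2] <- 4.0                              # lone spike
  sm2 <- smooth_and_center_profiles(co2)
  expect_lt(abs(sm2$values[37, 2]), 0.5)
  expect_true(all(abs(apply(sm2$values, 2, median)) < 1e-12))
})

test_that("recursive segmentation finds planted breakpoints", {
  set.seed(44)
  hits <- vapply(1:20, function(i) {
    v <- c(rnorm(100, 0, 0.1), rnorm(100, 0.8, 0.1))
    seg <- subtypeforge:::segment_vector(v, min_seg = 3, alpha = 0.01)
    bks <- which(diff(seg) != 0)
    length(bks) == 1 && abs(bks - 100) <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_equal(subtypeforge:::segment_vector(rep(0.3, 50)), rep(1L, 50))

  co <- noise_cohort(80, 3, seed = 5)
  seg <- segment_profiles(co)
  # segments partition the markers of every sample
  per_sample <- tapply(seg$n_markers, seg$sample_id, sum)
  expect_true(all(per_sample == 80))
})

test_that("cyclic-shift test handles degenerate and planted cohorts", {
  co0 <- noise_cohort(80, 6, noise_sd = 0)
  r0 <- cyclic_shift_peak_test(co0, "gain", n_perm = 50, seed = 1)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)                           # inclusive comparison

  co <- noise_cohort(400, 40, seed = 46)
  set.seed(46)
  co <- plant_event(co, 101:140, sample(40, 16), 0.6)
  co <- smooth_and_center_profiles(co)
  r <- cyclic_shift_peak_test(co, "gain", n_perm = 250, seed = 2)
  idx <- match(r$peak_marker, co$markers$marker_id)
  expect_lte(r$p_value, 0.05)
  expect_true(idx >= 101 && idx <= 140)
  expect_error(cyclic_shift_peak_test(co, "gain", n_perm = 0), "n_perm")
})

test_that("cyclic shifting preserves each sample's marker multiset", {
  co <- noise_cohort(60, 5, seed = 47)
  shifted <- subtypeforge:::cyclic_shift_matrix(co$values, c(0, 7, 59, 13, 30))
  for (j in 1:5)
    expect_equal(unname(sort(shifted[, j])), unname(sort(co$values[, j])))
  expect_equal(shifted[, 1], co$values[, 1])            # zero offset: identity
})

test_that("peeling exposes secondary peaks on other chromosomes", {
  co <- noise_cohort(400, 40, seed = 48)
  set.seed(48)
  co <- plant_event(co, 81:120, sample(40, 16), 0.7)    # chr1
  co <- plant_event(co, 261:300, sample(40, 16), 0.7)   # chr2
  co <- smooth_and_center_profiles(co)
  peaks <- peel_and_repeat(co, "gain", n_peaks = 4, n_perm = 150,
                           n_boot = 100, seed = 3)
  expect_gte(nrow(peaks), 2)
  first_two <- match(peaks$peak_marker[1:2], co$markers$marker_id)
  expect_true(any(first_two %in% 81:120))
  expect_true(any(first_two %in% 261:300))
  expect_true(all(peaks$p_value <= 0.05))

  quiet <- smooth_and_center_profiles(noise_cohort(400, 40, seed = 49))
  pq <- peel_and_repeat(quiet, "gain", n_peaks = 3, n_perm = 150,
                        n_boot = 100, seed = 4)
  expect_lte(nrow(pq), 1)                               # noise stops the loop
})

test_that("bootstrap peak intervals are ordered and degenerate-safe", {
  markers1 <- tibble::tibble(marker_id = "m1", chrom = "chr1", pos = 1e6,
                             arm = "chr1p")
  one <- cn_cohort(markers1, matrix(rnorm(8, 0.5, 0.1), 1, 8))
  ci1 <- peak_confidence_interval(one, "gain", n_boot = 50, seed = 1)
  expect_equal(ci1$ci_left, "m1")
  expect_equal(ci1$ci_right, "m1")

  co <- noise_cohort(400, 40, seed = 50)
  set.seed(50)
  co <- plant_event(co, 101:150, sample(40, 20), 0.5)
  co <- smooth_and_center_profiles(co)
  ci <- peak_confidence_interval(co, "gain", n_boot = 200, seed = 2)
  obs <- cyclic_shift_peak_test(co, "gain", n_perm = 50, seed = 3)
  ord <- match(c(ci$ci_left, obs$peak_marker, ci$ci_right), co$markers$marker_id)
  expect_true(ord[1] <= ord[2] && ord[2] <= ord[3])
})

test_that("gene-level copy number follows the flanking-marker rule", {
  markers <- tibble::tibble(marker_id = paste0("m", 1:6), chrom = "chr1",
                            pos = c(10, 20, 30, 40, 50, 60) * 1e5,
                            arm = "chr1p")
  segv <- matrix(c(0.42, 0.42, 0.5, 0.5, 0.1, 0.42), 6, 1,
                 dimnames = list(markers$marker_id, "s1"))
  inside <- gene_level_copy_number(segv, markers,
                                   list(gene_id = "G", chrom = "chr1",
                                        start = 5e5, end = 2.5e6), flank = 0)
  expect_equal(unname(inside), 0.42)                   # fully inside one value

  three <- gene_level_copy_number(segv, markers,
                                  list(gene_id = "G", chrom = "chr1",
                                       start = 2.5e6, end = 5.5e6), flank = 0)
  expect_equal(unname(three), mean(c(0.5, 0.5, 0.1))) # 0.3667 toy case

  between <- gene_level_copy_number(segv, markers,
                                    list(gene_id = "G", chrom = "chr1",
                                         start = 3.1e6, end = 3.9e6), flank = 1)
  expect_equal(unname(between), mean(c(0.5, 0.5)))     # flanks only

  expect_error(gene_level_copy_number(segv, markers,
                                      list(gene_id = "G", chrom = "chr1",
                                           start = 9e8, end = 9.1e8)),
               "within")
})

test_that("gain/loss calls use strict threshold inequalities", {
  expect_equal(call_gene_event(c(0.42, -0.42, 0.35, -0.35, 0)),
               c("gain", "loss", "neutral", "neutral", "neutral"))
  expect_error(call_gene_event(NaN), "finite")
})

test_that("chromosomal instability index matches arm-median arithmetic", {
  vals <- matrix(c(0.1, -0.1, 0.3, -0.2, -0.4, -0.6), 6, 1,
                 dimnames = list(paste0("m", 1:6), "s1"))
  arms <- rep(c("a1", "a2"), each = 3)
  cin <- chromosomal_instability_index(vals, arms)
  expect_equal(cin$cin, 0.25)                          # medians .1 and .4

  expect_equal(chromosomal_instability_index(vals * 0, arms)$cin, 0)
  expect_equal(chromosomal_instability_index(vals * 3, arms)$cin, 0.75)

  flip <- vals; flip[1:3, ] <- -flip[1:3, ]            # sign-flip one arm
  expect_equal(chromosomal_instability_index(flip, arms)$cin, 0.25)
  shuffle <- c(3, 1, 2, 6, 5, 4)                       # permute within arms
  expect_equal(chromosomal_instability_index(vals[shuffle, , drop = FALSE],
                                             arms)$cin, 0.25)
})

test_that("region association detects subtype-restricted gains", {
  co <- noise_cohort(400, 80, seed = 52)
  labels <- setNames(rep(1:4, 20), colnames(co$values))
  set.seed(52)
  carriers <- names(labels)[labels == 2]
  co <- plant_event(co, 61:100, carriers, 0.6)
  co <- smooth_and_center_profiles(co)
  r <- region_subtype_association(co, labels, 61:100)
  expect_lte(r$p_value, 0.01)
  r10 <- region_subtype_association(co, labels, 61:100, n_regions = 10)
  expect_equal(r10$p_adjusted, min(1, r10$p_value * 10))
  expect_error(region_subtype_association(co, rep(1, 80), 61:100),
               "two subtypes")
})
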