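test_that("exact Fisher p-values equal full hypergeometric enumeration", {
  expect_equal(fisher_exact_rxc(rbind(c(3, 1), c(1, 3)))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(rbind(c(2, 0), c(0, 2)))$p_value, 2 / 6,
               tolerance = 1e-12)

  set.seed(61)
  tab <- matrix(rpois(12, 6), 3, 4)
  p <- fisher_exact_rxc(tab)$p_value
  expect_true(p > 0 && p <= 1)
  expect_equal(fisher_exact_rxc(tab[3:1, c(2, 1, 4, 3)])$p_value, p,
               tolerance = 1e-12)                      # permutation invariance

  expect_error(fisher_exact_rxc(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(fisher_exact_rxc(matrix(1:4, 1, 4)), "2 rows")
})

test_that("tables beyond the enumeration budget point to the MC variant", {
  big <- rbind(c(10, 4, 5, 11), c(30, 18, 2, 5), c(3, 5, 20, 6), c(0, 2, 5, 6))
  expect_error(fisher_exact_rxc(big, workspace = 2e5), "fisher_monte_carlo")
  mc <- fisher_monte_carlo(big, n_sim = 20000, seed = 2)
  expect_lt(mc$p_value, 0.01)
})

test_that("Monte-Carlo Fisher agrees with enumeration and is seeded", {
  tab <- rbind(c(3, 1), c(1, 3))
  mc <- fisher_monte_carlo(tab, n_sim = 20000, seed = 7)
  expect_lt(abs(mc$p_value - 34 / 70), 3 * mc$mc_se)
  expect_identical(mc, fisher_monte_carlo(tab, n_sim = 20000, seed = 7))
  expect_gte(mc$p_value, 1 / 20001)
  expect_lte(mc$p_value, 1)
  expect_error(fisher_monte_carlo(tab, n_sim = 10), "at least 1000")
})

test_that("Kruskal-Wallis matches direct rank arithmetic", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$p_value, 1)

  g <- list(c(1, 2, 3), c(10, 11, 12))
  got <- kruskal_wallis(g)
  # direct computation: ranks 1..6, no ties
  n <- 6; rbars <- c(mean(1:3), mean(4:6))
  H <- 12 / (n * (n + 1)) * sum(3 * (rbars - (n + 1) / 2)^2)
  expect_equal(got$statistic, H, tolerance = 1e-12)
  expect_equal(got$df, 1)

  # invariance under strictly increasing transformation
  expect_equal(kruskal_wallis(lapply(g, exp))$statistic, got$statistic,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("SAM d-statistic follows its defining formula", {
  x <- expr_matrix(rbind(c(0, 0, 0, 1, 1, 1),
                         c(0, 1, 2, 0.5, 1.5, 2.5)))
  lab <- rep(c("a", "b"), each = 3)
  res <- sam_two_class(x, lab, n_perm = 100, s0 = 0.1, seed = 1)
  d <- tidy(res)$d
  expect_equal(d[1], -10)                              # (0-1)/(0+0.1), class1 - class2
})

test_that("SAM calls nothing on exchangeable labels and finds planted genes", {
  null_calls <- vapply(1:5, function(s) {
    set.seed(200 + s)
    x <- expr_matrix(matrix(rnorm(1000 * 30), 1000, 30))
    lab <- rep(c("a", "b"), each = 15)
    glance(sam_two_class(x, lab, n_perm = 100, seed = s))$n_called
  }, numeric(1))
  expect_equal(median(null_calls), 0)

  set.seed(62)
  x <- matrix(rnorm(2000 * 40), 2000, 40)
  lab <- rep(c("a", "b"), each = 20)
  x[1:100, lab == "b"] <- x[1:100, lab == "b"] + 2
  x <- expr_matrix(x)
  res <- sam_two_class(x, lab, n_perm = 200, seed = 3)
  called <- tidy(res)$called
  expect_gte(sum(called[1:100]), 80)
  expect_lte(sum(called[-(1:100)]), 5)

  # called set is monotone in the FDR threshold
  strict <- sam_two_class(x, lab, n_perm = 200, fdr_threshold = 0.001, seed = 3)
  loose <- sam_two_class(x, lab, n_perm = 200, fdr_threshold = 0.05, seed = 3)
  expect_true(all(tidy(strict)$called <= tidy(loose)$called))
  expect_lte(glance(res)$median_fdr, 0.01)
  expect_error(sam_two_class(x[, 1:21], c(rep("a", 20), "b"), seed = 1),
               "two samples")
})

test_that("log-rank statistic matches direct observed-minus-expected sums", {
  d0 <- tibble::tibble(rfs_months = c(1, 2, 3, 1, 2, 3),
                       event = 1L, subtype = rep(c("a", "b"), each = 3))
  r0 <- km_logrank(d0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  d <- tibble::tibble(rfs_months = c(1, 2, 3, 4, 10, 20, 30, 40),
                      event = 1L, subtype = rep(c("a", "b"), each = 4))
  r <- km_logrank(d)
  # direct computation at each event time: O - E and hypergeometric variance
  times <- sort(unique(d$rfs_months))
  OmE <- 0; V <- 0
  for (t in times) {
    at_risk <- d$rfs_months >= t
    n1 <- sum(at_risk & d$subtype == "a"); ntot <- sum(at_risk)
    dth <- sum(d$rfs_months == t)
    d1 <- sum(d$rfs_months == t & d$subtype == "a")
    OmE <- OmE + d1 - dth * n1 / ntot
    if (ntot > 1)
      V <- V + dth * (n1 / ntot) * (1 - n1 / ntot) * (ntot - dth) / (ntot - 1)
  }
  expect_equal(r$statistic, OmE^2 / V, tolerance = 1e-10)

  # group relabeling leaves the p-value unchanged
  d_swap <- d; d_swap$subtype <- ifelse(d$subtype == "a", "z", "y")
  expect_equal(km_logrank(d_swap)$p_value, r$p_value, tolerance = 1e-12)

  # product-limit estimate starts at 1
  expect_equal(unique(summary(r$fit, times = 0)$surv), 1)
  curves <- tidy(r)
  expect_true(all(curves$estimate >= 0 & curves$estimate <= 1))
})

test_that("contingency construction excludes missing covariates row-wise", {
  clin <- tibble::tibble(sample_id = paste0("s", 1:6),
                         subtype = c("1", "1", "2", "2", "2", "1"),
                         hpv = c("neg", NA, "pos", "neg", NA, "pos"))
  tab <- subtype_contingency(clin, "hpv")
  expect_equal(sum(tab), 4L)                           # NAs dropped, not imputed
  expect_equal(dim(tab), c(2L, 2L))
})
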