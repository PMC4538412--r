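test_that("percentile background adjustment subtracts and floors", {
  m <- matrix(100, 3, 2)
  expect_true(all(background_adjust(m, percentile = 0) == 1))
  col <- matrix(c(10, 100, 1000), 3, 1)
  expect_equal(as.vector(background_adjust(col, percentile = 0)),
               c(1, 90, 990))
  inc <- matrix(c(5, 20, 80, 300), 4, 1)
  out <- background_adjust(inc, percentile = 0)
  expect_true(all(diff(as.vector(out)) > 0))
  expect_error(background_adjust(matrix(c(-1, 2), 2, 1)), "positive")
})

test_that("quantile normalization matches its defining contract", {
  m <- cbind(a = c(1, 3), b = c(1, 3))
  expect_equal(quantile_normalize(m), m)
  m2 <- cbind(a = c(1, 3), b = c(2, 4))
  expect_equal(unname(quantile_normalize(m2)),
               cbind(c(1.5, 3.5), c(1.5, 3.5)))
  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "single sample")
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rnorm(10 * 3, 8), 10, 3)
    got <- quantile_normalize(m)
    expect_equal(unname(got), unname(limma::normalizeQuantiles(m)),
                 tolerance = 1e-12)
    # defining property and idempotence
    sorted <- apply(got, 2L, sort)
    expect_true(max(sorted - sorted[, 1]) < 1e-9)
    expect_equal(quantile_normalize(got), got, tolerance = 1e-12)
  }
})

test_that("tied values share the mean of the target values at their ranks", {
  m <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  # target (mean of sorted columns) is (1.5, 2.5, 5.5); the tied 1s occupy
  # ranks 1 and 2, so both become mean(1.5, 2.5) = 2
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2, 2, 5.5), c(1.5, 2.5, 5.5)))
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(sample(1:25, 30, replace = TRUE), 10, 3)  # ties likely
    expect_equal(unname(quantile_normalize(m)),
                 unname(ref_quantile_normalize(m)), tolerance = 1e-12)
  }
})

test_that("median-polish summarization reduces probesets to sample effects", {
  single <- list(ps1 = matrix(c(1, 2, 3), 1, 3,
                              dimnames = list("p1", c("s1", "s2", "s3"))))
  expect_equal(as.vector(median_polish_summarize(single)), c(1, 2, 3))
  two <- list(ps1 = matrix(c(1, 1, 2, 2), 2, 2))
  expect_equal(as.vector(median_polish_summarize(two)), c(1, 2))
  # shift equivariance
  set.seed(5)
  m <- matrix(rnorm(12), 3, 4)
  base <- median_polish_summarize(list(x = m))
  shifted <- median_polish_summarize(list(x = m + 3))
  expect_equal(shifted, base + 3, tolerance = 1e-9)
  expect_error(median_polish_summarize(list(bad = matrix(numeric(), 0, 3))),
               "empty")
})

test_that("one-way ANOVA reproduces the classical F test", {
  r <- anova_one_way(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(r$statistic, 8, tolerance = 1e-12)
  # oracle: upper-tail F probability at df (1, 2)
  expect_equal(r$p_value, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(r$p_value, 4), 0.1056)

  same <- anova_one_way(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(z <- anova_one_way(list(a = c(1, 1), b = c(2, 2))), "p = 0")
  expect_equal(z$p_value, 0)
  expect_warning(z1 <- anova_one_way(list(a = c(2, 2), b = c(2, 2))), "p = 1")
  expect_equal(z1$p_value, 1)
  expect_error(anova_one_way(list(a = 1, b = 2)), "degrees of freedom")
})

test_that("two-group ANOVA equals the equal-variance t-test", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(4 + i %% 3); y <- rnorm(5)
    a <- anova_one_way(list(x = x, y = y))$p_value
    t <- t.test(x, y, var.equal = TRUE)$p.value
    expect_equal(a, t, tolerance = 1e-12)
  }
})

test_that("vectorized per-row F screen matches the scalar ANOVA", {
  set.seed(31)
  m <- matrix(rnorm(50 * 9), 50, 9)
  groups <- rep(c("a", "b", "c"), each = 3)
  p_vec <- fluorosnc:::.row_anova_p(m, groups)
  p_ref <- apply(m, 1L, function(row)
    anova_one_way(split(row, groups))$p_value)
  expect_equal(p_vec, p_ref, tolerance = 1e-10)
})

test_that("signed fold change follows the magnitude >= 1 convention", {
  expect_equal(signed_fold_change(5, 5), 1)
  expect_equal(signed_fold_change(6, 5), 2)
  expect_equal(signed_fold_change(5, 6), -2)
  expect_equal(signed_fold_change(5 - 1.70044, 5), -3.25, tolerance = 1e-4)
})

test_that("DE screen applies p and fold-change cuts and counts directions", {
  res <- data.frame(probe_id = c("p1", "p2", "p3"),
                    p_value = c(0.01, 0.01, 0.2),
                    fc_dose = c(1.6, -1.4, 3.0))
  s <- de_screen(res, "dose")
  expect_equal(unname(s$counts), c(1L, 1L, 0L))
  expect_equal(s$screened$probe_id, "p1")
  expect_error(de_screen(res, "nope"), "unknown contrast")
  # monotone non-increasing in fc_cut
  totals <- vapply(c(1, 1.5, 2, 3, 4), function(fc)
    de_screen(res, "dose", p_cut = 1, fc_cut = fc)$counts[["total"]],
    integer(1L))
  expect_true(all(diff(totals) <= 0))
})

test_that("the pipeline is invariant to a global intensity rescaling", {
  sim <- gen_probe_matrix(120, de_fraction = 0.1, seed = 4)
  de1 <- array_screen(sim$values, sim$groups, background = FALSE)
  de2 <- array_screen(sim$values * 7.3, sim$groups, background = FALSE)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-9)
  expect_equal(de1$fc_dose_low, de2$fc_dose_low, tolerance = 1e-9)
  expect_equal(de1$fc_dose_high, de2$fc_dose_high, tolerance = 1e-9)
})
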