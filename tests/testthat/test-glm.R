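test_that("design matrix columns follow the convolution oracle", {
  p1 <- paradigm(0, 15, "care", tr = 1, n_scans = 60)
  h <- canonical_hrf(1)
  dm <- build_design_matrix(p1, h, drift_order = 0)
  expect_identical(colnames(dm$matrix), c("care", "constant"))
  col <- dm$matrix[, "care"]
  # independent discrete convolution oracle
  box <- as.numeric(scan_times(p1) < 15)
  oracle <- vapply(seq_len(60), function(t) {
    sum(box[seq_len(t)] * h[t - seq_len(t) + 1], na.rm = TRUE)
  }, 0)
  expect_equal(col, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # a sustained 15 s block peaks where the oracle peaks (~12 s), well after
  # the HRF impulse peak
  expect_equal(which.max(col), which.max(oracle))
  expect_gte(which.max(col) - 1, 10); expect_lte(which.max(col) - 1, 14)
})

test_that("conditions absent from the paradigm get no column; drift count", {
  p <- paradigm(c(0, 15, 30), rep(15, 3), c("justice", "neutral", "justice"),
                tr = 2, n_scans = 30)
  dm <- build_design_matrix(p, drift_order = 0)
  expect_false("care" %in% colnames(dm$matrix))
  expect_equal(ncol(dm$matrix), 3)  # two conditions + constant
  dm2 <- build_design_matrix(p, drift_order = 3)
  expect_equal(ncol(dm2$matrix), 6)
  # default drift order derives from the 128 s high-pass cutoff
  dm3 <- build_design_matrix(p)
  expect_equal(sum(grepl("^drift_", colnames(dm3$matrix))),
               floor(2 * 30 * 2 / 128))
})

test_that("OLS recovers exact structure and errors on collinearity", {
  p <- make_paradigm(seed = 2)
  dm <- build_design_matrix(p)
  y <- dm$matrix[, "care"]
  fit <- fit_glm(y, dm, contrasts = list(cn = c(care = 1, neutral = -1)))
  expect_equal(unname(fit$betas["care"]), 1, tolerance = 1e-8)
  expect_equal(unname(fit$betas["neutral"]), 0, tolerance = 1e-8)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
  # residual orthogonality on a noisy fit
  set.seed(1)
  y2 <- y + rnorm(length(y))
  fit2 <- fit_glm(y2, dm, contrasts = list(cn = c(care = 1, neutral = -1),
                                           zero = c(care = 0)))
  expect_lt(max(abs(crossprod(dm$matrix, fit2$residuals))), 1e-8)
  expect_equal(fit2$contrasts$t[fit2$contrasts$contrast == "zero"], 0)
  # contrast negation symmetry
  fit3 <- fit_glm(y2, dm, contrasts = list(nc = c(care = -1, neutral = 1)))
  expect_equal(fit3$contrasts$t[1],
               -fit2$contrasts$t[fit2$contrasts$contrast == "cn"])
  # duplicated column -> informative error
  X <- cbind(dm$matrix, care2 = dm$matrix[, "care"])
  expect_error(fit_glm(y2, X), "care2")
})

test_that("null care-neutral contrast t is centred near zero", {
  p <- make_paradigm(seed = 3)
  dm <- build_design_matrix(p)
  set.seed(42)
  ts <- replicate(500, {
    fit_glm(rnorm(p$n_scans), dm,
            contrasts = list(cn = c(care = 1, neutral = -1)))$contrasts$t
  })
  expect_lt(abs(mean(ts)), 0.15)
  expect_lt(abs(stats::sd(ts) - 1), 0.2)
})

test_that("group correlation returns exact r^2 and guards degeneracies", {
  x <- c(0.2, 0.5, 0.9, 1.3, 1.4, 2.0, 2.2)
  y <- 2 * x + 5
  res <- group_contrast_correlation(x, y)
  expect_equal(res$r_squared, 1)
  set.seed(2)
  y2 <- y + rnorm(7)
  res2 <- group_contrast_correlation(x, y2)
  expect_equal(res2$r_squared, stats::cor(x, y2)^2)
  expect_equal(res2$p, summary(stats::lm(y2 ~ x))$coefficients[2, 4],
               tolerance = 1e-10)
  expect_error(group_contrast_correlation(x[1:2], y[1:2]), "3 subjects")
  expect_error(group_contrast_correlation(rep(1, 7), y), "variance")
})

test_that("group correlation p is calibrated under the null", {
  set.seed(99)
  rej <- mean(replicate(500, {
    group_contrast_correlation(rnorm(17), rnorm(17))$p < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("median split uses a ties-to-low rule and Welch's t", {
  scores <- 1:10
  res <- median_split_compare(scores, rep(2, 10))
  expect_equal(res$t, 0); expect_equal(res$p, 1)
  expect_equal(res$groups$n, c(5, 5))
  # ties at the median go to the low group
  scores2 <- c(1, 2, 3, 5, 5, 5, 8, 9)
  res2 <- median_split_compare(scores2, rnorm(8))
  expect_equal(res2$groups$n[res2$groups$group == "low"], 6)
  expect_error(median_split_compare(rep(3, 6), rnorm(6)), "identical")
})

test_that("median split detects a 3-sd contrast separation", {
  set.seed(5)
  hits <- mean(replicate(200, {
    scores <- c(rnorm(8, 10), rnorm(8, 20))
    contrasts <- c(rnorm(8, 0), rnorm(8, 3))
    median_split_compare(scores, contrasts)$p < 0.01
  }))
  expect_gte(hits, 0.95)
})
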