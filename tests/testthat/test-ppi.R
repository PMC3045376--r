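test_that("first eigenvariate recovers shared and rank-1 structure", {
  set.seed(1)
  s <- rnorm(80)
  M <- cbind(s, s, s)
  e <- first_eigenvariate(M)
  expect_gt(stats::cor(e, s), 0.999999)
  # rank-1 u v' with positive v: recovers u up to positive scale
  u <- rnorm(60); v <- runif(5, 0.5, 2)
  e2 <- first_eigenvariate(u %o% v)
  expect_gt(abs(stats::cor(e2, u)), 0.999)
  expect_gt(stats::cor(e2, rowMeans(u %o% v)), 0)
  # single column returns the (centred, rescaled) column itself
  x <- rnorm(30)
  e3 <- first_eigenvariate(matrix(x, ncol = 1))
  expect_gt(stats::cor(e3, x), 0.999999)
  expect_error(first_eigenvariate(matrix(1, 10, 2)), "variance")
})

test_that("PPI regressors code the contrast and build the product term", {
  p <- paradigm(c(0, 15, 30), rep(15, 3), c("care", "neutral", "justice"),
                tr = 1, n_scans = 50)
  set.seed(2)
  seed_ts <- rnorm(50)
  regs <- build_ppi_regressors(seed_ts, p, c("care", "neutral"))
  expect_equal(length(regs$psychological), 50)
  expect_equal(mean(regs$psychological[regs$psychological != 0]), 0)
  expect_equal(sort(unique(regs$psychological)), c(-1, 0, 1))
  expect_equal(regs$interaction,
               (seed_ts - mean(seed_ts)) * regs$psychological)
  # seed equal to the psychological vector: interaction = centred psych^2
  regs2 <- build_ppi_regressors(regs$psychological, p, c("care", "neutral"))
  expect_equal(regs2$interaction,
               (regs$psychological - mean(regs$psychological)) *
                 regs$psychological)
  # zero seed gives a zero interaction in both modes
  z <- rep(0, 50)
  expect_equal(build_ppi_regressors(z, p, c("care", "neutral"))$interaction, z)
  expect_equal(build_ppi_regressors(z, p, c("care", "neutral"),
                                    mode = "deconvolve")$interaction, z)
  expect_error(build_ppi_regressors(seed_ts, p, c("care", "strategic")),
               "absent")
})

test_that("PPI regression recovers exact and null interaction structure", {
  p <- paradigm(c(0, 15, 30), rep(15, 3), c("care", "neutral", "care"),
                tr = 1, n_scans = 60)
  set.seed(3)
  seed_ts <- rnorm(60)
  regs <- build_ppi_regressors(seed_ts, p, c("care", "neutral"))
  fit <- fit_ppi(regs$interaction, regs)
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  # target = physiological only: interaction beta within 3 SE of zero
  fit2 <- fit_ppi(regs$physiological + rnorm(60, sd = 0.1), regs)
  expect_lt(abs(fit2$beta), 3 * fit2$se)
  expect_error(fit_ppi(seed_ts, regs,
                       confounds = cbind(dup = regs$interaction)),
               "collinear")
})

test_that("interaction t grows with coupling modulation strength", {
  p <- make_paradigm(seed = 4)
  cond <- condition_at_scans(p)
  psych_raw <- (cond == "care") - (cond == "neutral")
  set.seed(10)
  mean_t <- vapply(c(0, 0.25, 0.5, 1), function(g) {
    mean(replicate(60, {
      seed_ts <- rnorm(p$n_scans)
      target <- seed_ts * (1 + g * psych_raw) + rnorm(p$n_scans, sd = 0.5)
      regs <- build_ppi_regressors(seed_ts, p, c("care", "neutral"))
      fit_ppi(target, regs)$t
    }))
  }, 0)
  expect_true(all(diff(mean_t) > 0))
  expect_lt(abs(mean_t[1]), 0.5)
})

test_that("multiply and deconvolve modes agree in interaction sign", {
  p <- paradigm(c(0, 15, 30, 45), rep(15, 4),
                c("care", "neutral", "care", "neutral"), tr = 1, n_scans = 70)
  h <- canonical_hrf(1)
  set.seed(6)
  neural <- abs(rnorm(70)) + 0.5
  seed_ts <- roisem:::convolve_causal(neural, h)
  cond <- condition_at_scans(p)
  psych_raw <- (cond == "care") - (cond == "neutral")
  target <- roisem:::convolve_causal(neural * (1 + 0.8 * psych_raw), h)
  b_mult <- fit_ppi(target, build_ppi_regressors(seed_ts, p,
                                                 c("care", "neutral")))$beta
  b_dec <- fit_ppi(target, build_ppi_regressors(seed_ts, p,
                                                c("care", "neutral"),
                                                mode = "deconvolve",
                                                hrf = h))$beta
  expect_gt(b_mult, 0)
  expect_gt(b_dec, 0)
})

test_that("group paired PPI test behaves at degeneracy and with signal", {
  b <- c(0.1, 0.2, 0.3, 0.4)
  res <- group_ppi_test(b, b)
  expect_equal(res$t, 0); expect_equal(res$p, 1)
  expect_error(group_ppi_test(b[1:2], b[1:2]), "3 subjects")
  expect_error(group_ppi_test(b + 1, b), "zero variance")
  set.seed(7)
  hits <- mean(replicate(200, {
    a <- rnorm(17, 1, 0.1)
    group_ppi_test(a, rnorm(17, 0, 0.1))$p < 0.001
  }))
  expect_gte(hits, 0.95)
})
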