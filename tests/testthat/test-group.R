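test_that("Bonferroni thresholds reproduce the reported levels", {
  expect_equal(bonferroni_threshold(0.05, 19) * 19, 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 19), 2), 0.0026)
  expect_equal(round(bonferroni_threshold(0.05, 7), 3), 0.007)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 5), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_comparisons")
})

test_that("shared-path counting is plain set arithmetic", {
  nodes <- roi4()
  m1 <- path_model(nodes, rbind(c("FP", "pSTS"), c("pSTS", "PCC"),
                                c("PCC", "rACC"), c("rACC", "FP"),
                                c("FP", "PCC")))
  expect_equal(count_shared_paths(list(a = m1, b = m1))$count, 5)
  m2 <- path_model(nodes, rbind(c("pSTS", "FP"), c("PCC", "pSTS")))
  expect_equal(count_shared_paths(list(a = m1, b = m2))$count, 0)
  # pairwise-different single shared edges
  e1 <- c("FP", "pSTS"); e2 <- c("PCC", "rACC")
  A <- path_model(nodes, rbind(e1, c("FP", "rACC")))
  B <- path_model(nodes, rbind(e1, e2))
  C <- path_model(nodes, rbind(e2, c("pSTS", "FP")))
  res <- count_shared_paths(list(A = A, B = B, C = C))
  expect_equal(res$count, 2)
  expect_setequal(res$paths, c("FP->pSTS", "PCC->rACC"))
})

test_that("pathwise comparisons are paired, antisymmetric and guarded", {
  set.seed(30)
  paths <- c("FP->pSTS", "pSTS->PCC", "rACC->pSTS")
  A <- matrix(rnorm(17 * 3), 17, 3, dimnames = list(NULL, paths))
  B <- A + matrix(rnorm(17 * 3, sd = 0.3), 17, 3)
  res_ab <- compare_paths(A, B, alpha = 0.05, n_comparisons = 19)
  res_ba <- compare_paths(B, A, alpha = 0.05, n_comparisons = 19)
  expect_equal(res_ab$t, -res_ba$t)
  expect_equal(res_ab$threshold, rep(0.05 / 19, 3))
  expect_equal(res_ab$significant, res_ab$p < 0.05 / 19)
  # identical coefficients: t = 0, not significant
  res_id <- compare_paths(A, A)
  expect_equal(res_id$t, rep(0, 3))
  expect_false(any(res_id$significant))
  # missing path is marked not-comparable, never dropped
  res_m <- compare_paths(A, B[, 1:2], paths = paths)
  expect_equal(sum(!res_m$comparable), 1)
  expect_true(all(is.na(res_m$t[!res_m$comparable])))
  expect_error(compare_paths(A[1:2, ], B[1:2, ]), "3 subjects")
})

test_that("a fixed shift is detected under Bonferroni at n = 17", {
  set.seed(31)
  hits <- mean(replicate(200, {
    a <- matrix(rnorm(17, 0, 0.1), ncol = 1,
                dimnames = list(NULL, "FP->pSTS"))
    b <- a + 1 + rnorm(17, 0, 0.1)
    compare_paths(b, a, n_comparisons = 19)$significant
  }))
  expect_gte(hits, 0.95)
})

test_that("confirmatory cohort fits isolate failures per subject", {
  d <- dag3()
  Sig <- model_implied_covariance(d$B, d$psi)
  series <- list(S1 = Sig, S2 = Sig, S3 = diag(0, 3))  # third is singular
  res <- confirmatory_fit_cohort(series, d$model, n = 100)
  expect_equal(unname(res$coefficients[1, ]),
               unname(res$coefficients[2, ]))
  expect_true(all(is.na(res$coefficients[3, ])))
  expect_match(res$reasons[3], "positive definite")
  # shared covariance gives identical rows equal to the generating values
  expect_equal(unname(res$coefficients[1, "x->y"]), 0.7, tolerance = 1e-6)
})

test_that("between-subject coefficient spread grows with subject_sd", {
  p <- make_paradigm(seed = 6)
  rec <- justice_recovery_model()
  spread <- vapply(c(0.05, 0.1, 0.2), function(ssd) {
    gm <- default_generating_model(subject_sd = ssd)
    gm$B_by_condition$justice <- rec$B
    sds <- vapply(1:40, function(s) {
      cohort <- simulate_cohort(gm, p, 8, seed = s)
      cs <- lapply(cohort, function(x)
        extract_condition_blocks(x$timeseries, p, "justice"))
      conf <- confirmatory_fit_cohort(cs, rec$model, seed = s)
      stats::sd(conf$coefficients[, "FP->pSTS"], na.rm = TRUE)
    }, 0)
    mean(sds)
  }, 0)
  expect_true(all(diff(spread) > 0))
})

test_that("stepwise regression honours entry/removal thresholds", {
  set.seed(32)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
  # perfect predictor: selected alone with r^2 = 1
  res <- stepwise_regress(X, X[, "p3"])
  expect_identical(res$selected, "p3")
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  # constant column rejected
  Xc <- cbind(X, k = 1)
  expect_error(stepwise_regress(Xc, rnorm(40)), "constant")
  # no relationship: empty selection is a result, not an error
  res0 <- stepwise_regress(X, rep(c(1, 2), 20) + 0.001 * rnorm(40))
  expect_s3_class(res0, "stepwise_result")
})

test_that("two orthogonal true predictors enter in slope order", {
  set.seed(33)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- stats::residuals(stats::lm(x2 ~ x1))  # exactly orthogonal
  x1 <- scale(x1)[, 1]; x2 <- scale(x2)[, 1]
  y <- 0.8 * x1 + 0.5 * x2 + rnorm(n, sd = 0.33)
  X <- cbind(strong = x1, weak = x2, noise = rnorm(n))
  res <- stepwise_regress(X, y)
  expect_identical(res$selected[1:2], c("strong", "weak"))
  expect_true(all(diff(res$steps$r_squared[res$steps$action == "enter"]) > 0))
})

test_that("stepwise equals absolute-correlation ranking on orthonormal designs", {
  set.seed(34)
  n <- 64
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n, 5))))[, 2:6]  # mean-zero
  colnames(Q) <- paste0("q", 1:5)
  beta <- c(1.2, -0.9, 0.6, 0, 0)
  y <- Q %*% beta + rnorm(n, sd = 0.2)
  res <- stepwise_regress(Q, drop(y))
  # closed-form oracle: on an orthonormal, mean-zero design the entry order
  # is exactly the descending |projection| order
  r_abs <- abs(drop(crossprod(Q, y - mean(y))))
  oracle_order <- names(sort(r_abs, decreasing = TRUE))
  expect_identical(res$selected,
                   oracle_order[seq_along(res$selected)])
  expect_gte(length(res$selected), 2)
})

test_that("null stepwise selection rate matches a permutation oracle", {
  set.seed(35)
  n <- 17; k <- 7
  # analytic step-1 family-wise rate under independence, verified by a
  # permutation oracle rather than assumed
  sims <- replicate(600, {
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    length(stepwise_regress(X, y)$selected) >= 1
  })
  rate <- mean(sims)
  perm_rate <- mean(replicate(600, {
    X <- matrix(rnorm(n * k), n, k)
    y <- sample(rnorm(n))
    ps <- vapply(seq_len(k), function(j) {
      summary(stats::lm(y ~ X[, j]))$coefficients[2, 4]
    }, 0)
    min(ps) < 0.05
  }))
  se <- sqrt(perm_rate * (1 - perm_rate) / 600) +
    sqrt(rate * (1 - rate) / 600)
  expect_lt(abs(rate - perm_rate), 3 * se + 0.02)
})
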