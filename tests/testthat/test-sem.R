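test_that("model-implied covariance matches closed forms and simulation", {
  expect_equal(model_implied_covariance(matrix(0, 4, 4), rep(1, 4)), diag(4))
  B <- matrix(0, 2, 2); B[2, 1] <- 0.5
  expect_equal(model_implied_covariance(B, c(1, 1)),
               matrix(c(1, 0.5, 0.5, 1.25), 2, 2))
  # Monte-Carlo oracle on a random stable system
  set.seed(8)
  B3 <- random_stable_B(3)
  psi <- runif(3, 0.5, 2)
  Sig <- model_implied_covariance(B3, psi)
  expect_lt(max(abs(Sig - t(Sig))), 1e-12)
  expect_true(all(eigen(Sig, only.values = TRUE)$values > 0))
  e <- matrix(rnorm(3e5 * 3), ncol = 3) * rep(sqrt(psi), each = 3e5)
  x <- t(solve(diag(3) - B3, t(e)))
  expect_lt(norm(stats::cov(x) - Sig, "F") / norm(Sig, "F"), 0.02)
  B[1, 1] <- 1  # I - B singular
  expect_error(model_implied_covariance(B, c(1, 1)), "singular")
})

test_that("ML discrepancy has its closed-form values and positivity", {
  S <- diag(2)
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(diag(c(2, 1)), diag(2)), 1 - log(2))
  set.seed(9)
  for (i in 1:200) {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
    Bm <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
    f <- ml_discrepancy(A, Bm)
    expect_gte(f, 0)
  }
  expect_error(ml_discrepancy(diag(2), -diag(2)), "positive definite")
  # zero discrepancy iff matrices coincide
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_lt(ml_discrepancy(A, A + 0), 1e-12)
  expect_gt(ml_discrepancy(A, A + diag(0.1, 3)), 1e-4)
})

test_that("recursive fits recover generating parameters exactly", {
  d <- dag3()
  Sig <- model_implied_covariance(d$B, d$psi)
  fit <- fit_sem(Sig, 500, d$model)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$B - d$B)), 1e-4)
  expect_lt(max(abs(fit$psi - d$psi)), 1e-4)
  # two-node analytic case
  S2 <- matrix(c(1, 0.5, 0.5, 1.25), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  f2 <- fit_sem(S2, 200, path_model(c("a", "b"), rbind(c("a", "b"))))
  expect_equal(unname(f2$B[2, 1]), 0.5, tolerance = 1e-10)
  expect_equal(unname(f2$psi), c(1, 1), tolerance = 1e-10)
})

test_that("a just-identified recursive model reproduces S exactly", {
  set.seed(10)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  dimnames(S) <- rep(list(c("n1", "n2", "n3", "n4")), 2)
  # saturated recursive edge set: full lower-triangular ordering
  edges <- do.call(rbind, lapply(2:4, function(j) {
    cbind(paste0("n", seq_len(j - 1)), paste0("n", j))
  }))
  fit <- fit_sem(S, 100, path_model(paste0("n", 1:4), edges))
  expect_equal(fit$df, 0)
  expect_lt(fit$fml, 1e-8)
  expect_lt(max(abs(model_implied_covariance(fit$B, fit$psi) - S)), 1e-6)
})

test_that("identified non-recursive (feedback) systems are recovered", {
  nodes <- c("x", "y", "z")
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  B["y", "x"] <- 0.8; B["y", "z"] <- 0.5; B["z", "y"] <- -0.6
  Sig <- model_implied_covariance(B, c(1, 0.8, 1.2))
  fit <- fit_sem(Sig, 500,
                 path_model(nodes, rbind(c("x", "y"), c("z", "y"),
                                         c("y", "z"))), seed = 2)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$B - B)), 1e-6)
  expect_equal(fit$stability, roisem:::spectral_radius(B), tolerance = 1e-6)
})

test_that("locally non-identified reciprocal loops are flagged, not hidden", {
  # pure 2-cycle without instruments: exact fit but singular information
  nodes <- c("u", "v", "w")
  Bc <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  Bc["u", "v"] <- 0.4; Bc["v", "u"] <- 0.5
  S2 <- model_implied_covariance(Bc, c(1, 1, 1))
  f <- fit_sem(S2, 300,
               path_model(nodes, rbind(c("u", "v"), c("v", "u"))), seed = 3)
  expect_lt(f$fml, 1e-8)        # the discrepancy is driven to zero
  expect_false(f$converged)     # but the solution is not identified
})

test_that("adding an edge never increases the minimised discrepancy", {
  set.seed(11)
  nodes <- c("a", "b", "c")
  for (i in 1:40) {
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
    dimnames(S) <- list(nodes, nodes)
    all_e <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    all_e <- all_e[all_e$from != all_e$to, ]
    k <- sample(0:2, 1)
    base_idx <- sample(nrow(all_e), k)
    extra <- sample(setdiff(seq_len(nrow(all_e)), base_idx), 1)
    m_small <- path_model(nodes, as.matrix(all_e[base_idx, , drop = FALSE]))
    m_large <- path_model(nodes,
                          as.matrix(all_e[c(base_idx, extra), , drop = FALSE]))
    f_small <- fit_sem(S, 200, m_small, se = FALSE, restarts = 4, seed = i)
    f_large <- fit_sem(S, 200, m_large, se = FALSE, restarts = 4, seed = i)
    expect_lte(f_large$fml, f_small$fml + 1e-6)
  }
})

test_that("finite-sample estimates approach the truth as n grows", {
  d <- dag3()
  m <- generating_model(d$nodes, list(neutral = d$B),
                        Psi_by_condition = list(neutral = d$psi),
                        noise_sd = 0, subject_sd = 0, score_sd = 0)
  med_err <- vapply(c(100, 400, 1600), function(n) {
    errs <- vapply(1:30, function(s) {
      p <- paradigm(0, n, "neutral", tr = 1, n_scans = n)
      x <- simulate_subject(m, p, seed = s * 1000 + n)$neural
      fit <- fit_sem(stats::cov(x), n, d$model, se = FALSE)
      max(abs(fit$B - d$B))
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(all(diff(med_err) < 0))
})

test_that("reported standard errors track the sampling variability", {
  d <- dag3()
  Sig <- model_implied_covariance(d$B, d$psi)
  R <- chol(Sig)
  set.seed(12)
  out <- t(replicate(500, {
    x <- matrix(rnorm(500 * 3), ncol = 3) %*% R
    fit <- fit_sem(stats::cov(x), 500, d$model)
    c(fit$params$estimate[1], fit$params$se[1])
  }))
  ratio <- stats::sd(out[, 1]) / mean(out[, 2])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.2)
})

test_that("fit index panel follows the stated formulas", {
  d <- dag3()
  Sig <- model_implied_covariance(d$B, d$psi)
  fit <- fit_sem(Sig, 500, d$model)
  ix <- fit$indices
  expect_equal(ix$gfi, 1, tolerance = 1e-8)
  expect_equal(ix$srmr, 0, tolerance = 1e-8)
  expect_equal(ix$chisq, 0, tolerance = 1e-6)
  expect_equal(ix$aic, fit$chisq + 2 * fit$q)
  # arithmetic identities on a synthetic fit object
  fake <- fit
  fake$chisq <- 100; fake$df <- 10; fake$n <- 101; fake$q <- 10
  ix2 <- fit_indices(fake, Sig)
  expect_equal(ix2$rmsea, 0.3)
  fake$chisq <- 50
  expect_equal(fit_indices(fake, Sig)$aic, 70)
  # df = 0: RMSEA/AGFI/PGFI are not-applicable markers, never a division
  sat <- fit_sem(Sig, 500, path_model(d$nodes,
                                      rbind(c("x", "y"), c("x", "z"),
                                            c("y", "z"))))
  expect_true(is.na(sat$indices$rmsea))
  expect_true(is.na(sat$indices$agfi))
  expect_true(is.na(sat$indices$pgfi))
  # min_t is the smallest |t| over free path coefficients
  expect_equal(fit$indices$min_t,
               min(abs(fit$params$t[1:2])))
})

test_that("condition blocks follow the shift-and-trim rule", {
  set.seed(13)
  ts <- matrix(rnorm(120 * 2), ncol = 2, dimnames = list(NULL, c("r1", "r2")))
  p <- paradigm(c(0, 30, 60), c(15, 15, 15),
                c("neutral", "care", "neutral"), tr = 1, n_scans = 120)
  cs <- extract_condition_blocks(ts, p, "care")
  # block at 30 s: shifted window [36, 51) -> scans 36..50; minus 2 head,
  # 1 tail -> scan times 38..49... with 15 s window: scans 36-50 are 15
  # samples; default trimming leaves 12
  expect_equal(cs$n_samples, 12)
  expect_equal(cs$samples, ts[39:50, ], ignore_attr = TRUE)
  # identity configuration returns exactly the in-block scans
  cs0 <- extract_condition_blocks(ts, p, "care", shift = 0, drop_head = 0,
                                  drop_tail = 0)
  expect_equal(cs0$samples, ts[31:45, ], ignore_attr = TRUE)
  # covariance equals the brute-force covariance of the concatenation
  cs2 <- extract_condition_blocks(ts, p, "neutral")
  rows <- c(9:20, 69:80)
  expect_equal(cs2$S, stats::cov(ts[rows, ]))
  expect_error(extract_condition_blocks(ts, p, "justice"), "not present")
  expect_error(extract_condition_blocks(ts, p, "care", shift = 200), "block")
})
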