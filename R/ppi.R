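#' First eigenvariate of a set of member series
#'
#' The summary time course of a region: the first left singular vector of
#' the column-centred member matrix, scaled to the standard deviation of the
#' mean member series and signed so it correlates non-negatively with that
#' mean series.
#'
#' @param series_matrix Scans x members numeric matrix (>= 1 column).
#' @return Numeric series of length `nrow(series_matrix)`.
#' @export
first_eigenvariate <- function(series_matrix) {
  M <- as.matrix(series_matrix)
  if (ncol(M) < 1L) stop_("need at least one member column")
  Mc <- scale(M, center = TRUE, scale = FALSE)
  if (max(abs(Mc)) == 0) stop_("zero-variance member matrix")
  sv <- svd(Mc, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1]
  mean_series <- rowMeans(M)
  s_ref <- stats::sd(mean_series)
  if (s_ref > 0) e <- e * (s_ref / stats::sd(e))
  if (stats::sd(mean_series) > 0 && stats::cor(e, mean_series) < 0) e <- -e
  e
}

#' Build psychophysiological-interaction regressors
#'
#' Constructs the three PPI regressors for a pairwise condition contrast:
#' the physiological regressor (the centred seed series), the psychological
#' regressor (+1 during `contrast[1]` segments, -1 during `contrast[2]`,
#' 0 elsewhere, mean-centred over the coded scans), and their interaction.
#' In `multiply` mode the interaction is the elementwise product of centred
#' seed and psychological vector. In `deconvolve` mode the seed is first
#' deconvolved to neural scale by ridge-regularised least squares against
#' the HRF convolution operator (ridge penalty chosen by generalised
#' cross-validation), multiplied by the psychological vector, and
#' reconvolved with the HRF.
#'
#' @param seed Seed ROI series (length `n_scans`).
#' @param paradigm A [paradigm()].
#' @param contrast Character vector of two condition labels `(condA, condB)`.
#' @param mode `"multiply"` (default) or `"deconvolve"`.
#' @param hrf HRF kernel sampled at the paradigm `tr`.
#' @return Object of class `ppi_regressors` with `physiological`,
#'   `psychological`, `interaction`, `mode`.
#' @export
build_ppi_regressors <- function(seed, paradigm, contrast,
                                 mode = c("multiply", "deconvolve"),
                                 hrf = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(paradigm, "paradigm"), length(contrast) == 2)
  if (length(seed) != paradigm$n_scans) {
    stop_("seed length (%d) does not match n_scans (%d)",
          length(seed), paradigm$n_scans)
  }
  present <- unique(paradigm$segments$category)
  missing <- setdiff(contrast, present)
  if (length(missing)) {
    stop_("contrast condition(s) absent from paradigm: %s",
          paste(missing, collapse = ", "))
  }
  cond <- condition_at_scans(paradigm)
  psych <- rep(0, paradigm$n_scans)
  psych[cond == contrast[1]] <- 1
  psych[cond == contrast[2]] <- -1
  coded <- psych != 0
  if (!any(coded)) stop_("no scans are coded by the contrast conditions")
  psych[coded] <- psych[coded] - mean(psych[coded])
  phys <- seed - mean(seed)
  if (mode == "multiply") {
    interaction <- phys * psych
  } else {
    hrf <- hrf %||% canonical_hrf(paradigm$tr)
    n <- length(seed)
    H <- matrix(0, n, n)
    for (j in seq_len(n)) {
      k <- seq_len(min(length(hrf), n - j + 1))
      H[j + k - 1, j] <- hrf[k]
    }
    z <- deconvolve_ridge(phys, H)
    interaction <- drop(H %*% (z * psych))
    interaction <- interaction - mean(interaction)
  }
  structure(list(physiological = phys, psychological = psych,
                 interaction = interaction, mode = mode,
                 contrast = contrast),
            class = "ppi_regressors")
}

# ridge deconvolution with GCV-selected penalty
deconvolve_ridge <- function(y, H, lambdas = 10^seq(-4, 2, by = 0.5)) {
  n <- length(y)
  sv <- svd(H)
  uty <- crossprod(sv$u, y)
  best <- NULL
  for (lam in lambdas) {
    shrink <- sv$d / (sv$d^2 + lam)
    fit_coef <- sv$d * shrink     # hat-matrix eigenvalues d^2/(d^2+lam)
    rss <- sum(((1 - fit_coef) * uty)^2)
    edf <- sum(fit_coef)
    gcv <- n * rss / (n - edf)^2
    if (is.null(best) || gcv < best$gcv) best <- list(gcv = gcv, lam = lam)
  }
  shrink <- sv$d / (sv$d^2 + best$lam)
  drop(sv$v %*% (shrink * uty))
}

#' Fit the PPI regression for one target ROI
#'
#' OLS of the target series on physiological, psychological and interaction
#' regressors plus optional confound columns and a constant; the interaction
#' term's slope and t-value quantify the task-dependent change in
#' seed-target coupling.
#'
#' @param target Target ROI series.
#' @param regs A [build_ppi_regressors()] result.
#' @param confounds Optional matrix of confound regressors (e.g. drift
#'   columns of a [build_design_matrix()]).
#' @return Object of class `ppi_result`: `beta`, `se`, `t`, `df`, `p` for
#'   the interaction term, plus full `betas`.
#' @export
fit_ppi <- function(target, regs, confounds = NULL) {
  stopifnot(inherits(regs, "ppi_regressors"))
  n <- length(regs$physiological)
  if (length(target) != n) stop_("target length does not match regressors")
  X <- cbind(physiological = regs$physiological,
             psychological = regs$psychological,
             interaction = regs$interaction)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    }
    keep <- colnames(confounds) != "constant"
    X <- cbind(X, confounds[, keep, drop = FALSE])
  }
  X <- cbind(X, constant = 1)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_("collinear PPI regressors (rank %d < %d columns)", qx$rank, ncol(X))
  }
  beta <- qr.coef(qx, target)
  res <- target - X %*% beta
  df <- n - qx$rank
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  j <- which(colnames(X) == "interaction")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- beta[j] / se
  structure(list(beta = unname(beta[j]), se = se, t = unname(tval), df = df,
                 p = 2 * stats::pt(-abs(tval), df),
                 betas = stats::setNames(drop(beta), colnames(X)),
                 mode = regs$mode, contrast = regs$contrast),
            class = "ppi_result")
}

#' @export
print.ppi_result <- function(x, ...) {
  cat(sprintf("ppi_result (%s, %s - %s): interaction beta %.4g, t(%d) = %.3f, p = %.3g\n",
              x$mode, x$contrast[1], x$contrast[2], x$beta, x$df, x$t, x$p))
  invisible(x)
}

#' Group-level paired test on PPI interaction slopes
#'
#' Paired t-test across subjects on the per-subject interaction betas of two
#' conditions (or contrasts).
#'
#' @param betas_a,betas_b Paired per-subject interaction betas.
#' @return List with `t`, `df`, `p`, `mean_difference`, `n`.
#' @export
group_ppi_test <- function(betas_a, betas_b) {
  if (length(betas_a) != length(betas_b)) stop_("betas must be paired")
  n <- length(betas_a)
  if (n < 3) stop_("need at least 3 subjects")
  d <- betas_a - betas_b
  if (stats::sd(d) <= 1e-12 * (1 + abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) {
      return(list(t = 0, df = n - 1, p = 1, mean_difference = 0, n = n))
    }
    stop_("zero variance of paired differences")
  }
  tt <- stats::t.test(betas_a, betas_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = mean(d), n = n)
}
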