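#' Build a GLM design matrix for a block paradigm
#'
#' One regressor per condition present in the paradigm (its boxcar convolved
#' with the canonical HRF and sampled at scan times), followed by
#' discrete-cosine drift regressors up to the high-pass cutoff, and a
#' constant column last.
#'
#' @param paradigm A [paradigm()].
#' @param hrf HRF kernel sampled at the paradigm `tr` (default
#'   [canonical_hrf()]).
#' @param drift_order Number of DCT drift columns; default derived from
#'   `highpass_cutoff` as `floor(2 * n_scans * tr / cutoff)`. Use 0 for a
#'   constant-only baseline.
#' @param highpass_cutoff High-pass period in seconds (default 128).
#' @return Object of class `design_matrix`: `matrix` (scans x regressors
#'   with labelled columns), `conditions`, `tr`.
#' @export
build_design_matrix <- function(paradigm, hrf = NULL, drift_order = NULL,
                                highpass_cutoff = 128) {
  stopifnot(inherits(paradigm, "paradigm"))
  hrf <- hrf %||% canonical_hrf(paradigm$tr)
  n <- paradigm$n_scans
  t <- scan_times(paradigm)
  conds <- unique(paradigm$segments$category)
  cols <- lapply(conds, function(cond) {
    segs <- paradigm$segments[paradigm$segments$category == cond, ,
                              drop = FALSE]
    box <- rep(0, n)
    for (i in seq_len(nrow(segs))) {
      box[t >= segs$onset[i] - 1e-9 &
            t < segs$onset[i] + segs$duration[i] - 1e-9] <- 1
    }
    convolve_causal(box, hrf)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- conds
  if (is.null(drift_order)) {
    drift_order <- max(floor(2 * n * paradigm$tr / highpass_cutoff), 0)
  }
  if (drift_order > 0) {
    i <- seq_len(n) - 1
    D <- sapply(seq_len(drift_order), function(k) {
      sqrt(2 / n) * cos(pi * (2 * i + 1) * k / (2 * n))
    })
    colnames(D) <- paste0("drift_", seq_len(drift_order))
    X <- cbind(X, D)
  }
  X <- cbind(X, constant = 1)
  if (qr(X)$rank < ncol(X) || kappa(X) > 1e10) {
    stop_("design matrix is rank deficient or near-collinear")
  }
  structure(list(matrix = X, conditions = conds, tr = paradigm$tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d scans x %d regressors (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(colnames(x$matrix), collapse = ", ")))
  invisible(x)
}

#' Fit an ordinary-least-squares GLM to one ROI series
#'
#' @param y Numeric BOLD series for one ROI.
#' @param design A [build_design_matrix()] result (or a plain labelled
#'   matrix).
#' @param contrasts Named list of contrast vectors over condition labels,
#'   e.g. `list(care_gt_neutral = c(care = 1, neutral = -1))`; entries for
#'   unnamed regressors default to 0.
#' @return Object of class `glm_fit`: `betas`, `sigma2` (residual variance),
#'   `df` (scans - rank), `residuals`, and a `contrasts` data frame with
#'   estimate, SE, t and two-sided p per contrast
#'   (`t = c'b / sqrt(sigma2 c'(X'X)^-1 c)`).
#' @export
fit_glm <- function(y, design, contrasts = NULL) {
  X <- if (inherits(design, "design_matrix")) design$matrix else design
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (length(y) != nrow(X)) {
    stop_("series length (%d) does not match design rows (%d)",
          length(y), nrow(X))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    stop_("design matrix is rank deficient; collinear column(s): %s",
          paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- nrow(X) - qx$rank
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  ctab <- NULL
  if (!is.null(contrasts)) {
    ctab <- do.call(rbind, lapply(names(contrasts), function(nm) {
      cv <- contrasts[[nm]]
      bad <- setdiff(names(cv), colnames(X))
      if (length(bad)) stop_("contrast '%s' names unknown regressor(s): %s",
                             nm, paste(bad, collapse = ", "))
      cfull <- stats::setNames(rep(0, ncol(X)), colnames(X))
      cfull[names(cv)] <- cv
      est <- sum(cfull * beta)
      vr <- sigma2 * drop(t(cfull) %*% xtx_inv %*% cfull)
      tval <- if (all(cfull == 0)) 0 else est / sqrt(vr)
      data.frame(contrast = nm, estimate = est,
                 se = sqrt(vr), t = tval,
                 p = 2 * stats::pt(-abs(tval), df),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(betas = stats::setNames(drop(beta), colnames(X)),
                 sigma2 = sigma2, df = df, residuals = drop(res),
                 contrasts = ctab),
            class = "glm_fit")
}

#' Correlate per-subject contrast values with behaviour scores
#'
#' Simple regression of scores on contrast values: Pearson r, r-squared,
#' and the F-test p-value of the regression.
#'
#' @param contrast_values Per-subject contrast estimates.
#' @param scores Per-subject behaviour scores, same order.
#' @return List with `r`, `r_squared`, `p`, `n`.
#' @export
group_contrast_correlation <- function(contrast_values, scores) {
  stopifnot(length(contrast_values) == length(scores))
  n <- length(scores)
  if (n < 3) stop_("need at least 3 subjects")
  if (stats::sd(contrast_values) == 0 || stats::sd(scores) == 0) {
    stop_("zero variance in contrast values or scores")
  }
  r <- stats::cor(contrast_values, scores)
  fstat <- (r^2 / (1 - r^2)) * (n - 2)
  p <- if (abs(r) >= 1) 0 else stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(r = r, r_squared = r^2, p = p, n = n)
}

#' Median-split comparison of contrast values by behaviour score
#'
#' Splits subjects at the median score (subjects strictly above the median
#' form the "high" group; ties go to "low"), then compares contrast values
#' between groups with a Welch two-sample t-test.
#'
#' @param scores Per-subject behaviour scores.
#' @param contrast_values Per-subject contrast estimates.
#' @return List with the per-group summary (`groups` data frame: n, score
#'   mean/sd, contrast mean/sd), `median`, `t`, `df`, `p`.
#' @export
median_split_compare <- function(scores, contrast_values) {
  stopifnot(length(scores) == length(contrast_values))
  if (stats::sd(scores) == 0) stop_("all scores identical; cannot split")
  med <- stats::median(scores)
  high <- scores > med
  if (sum(high) < 2 || sum(!high) < 2) {
    stop_("need at least 2 subjects per split group")
  }
  if (stats::sd(contrast_values[high]) == 0 &&
      stats::sd(contrast_values[!high]) == 0) {
    same <- mean(contrast_values[high]) == mean(contrast_values[!high])
    tt <- list(statistic = if (same) 0 else sign(mean(contrast_values[high]) -
                                                   mean(contrast_values[!high])) * Inf,
               parameter = NA_real_, p.value = if (same) 1 else 0)
  } else {
    tt <- stats::t.test(contrast_values[high], contrast_values[!high],
                        var.equal = FALSE)
  }
  groups <- data.frame(
    group = c("high", "low"), n = c(sum(high), sum(!high)),
    score_mean = c(mean(scores[high]), mean(scores[!high])),
    score_sd = c(stats::sd(scores[high]), stats::sd(scores[!high])),
    contrast_mean = c(mean(contrast_values[high]), mean(contrast_values[!high])),
    contrast_sd = c(stats::sd(contrast_values[high]),
                    stats::sd(contrast_values[!high])),
    stringsAsFactors = FALSE)
  list(groups = groups, median = med, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
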