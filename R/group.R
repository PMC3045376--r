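#' Bonferroni per-comparison significance level
#'
#' @param alpha Family-wise error level (0 < alpha < 1).
#' @param n_comparisons Number of comparisons in the family (>= 1).
#' @return `alpha / n_comparisons`.
#' @examples
#' bonferroni_threshold(0.05, 19)  # 0.00263..., reported as 0.0026
#' bonferroni_threshold(0.05, 7)   # 0.00714..., reported as 0.007
#' @export
bonferroni_threshold <- function(alpha, n_comparisons) {
  if (alpha <= 0 || alpha >= 1) stop_("alpha must be in (0, 1)")
  if (n_comparisons < 1) stop_("n_comparisons must be >= 1")
  alpha / n_comparisons
}

#' Paths shared by two or more condition models
#'
#' @param models Named list (>= 2) of [path_model()] objects, one per
#'   condition.
#' @return List with `count` and the character vector `paths`
#'   ("from->to"), each present in at least two models.
#' @export
count_shared_paths <- function(models) {
  stopifnot(is.list(models), length(models) >= 2)
  sets <- lapply(models, function(m) {
    stopifnot(inherits(m, "path_model"))
    unique(edge_label(m$edges[, 1], m$edges[, 2]))
  })
  all_paths <- unlist(sets, use.names = FALSE)
  tallies <- table(all_paths)
  shared <- names(tallies)[tallies >= 2]
  list(count = length(shared), paths = shared)
}

#' Pathwise comparison of conditions with Bonferroni control
#'
#' For every path, a paired t-test across subjects on the per-subject
#' confirmatory coefficients of the two conditions. Significance is judged
#' against the Bonferroni-corrected per-comparison level
#' `alpha / n_comparisons`. Paths missing from either condition's
#' coefficient table are marked not comparable rather than dropped.
#'
#' @param coefs_a,coefs_b Subjects x paths coefficient matrices (columns
#'   named "from->to"), paired by row.
#' @param paths Character paths to compare (default: union of columns).
#' @param alpha Family-wise level (default 0.05).
#' @param n_comparisons Size of the comparison family (default:
#'   `length(paths)`).
#' @return Data frame with one row per path: per-condition mean betas, t,
#'   df, raw p, the corrected threshold, `significant` and `comparable`.
#' @export
compare_paths <- function(coefs_a, coefs_b, paths = NULL, alpha = 0.05,
                          n_comparisons = NULL) {
  coefs_a <- as.matrix(coefs_a)
  coefs_b <- as.matrix(coefs_b)
  if (nrow(coefs_a) != nrow(coefs_b)) {
    stop_("conditions have different subject counts; comparisons are paired")
  }
  if (nrow(coefs_a) < 3) stop_("need at least 3 subjects")
  paths <- paths %||% union(colnames(coefs_a), colnames(coefs_b))
  n_comparisons <- n_comparisons %||% length(paths)
  thr <- bonferroni_threshold(alpha, n_comparisons)
  rows <- lapply(paths, function(pth) {
    in_a <- pth %in% colnames(coefs_a)
    in_b <- pth %in% colnames(coefs_b)
    if (!in_a || !in_b) {
      return(data.frame(path = pth,
                        beta_a = if (in_a) mean(coefs_a[, pth]) else NA_real_,
                        beta_b = if (in_b) mean(coefs_b[, pth]) else NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        threshold = thr, significant = NA,
                        comparable = FALSE, stringsAsFactors = FALSE))
    }
    d <- coefs_a[, pth] - coefs_b[, pth]
    if (stats::sd(d) == 0) {
      tval <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
      pval <- if (all(d == 0)) 1 else 0
      dfv <- length(d) - 1
    } else {
      tt <- stats::t.test(coefs_a[, pth], coefs_b[, pth], paired = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
      dfv <- unname(tt$parameter)
    }
    data.frame(path = pth, beta_a = mean(coefs_a[, pth]),
               beta_b = mean(coefs_b[, pth]), t = tval, df = dfv, p = pval,
               threshold = thr, significant = pval < thr, comparable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Confirmatory per-subject fits of a fixed group model
#'
#' Fits one fixed topology to every subject's condition covariance via
#' [fit_sem()]. Subjects whose fit fails or does not converge are flagged
#' with a reason and their coefficients set to `NA` so downstream analyses
#' can exclude them explicitly.
#'
#' @param series_list List of per-subject [extract_condition_blocks()]
#'   results (or plain covariance matrices, in which case `n` is required).
#' @param group_model A [path_model()].
#' @param n Sample size per subject when plain covariances are given.
#' @param restarts,seed Passed to [fit_sem()].
#' @return List with `coefficients` (subjects x paths matrix, columns
#'   "from->to"), `converged` (logical), `reasons`, and the per-subject
#'   `fits`.
#' @export
confirmatory_fit_cohort <- function(series_list, group_model, n = NULL,
                                    restarts = 10, seed = 1) {
  stopifnot(inherits(group_model, "path_model"), length(series_list) >= 1)
  labels <- edge_label(group_model$edges[, 1], group_model$edges[, 2])
  coefs <- matrix(NA_real_, length(series_list), length(labels),
                  dimnames = list(names(series_list) %||%
                                    sprintf("sub-%02d", seq_along(series_list)),
                                  labels))
  conv <- logical(length(series_list))
  reasons <- character(length(series_list))
  fits <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    x <- series_list[[i]]
    if (inherits(x, "condition_series")) {
      S <- x$S; ni <- x$n_samples
    } else {
      S <- as.matrix(x)
      ni <- n %||% stop_("n is required when passing plain covariances")
    }
    fit <- tryCatch(
      fit_sem(S, ni, group_model, restarts = restarts,
              seed = derive_seed(seed, sprintf("confirm-%04d", i))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      reasons[i] <- conditionMessage(fit)
    } else {
      fits[[i]] <- fit
      conv[i] <- fit$converged
      if (fit$converged) {
        coefs[i, ] <- fit$params$estimate[seq_along(labels)]
      } else {
        reasons[i] <- "did not converge"
      }
    }
  }
  list(coefficients = coefs, converged = conv, reasons = reasons, fits = fits)
}

#' Stepwise regression of path coefficients onto behaviour scores
#'
#' Classic p-value-driven stepwise selection: at each step the candidate
#' predictor with the largest partial correlation (equivalently, smallest
#' increment-F p-value with df (1, n - k - 1)) enters if its p-value is
#' below `p_in`; after each entry any retained predictor whose partial-F
#' p-value exceeds `p_out` is removed. Iterates to a fixed point. An empty
#' selection (no predictor reaches `p_in`) is a valid result, not an error.
#'
#' @param coefficients Subjects x paths numeric matrix (no constant
#'   columns); rows with any `NA` are dropped with a message.
#' @param scores Per-subject behaviour scores.
#' @param p_in Entry threshold (default 0.05).
#' @param p_out Removal threshold (default 0.10).
#' @return Object of class `stepwise_result`: `selected` (ordered predictor
#'   names), `steps` (data frame of entries/removals with p and cumulative
#'   r-squared), `r_squared`, `coefficients` of the final model.
#' @export
stepwise_regress <- function(coefficients, scores, p_in = 0.05, p_out = 0.10) {
  X <- as.matrix(coefficients)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(scores) == nrow(X))
  ok <- stats::complete.cases(X) & !is.na(scores)
  if (!all(ok)) {
    message(sprintf("dropping %d subject(s) with missing coefficients",
                    sum(!ok)))
    X <- X[ok, , drop = FALSE]
    scores <- scores[ok]
  }
  n <- nrow(X)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop_("constant predictor column(s): %s",
          paste(colnames(X)[apply(X, 2, stats::sd) == 0], collapse = ", "))
  }

  r2_of <- function(sel) {
    if (!length(sel)) return(0)
    fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), scores)
    1 - sum(fit$residuals^2) / sum((scores - mean(scores))^2)
  }
  partial_p <- function(sel, var) {
    # p-value of `var` in the model containing sel (var included in sel or not)
    others <- setdiff(sel, var)
    k <- length(others) + 1
    if (n - k - 1 < 1) return(NA_real_)
    r2_full <- r2_of(c(others, var))
    r2_red <- r2_of(others)
    inc <- r2_full - r2_red
    denom <- (1 - r2_full) / (n - k - 1)
    if (denom < 1e-12) {
      # saturated fit: a vanishing increment carries no evidence
      return(if (inc < 1e-12) 1 else 0)
    }
    stats::pf(inc / denom, 1, n - k - 1, lower.tail = FALSE)
  }

  sel <- character(0)
  steps <- list()
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 4L * ncol(X) + 4L) break
    entered <- FALSE
    cand <- setdiff(colnames(X), sel)
    if (length(cand) && n > length(sel) + 3) {
      ps <- vapply(cand, function(v) partial_p(c(sel, v), v), numeric(1))
      best <- cand[which.min(ps)]
      if (is.finite(ps[best]) && ps[best] < p_in) {
        sel <- c(sel, best)
        steps[[length(steps) + 1L]] <- data.frame(
          step = length(steps) + 1L, action = "enter", path = best,
          p = unname(ps[best]), r_squared = r2_of(sel),
          stringsAsFactors = FALSE)
        entered <- TRUE
      }
    }
    repeat {
      if (length(sel) == 0L) break
      ps <- vapply(sel, function(v) partial_p(sel, v), numeric(1))
      worst <- sel[which.max(ps)]
      if (is.finite(ps[worst]) && ps[worst] > p_out) {
        sel <- setdiff(sel, worst)
        steps[[length(steps) + 1L]] <- data.frame(
          step = length(steps) + 1L, action = "remove", path = worst,
          p = unname(ps[worst]), r_squared = r2_of(sel),
          stringsAsFactors = FALSE)
      } else break
    }
    if (!entered) break
  }

  final_coef <- NULL
  if (length(sel)) {
    fit <- stats::lm.fit(cbind(`(intercept)` = 1, X[, sel, drop = FALSE]),
                         scores)
    final_coef <- fit$coefficients
  }
  structure(list(selected = sel,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(step = integer(0), action = character(0),
                                         path = character(0), p = numeric(0),
                                         r_squared = numeric(0)),
                 r_squared = r2_of(sel), coefficients = final_coef, n = n),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (!length(x$selected)) {
    cat("stepwise_result: no predictor met the entry threshold\n")
  } else {
    cat(sprintf("stepwise_result: selected %s; r^2 = %.3f (n = %d)\n",
                paste(x$selected, collapse = ", "), x$r_squared, x$n))
    print(x$steps, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
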