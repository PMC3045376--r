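#' Construct a path model
#'
#' A path model is a directed graph over named ROIs: each edge is a free
#' path coefficient and each node carries a free residual variance, so the
#' parameter count is `q = |edges| + |nodes|` and the degrees of freedom
#' against a p-node covariance are `df = p(p+1)/2 - q`.
#'
#' @param nodes Ordered character vector of node labels.
#' @param edges Two-column matrix or data frame with columns `from`, `to`
#'   (or a list of length-2 vectors); may have zero rows for the empty model.
#' @return An object of class `path_model` with elements `nodes`, `edges`
#'   (character matrix), `q`, `df`.
#' @export
path_model <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 2, !anyDuplicated(nodes))
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (is.list(edges) && length(edges) == 0L)) {
    edges <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.list(edges)) edges <- do.call(rbind, edges)
    edges <- matrix(as.character(edges), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  }
  bad <- setdiff(c(edges), nodes)
  if (length(bad)) stop_("edges reference unknown node(s): %s",
                         paste(unique(bad), collapse = ", "))
  if (any(edges[, 1] == edges[, 2])) stop_("self-loops are not allowed")
  lab <- edge_label(edges[, 1], edges[, 2])
  if (anyDuplicated(lab)) stop_("duplicate edge(s): %s",
                                paste(lab[duplicated(lab)], collapse = ", "))
  p <- length(nodes)
  q <- nrow(edges) + p
  structure(list(nodes = nodes, edges = edges, q = q,
                 df = p * (p + 1) / 2 - q),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("path_model: %d nodes, %d edges (q = %d, df = %d)%s\n",
              length(x$nodes), nrow(x$edges), x$q, x$df,
              if (is_acyclic(x)) ", recursive" else ", non-recursive"))
  if (nrow(x$edges)) {
    cat(" ", paste(edge_label(x$edges[, 1], x$edges[, 2]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Is a path model recursive (acyclic)?
#'
#' @param model A [path_model()].
#' @return TRUE when the directed edge set contains no cycle.
#' @export
is_acyclic <- function(model) {
  nodes <- model$nodes
  edges <- model$edges
  repeat {
    if (length(nodes) == 0L || nrow(edges) == 0L) return(TRUE)
    sinks <- setdiff(nodes, edges[, "from"])
    if (length(sinks) == 0L) return(FALSE)
    keep <- !(edges[, "to"] %in% sinks)
    edges <- edges[keep, , drop = FALSE]
    nodes <- setdiff(nodes, sinks)
  }
}

# coefficient matrix skeleton: B[target, source] free where edges exist
edge_index <- function(model) {
  p <- length(model$nodes)
  if (nrow(model$edges) == 0L) return(integer(0))
  i <- match(model$edges[, "to"], model$nodes)
  j <- match(model$edges[, "from"], model$nodes)
  (j - 1L) * p + i
}

#' Model-implied covariance of a linear structural system
#'
#' For the system `x = B x + e`, `e ~ N(0, diag(Psi))`, the implied
#' covariance is `Sigma = (I - B)^-1 diag(Psi) (I - B)^-T`.
#'
#' @param B Square path-coefficient matrix (`B[target, source]`).
#' @param Psi Vector of positive residual variances.
#' @return Symmetric positive-definite covariance matrix.
#' @export
model_implied_covariance <- function(B, Psi) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B), length(Psi) == nrow(B))
  if (any(Psi <= 0)) stop_("all residual variances must be > 0")
  if (!check_invertible(B)) stop_("I - B is singular")
  Ai <- solve(diag(nrow(B)) - B)
  S <- Ai %*% (Psi * t(Ai))
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(B)
  S
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The ML fit function minimised in covariance structure analysis:
#' `F_ML = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p`. Non-negative, and zero
#' exactly when `S == Sigma`.
#'
#' @param S Observed covariance (symmetric positive definite).
#' @param Sigma Model-implied covariance (symmetric positive definite, same
#'   order).
#' @return Scalar discrepancy value.
#' @export
ml_discrepancy <- function(S, Sigma) {
  if (!is_square_sym(S, 1e-8) || !is_square_sym(Sigma, 1e-8)) {
    stop_("S and Sigma must be symmetric square matrices")
  }
  if (nrow(S) != nrow(Sigma)) stop_("S and Sigma must have the same order")
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  cV <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS) || is.null(cV)) stop_("S and Sigma must be positive definite")
  Vinv <- chol2inv(cV)
  f <- 2 * sum(log(diag(cV))) + sum(S * Vinv) - 2 * sum(log(diag(cS))) - p
  max(f, 0)
}

# ---- internal ML machinery ------------------------------------------------

# F_ML and analytic gradient wrt (b_edges, psi) in the given parameterisation.
# theta = c(b, log(psi)) when log_psi, else c(b, psi).
#
# With A = I - B and D = diag(psi), Sigma = A^-1 D A^-T is positive definite
# whenever A is invertible, and Sigma^-1 = A^T D^-1 A, so no Cholesky of
# Sigma is needed:
#   F     = sum(log psi) - 2 log|det A| + tr(D^-1 A S A^T) - log|S| - p
#   dF/dB = 2 (A^-T - D^-1 A S)
#   dF/dpsi_k = 1/psi_k - [A S A^T]_kk / psi_k^2
sem_objective <- function(theta, S, idx, p, log_psi = TRUE) {
  e <- length(idx)
  B <- matrix(0, p, p)
  B[idx] <- theta[seq_len(e)]
  psi <- if (log_psi) exp(theta[e + seq_len(p)]) else theta[e + seq_len(p)]
  if (any(!is.finite(psi)) || (!log_psi && any(psi <= 0))) {
    return(list(value = 1e10 + sum(theta^2), gradient = 2 * theta))
  }
  A <- -B
  dix <- seq.int(1L, p * p, by = p + 1L)
  A[dix] <- A[dix] + 1
  detA <- det(A)
  if (abs(detA) < 1e-12) {
    return(list(value = 1e10 + sum(theta^2), gradient = 2 * theta))
  }
  M <- A %*% S %*% t(A)
  dM <- M[dix]
  val <- sum(log(psi)) - 2 * log(abs(detA)) + sum(dM / psi) -
    attr(S, "logdetS") - p
  Ait <- t(solve(A))
  gB <- 2 * (Ait - (1 / psi) * (A %*% S))
  gpsi <- 1 / psi - dM / psi^2
  if (log_psi) gpsi <- gpsi * psi
  list(value = val, gradient = c(gB[idx], gpsi))
}

with_logdet <- function(S) {
  attr(S, "logdetS") <- 2 * sum(log(diag(chol(S))))
  S
}

# closed-form ML fit for recursive (acyclic) models: per-node regressions on S
sem_fit_recursive <- function(S, model) {
  p <- length(model$nodes)
  B <- matrix(0, p, p, dimnames = list(model$nodes, model$nodes))
  psi <- stats::setNames(diag(S), model$nodes)
  for (i in seq_len(p)) {
    pa <- match(model$edges[model$edges[, "to"] == model$nodes[i], "from"],
                model$nodes)
    if (length(pa)) {
      b <- solve(S[pa, pa, drop = FALSE], S[pa, i])
      B[i, pa] <- b
      psi[i] <- S[i, i] - sum(S[i, pa] * b)
    }
  }
  list(B = B, psi = unname(psi))
}

# optimiser core for non-recursive models: BFGS on (b, log psi) with a
# value/gradient cache (optim calls fn and gr separately), followed by a
# damped Newton polish to drive the gradient below tolerance. Additional
# random restarts are used only when the first start fails the tolerance.
sem_fit_cyclic <- function(S, Sl, idx, p, restarts, seed, grad_tol) {
  e <- length(idx)
  cache <- new.env(parent = emptyenv())
  obj <- function(theta) {
    key <- cache$theta
    if (!is.null(key) && identical(key, theta)) return(cache$res)
    res <- sem_objective(theta, Sl, idx, p, log_psi = TRUE)
    cache$theta <- theta
    cache$res <- res
    res
  }
  fn <- function(theta) obj(theta)$value
  gr <- function(theta) obj(theta)$gradient

  polish <- function(theta) {
    for (it in seq_len(8)) {
      o <- obj(theta)
      if (max(abs(o$gradient)) < grad_tol) break
      H <- numerical_hessian(gr, theta)
      step <- tryCatch(solve(H + diag(1e-8, length(theta)), o$gradient),
                       error = function(err) o$gradient)
      lam <- 1
      repeat {
        cand <- theta - lam * step
        if (fn(cand) <= o$value + 1e-12 || lam < 1e-6) break
        lam <- lam / 2
      }
      if (max(abs(cand - theta)) < 1e-15) break
      theta <- cand
    }
    theta
  }
  run_start <- function(st) {
    op <- tryCatch(
      stats::optim(st, fn, gr, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12)),
      error = function(err) NULL)
    if (is.null(op)) return(NULL)
    theta <- polish(op$par)
    list(theta = theta, value = fn(theta),
         gnorm = max(abs(gr(theta))))
  }

  start0 <- local({
    b0 <- numeric(e)
    for (k in seq_len(e)) {
      i <- ((idx[k] - 1) %% p) + 1
      j <- ((idx[k] - 1) %/% p) + 1
      b0[k] <- 0.5 * S[i, j] / S[j, j]
    }
    c(b0, log(pmax(diag(S) / 2, 1e-3)))
  })
  best <- run_start(start0)
  if ((is.null(best) || best$gnorm >= grad_tol) && restarts > 1) {
    extra <- with_seed(seed, {
      lapply(seq_len(restarts - 1), function(r) {
        c(stats::rnorm(e, sd = 0.3),
          log(pmax(diag(S) * stats::runif(p, 0.3, 1), 1e-3)))
      })
    })
    for (st in extra) {
      cand <- run_start(st)
      if (is.null(cand)) next
      if (is.null(best) || cand$value < best$value - 1e-12) best <- cand
      if (best$gnorm < grad_tol && best$value <= cand$value + 1e-10) break
    }
  }
  if (is.null(best)) {
    B <- matrix(0, p, p)
    psi <- diag(S)
  } else {
    B <- matrix(0, p, p)
    B[idx] <- best$theta[seq_len(e)]
    psi <- exp(best$theta[e + seq_len(p)])
  }
  list(B = B, psi = psi)
}

numerical_hessian <- function(grad_fn, theta, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (grad_fn(tp) - grad_fn(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a path model to a covariance matrix by maximum likelihood
#'
#' Minimises the ML discrepancy [ml_discrepancy()] over the free path
#' coefficients and residual variances. Recursive (acyclic) models are
#' solved in closed form by per-node regressions on `S` (the exact MLE for
#' a recursive system with uncorrelated errors); non-recursive models use a
#' seeded multi-start quasi-Newton optimiser on `(b, log psi)` with analytic
#' gradients and a Newton polish to the gradient tolerance. Non-convergence
#' is reported via the `converged` flag, never as an error.
#'
#' Standard errors come from the inverse observed information of the fit
#' function: `acov = (2/(n-1)) H^-1` with `H` the Hessian of `F_ML` at the
#' optimum (natural parameterisation), and `t = estimate / SE`.
#'
#' @param S Observed covariance matrix (symmetric positive definite).
#' @param n Number of samples behind `S`.
#' @param model A [path_model()].
#' @param restarts Number of random optimiser restarts for non-recursive
#'   models (default 10).
#' @param seed Integer seed for the restarts.
#' @param se Compute standard errors, t-values and the fit-index panel
#'   (default TRUE). Skipping them speeds up exhaustive searches.
#' @param grad_tol Gradient infinity-norm defining convergence
#'   (default 1e-8).
#' @return An object of class `sem_fit`: coefficient matrix `B`, residual
#'   variances `psi`, per-parameter `se` and `t` tables, `fml`, `chisq`,
#'   `df`, `n`, index panel `indices`, `converged`, `stability` (spectral
#'   radius of `B`), plus the `model` and `S`.
#' @export
fit_sem <- function(S, n, model, restarts = 10, seed = 1, se = TRUE,
                    grad_tol = 1e-8) {
  stopifnot(inherits(model, "path_model"))
  S <- as.matrix(S)
  if (!is_square_sym(S, 1e-8)) stop_("S must be symmetric")
  S <- (S + t(S)) / 2
  p <- length(model$nodes)
  if (nrow(S) != p) stop_("S order (%d) does not match model (%d nodes)",
                          nrow(S), p)
  if (!is.null(rownames(S)) && !identical(rownames(S), model$nodes)) {
    if (!setequal(rownames(S), model$nodes)) {
      stop_("S labels {%s} do not match model nodes {%s}",
            paste(rownames(S), collapse = ","),
            paste(model$nodes, collapse = ","))
    }
    S <- S[model$nodes, model$nodes]
  }
  if (n <= p + 1) stop_("n must exceed the number of nodes + 1")
  if (model$q > p * (p + 1) / 2) {
    stop_("model has more free parameters (q=%d) than covariance moments (%d)",
          model$q, p * (p + 1) / 2)
  }
  if (is.null(tryCatch(chol(S), error = function(e) NULL))) {
    stop_("S must be positive definite")
  }

  idx <- edge_index(model)
  e <- length(idx)
  Sl <- with_logdet(S)
  converged <- FALSE

  if (is_acyclic(model)) {
    cf <- sem_fit_recursive(S, model)
    B <- cf$B
    psi <- cf$psi
  } else {
    cf <- sem_fit_cyclic(S, Sl, idx, p, restarts = restarts, seed = seed,
                         grad_tol = grad_tol)
    B <- cf$B
    dimnames(B) <- list(model$nodes, model$nodes)
    psi <- cf$psi
  }

  psi <- pmax(psi, .Machine$double.eps)
  theta_nat <- c(B[idx], psi)
  obj_nat <- function(th) sem_objective(th, Sl, idx, p, log_psi = FALSE)
  g_nat <- obj_nat(theta_nat)$gradient
  fml <- max(obj_nat(theta_nat)$value, 0)
  converged <- max(abs(g_nat)) < max(grad_tol, 1e-8) * (1 + fml)

  se_edge <- rep(NA_real_, e)
  se_psi <- rep(NA_real_, p)
  acyclic <- is_acyclic(model)
  # recursive models are globally identified; non-recursive ones must pass
  # an information-rank check even when standard errors are not requested
  if (se || !acyclic) {
    H <- numerical_hessian(function(th) obj_nat(th)$gradient, theta_nat)
    hc <- tryCatch(chol(H), error = function(err) NULL)
    if (is.null(hc)) {
      converged <- FALSE
    } else if (!se) {
    } else {
      acov <- (2 / (n - 1)) * chol2inv(hc)
      sds <- sqrt(pmax(diag(acov), 0))
      se_edge <- sds[seq_len(e)]
      se_psi <- sds[e + seq_len(p)]
    }
  }

  est_edge <- B[idx]
  t_edge <- est_edge / se_edge
  labels <- if (e) edge_label(model$edges[, 1], model$edges[, 2]) else character(0)
  params <- data.frame(
    parameter = c(labels, paste0("psi_", model$nodes)),
    estimate = c(est_edge, psi),
    se = c(se_edge, se_psi),
    t = c(t_edge, psi / se_psi),
    stringsAsFactors = FALSE)

  fit <- structure(list(
    B = B, psi = stats::setNames(psi, model$nodes), params = params,
    fml = fml, chisq = (n - 1) * fml, df = model$df, n = n, q = model$q,
    converged = converged, stability = spectral_radius(B),
    gradient_norm = max(abs(g_nat)), model = model, S = S),
    class = "sem_fit")
  fit$indices <- fit_indices(fit, S)
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("sem_fit: %d nodes, %d paths; F_ML = %.5g, chi^2(%d) = %.4g, n = %d\n",
              length(x$model$nodes), nrow(x$model$edges), x$fml, x$df, x$chisq,
              x$n))
  cat(sprintf("  converged: %s; stability (spectral radius): %.3f\n",
              x$converged, x$stability))
  print(x$params, digits = 4)
  ix <- x$indices
  cat(sprintf("  AIC %.4g  RMSEA %s  SRMR %.4g  GFI %.4g  AGFI %s  PGFI %s  min|t| %s\n",
              ix$aic, format(ix$rmsea, digits = 3), ix$srmr, ix$gfi,
              format(ix$agfi, digits = 3), format(ix$pgfi, digits = 3),
              format(ix$min_t, digits = 3)))
  invisible(x)
}

#' Fit-index panel for a fitted path model
#'
#' Computes the classic covariance-structure fit panel: `chi^2 = (n-1) F_ML`;
#' `RMSEA = sqrt(max(chi^2 - df, 0) / (df (n-1)))`; `AIC = chi^2 + 2q` (the
#' model-AIC convention of the Lisrel family); `GFI = 1 -
#' tr[(Sigmahat^-1 S - I)^2] / tr[(Sigmahat^-1 S)^2]`;
#' `AGFI = 1 - [p(p+1)/(2 df)](1 - GFI)`; `PGFI = [2 df/(p(p+1))] GFI`;
#' SRMR as the root mean squared standardised residual over the unique
#' elements of `S - Sigmahat`; and `min_t`, the smallest |t| among free path
#' coefficients. When `df = 0`, RMSEA, AGFI and PGFI are reported as `NA`
#' (not applicable) rather than dividing by zero.
#'
#' @param fit A [fit_sem()] result.
#' @param S Observed covariance (defaults to the one stored in `fit`).
#' @return Named list of indices.
#' @export
fit_indices <- function(fit, S = fit$S) {
  stopifnot(inherits(fit, "sem_fit"))
  p <- nrow(S)
  df <- fit$df
  chisq <- fit$chisq
  Sigma <- model_implied_covariance(fit$B, fit$psi)
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (fit$n - 1))) else NA_real_
  aic <- chisq + 2 * fit$q
  M <- solve(Sigma, S)
  gfi <- 1 - sum((M - diag(p))^2) / sum(M^2)
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  pgfi <- if (df > 0) (2 * df / (p * (p + 1))) * gfi else NA_real_
  D <- (S - Sigma) / sqrt(outer(diag(S), diag(S)))
  srmr <- sqrt(mean(D[upper.tri(D, diag = TRUE)]^2))
  tvals <- fit$params$t[seq_len(nrow(fit$model$edges))]
  min_t <- if (length(tvals) && !anyNA(tvals)) min(abs(tvals)) else NA_real_
  list(min_t = min_t, rmsea = rmsea, aic = aic, srmr = srmr,
       gfi = gfi, agfi = agfi, pgfi = pgfi, chisq = chisq)
}

#' Extract condition samples from a BOLD time series
#'
#' Pools the scans belonging to one condition's blocks, compensating for the
#' haemodynamic delay by shifting each block window forward by `shift`
#' seconds and dropping the first `drop_head` and last `drop_tail` samples
#' of every shifted block (transition effects). The default shift of 6 s
#' with 2 + 1 trimmed samples matches the standard treatment of 15-s task
#' blocks.
#'
#' @param ts Scans x ROIs numeric matrix (column names are ROI labels).
#' @param paradigm A [paradigm()] describing `ts`.
#' @param condition Condition label to extract.
#' @param shift Forward shift of each block window, seconds (default 6).
#' @param drop_head,drop_tail Samples trimmed from each shifted block
#'   (defaults 2 and 1).
#' @return An object of class `condition_series`: `condition`, `samples`
#'   (pooled scans x ROIs), `n_samples`, and the sample covariance `S`
#'   (denominator n - 1).
#' @export
extract_condition_blocks <- function(ts, paradigm, condition, shift = 6,
                                     drop_head = 2, drop_tail = 1) {
  stopifnot(inherits(paradigm, "paradigm"), is.matrix(ts))
  if (nrow(ts) != paradigm$n_scans) {
    stop_("time series has %d rows but the paradigm declares %d scans",
          nrow(ts), paradigm$n_scans)
  }
  if (shift < 0) stop_("shift must be >= 0")
  segs <- paradigm$segments[paradigm$segments$category == condition, ,
                            drop = FALSE]
  if (nrow(segs) == 0L) stop_("condition '%s' not present in paradigm",
                              condition)
  t <- scan_times(paradigm)
  rows <- integer(0)
  for (i in seq_len(nrow(segs))) {
    a <- segs$onset[i] + shift
    b <- segs$onset[i] + segs$duration[i] + shift
    w <- which(t >= a - 1e-9 & t < b - 1e-9 & t <= t[length(t)])
    if (drop_head > 0) w <- w[-seq_len(min(drop_head, length(w)))]
    if (drop_tail > 0 && length(w) > 0) {
      w <- w[seq_len(max(length(w) - drop_tail, 0))]
    }
    if (length(w) < 1L) {
      stop_("block at onset %.1f s yields no samples after shifting/trimming",
            segs$onset[i])
    }
    rows <- c(rows, w)
  }
  samples <- ts[rows, , drop = FALSE]
  structure(list(condition = condition, samples = samples,
                 n_samples = nrow(samples), S = stats::cov(samples)),
            class = "condition_series")
}

#' @export
print.condition_series <- function(x, ...) {
  cat(sprintf("condition_series '%s': %d samples x %d ROIs\n",
              x$condition, x$n_samples, ncol(x$samples)))
  invisible(x)
}
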