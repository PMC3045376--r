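#' Enumerate every candidate path model over a node set
#'
#' Generates all subsets of the `p(p-1)` possible directed edges (no
#' self-loops), optionally capped at `max_edges` edges and filtered to
#' models with non-negative degrees of freedom. The order is deterministic:
#' edge-count ascending, then lexicographic in the canonical edge order
#' (source-major over the given node order).
#'
#' @param nodes Character node labels (>= 2).
#' @param max_edges Maximum edges per model (default: no cap beyond the df
#'   rule).
#' @param require_df_nonneg Keep only models with `df >= 0` (default TRUE);
#'   with 4 nodes this caps models at 6 edges and yields 2510 candidates.
#' @return List of [path_model()] objects.
#' @export
enumerate_models <- function(nodes, max_edges = NULL,
                             require_df_nonneg = TRUE) {
  stopifnot(is.character(nodes), length(nodes) >= 2)
  p <- length(nodes)
  all_edges <- expand.grid(to = nodes, from = nodes,
                           stringsAsFactors = FALSE)[, c("from", "to")]
  all_edges <- all_edges[all_edges$from != all_edges$to, ]
  # canonical lexicographic order: by source then target, in node order
  ord <- order(match(all_edges$from, nodes), match(all_edges$to, nodes))
  all_edges <- as.matrix(all_edges[ord, ])
  m <- nrow(all_edges)
  cap <- m
  if (require_df_nonneg) cap <- min(cap, p * (p + 1) / 2 - p)
  if (!is.null(max_edges)) cap <- min(cap, max_edges)
  models <- list(path_model(nodes))
  for (k in seq_len(cap)) {
    sets <- utils::combn(m, k, simplify = FALSE)
    models <- c(models, lapply(sets, function(s) {
      path_model(nodes, all_edges[s, , drop = FALSE])
    }))
  }
  models
}

# lightweight single-model fit used inside the exhaustive search: same
# estimator as fit_sem (closed-form regressions for recursive models,
# seeded multi-start quasi-Newton for non-recursive ones) without the
# standard-error machinery, returning only the ranking quantities.
search_fit_one <- function(S, Sl, n, model, restarts, seed, grad_tol = 1e-8) {
  p <- length(model$nodes)
  idx <- edge_index(model)
  if (is_acyclic(model)) {
    cf <- sem_fit_recursive(S, model)
    acyclic <- TRUE
  } else {
    cf <- sem_fit_cyclic(S, Sl, idx, p, restarts = restarts, seed = seed,
                         grad_tol = grad_tol)
    acyclic <- FALSE
  }
  psi <- pmax(cf$psi, .Machine$double.eps)
  theta <- c(cf$B[idx], psi)
  o <- sem_objective(theta, Sl, idx, p, log_psi = FALSE)
  fml <- max(o$value, 0)
  converged <- max(abs(o$gradient)) < max(grad_tol, 1e-8) * (1 + fml)
  if (!acyclic && converged) {
    H <- numerical_hessian(function(th)
      sem_objective(th, Sl, idx, p, log_psi = FALSE)$gradient, theta)
    if (is.null(tryCatch(chol(H), error = function(e) NULL))) {
      converged <- FALSE
    }
  }
  chisq <- (n - 1) * fml
  df <- model$df
  Ai <- solve(diag(p) - cf$B)
  Sigma <- Ai %*% (psi * t(Ai))
  D <- (S - Sigma) / sqrt(outer(diag(S), diag(S)))
  list(fml = fml, chisq = chisq, aic = chisq + 2 * model$q,
       rmsea = if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1)))
               else NA_real_,
       srmr = sqrt(mean(D[upper.tri(D, diag = TRUE)]^2)),
       stability = spectral_radius(cf$B), converged = converged)
}

#' Exhaustive exploratory SEM search over all candidate models
#'
#' Fits every model from [enumerate_models()] to the observed covariance and
#' ranks the converged fits by a goodness-of-fit criterion (default AIC
#' ascending; ties are broken by RMSEA, then fewer edges, then enumeration
#' order, with index values compared at 1e-6 resolution so that
#' saturated-equivalent models order deterministically). Non-converged fits
#' are excluded from the ranking and recorded with their diagnostics.
#'
#' @param S Observed covariance matrix.
#' @param n Sample size behind `S`.
#' @param nodes Node labels (default: row names of `S`).
#' @param max_edges,require_df_nonneg Passed to [enumerate_models()].
#' @param rank_by Ranking criterion: one of `"aic"`, `"rmsea"`, `"chisq"`,
#'   `"srmr"`, `"fml"`.
#' @param restarts Optimiser restarts per non-recursive model (default 2;
#'   the damped-regression start converges for almost every candidate, and
#'   the best model is refit at full restarts).
#' @param seed Integer seed (restart draws), making ranked lists
#'   reproducible.
#' @return An object of class `sem_search`: `table` (one row per fitted
#'   model with edges, q, df, chi^2, AIC, RMSEA, SRMR, convergence and
#'   stability), `best` (full [fit_sem()] refit of the top-ranked model with
#'   standard errors), `models`, and `failed` diagnostics.
#' @export
exploratory_search <- function(S, n, nodes = rownames(S), max_edges = NULL,
                               require_df_nonneg = TRUE, rank_by = "aic",
                               restarts = 2, seed = 1) {
  rank_by <- match.arg(rank_by, c("aic", "rmsea", "chisq", "srmr", "fml"))
  if (is.null(nodes)) stop_("nodes must be given when S has no row names")
  S <- as.matrix(S)
  if (!is.null(rownames(S))) S <- S[nodes, nodes]
  S <- (S + t(S)) / 2
  if (n <= length(nodes) + 1) stop_("n must exceed the number of nodes + 1")
  if (is.null(tryCatch(chol(S), error = function(e) NULL))) {
    stop_("S must be positive definite")
  }
  Sl <- with_logdet(S)
  p <- length(nodes)
  models <- enumerate_models(nodes, max_edges, require_df_nonneg)
  nm <- length(models)
  col_edges <- character(nm); col_ne <- integer(nm); col_q <- integer(nm)
  col_df <- integer(nm); col_conv <- logical(nm)
  col_fml <- col_chisq <- col_aic <- col_rmsea <- col_srmr <-
    col_stab <- rep(NA_real_, nm)
  col_reason <- character(nm)
  for (k in seq_len(nm)) {
    mod <- models[[k]]
    col_edges[k] <- paste(edge_label(mod$edges[, 1], mod$edges[, 2]),
                          collapse = ";")
    col_ne[k] <- nrow(mod$edges); col_q[k] <- mod$q; col_df[k] <- mod$df
    res <- tryCatch(
      search_fit_one(S, Sl, n, mod, restarts = restarts,
                     seed = derive_seed(seed, sprintf("model-%06d", k))),
      error = function(e) e)
    if (inherits(res, "error")) {
      col_reason[k] <- conditionMessage(res)
      next
    }
    col_conv[k] <- res$converged
    col_fml[k] <- res$fml; col_chisq[k] <- res$chisq; col_aic[k] <- res$aic
    col_rmsea[k] <- res$rmsea; col_srmr[k] <- res$srmr
    col_stab[k] <- res$stability
    if (!res$converged) col_reason[k] <- "gradient/information tolerance unmet"
  }
  tab <- data.frame(model_id = seq_len(nm), edges = col_edges,
                    n_edges = col_ne, q = col_q, df = col_df,
                    converged = col_conv, fml = col_fml, chisq = col_chisq,
                    aic = col_aic, rmsea = col_rmsea, srmr = col_srmr,
                    stability = col_stab, reason = col_reason,
                    stringsAsFactors = FALSE)
  ok <- tab[tab$converged, , drop = FALSE]
  failed <- tab[!tab$converged, , drop = FALSE]
  if (nrow(ok) == 0L) {
    err <- structure(
      class = c("sem_search_error", "error", "condition"),
      list(message = "no candidate model converged", call = NULL,
           diagnostics = failed))
    stop(err)
  }
  crit <- switch(rank_by, aic = ok$aic, rmsea = ok$rmsea, chisq = ok$chisq,
                 srmr = ok$srmr, fml = ok$fml)
  crit[is.na(crit)] <- Inf
  rmsea_key <- ifelse(is.na(ok$rmsea), Inf, ok$rmsea)
  o <- order(round(crit, 6), round(rmsea_key, 6), ok$n_edges, ok$model_id)
  ok <- ok[o, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  best_id <- ok$model_id[1L]
  best <- fit_sem(S, n, models[[best_id]], restarts = max(restarts, 10),
                  seed = derive_seed(seed, "best-refit"), se = TRUE)
  structure(list(table = ok, failed = failed, best = best,
                 best_model = models[[best_id]], models = models,
                 rank_by = rank_by, n = n),
            class = "sem_search")
}

#' @export
print.sem_search <- function(x, ...) {
  cat(sprintf("sem_search: %d candidate models, %d converged, ranked by %s\n",
              length(x$models), nrow(x$table), x$rank_by))
  print(utils::head(x$table[, c("rank", "edges", "n_edges", "df", "chisq",
                                "aic", "rmsea")], 5), row.names = FALSE)
  cat("best model:\n")
  print(x$best_model)
  invisible(x)
}
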