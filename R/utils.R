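`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded helpers never perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic 32-bit-safe hash of (seed, stage label) so each pipeline
#' stage gets an independent but reproducible RNG stream.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed in [0, 2^31 - 19).
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

spectral_radius <- function(B) {
  if (all(B == 0)) return(0)
  max(Mod(eigen(B, only.values = TRUE)$values))
}

is_square_sym <- function(S, tol = 1e-10) {
  is.matrix(S) && nrow(S) == ncol(S) && max(abs(S - t(S))) <= tol
}

# smallest-singular-value check that I - B is usable as a structural matrix
check_invertible <- function(B, tol = 1e-8) {
  A <- diag(nrow(B)) - B
  min(svd(A, nu = 0, nv = 0)$d) > tol
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

edge_label <- function(from, to) paste0(from, "->", to)

# causal discrete convolution, truncated to length(x)
convolve_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, rep(0, length(kernel))), rev(kernel), type = "open")
  out[seq_len(n)]
}
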