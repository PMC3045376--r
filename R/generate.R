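#' Default ROI labels of the moral-cognition network
#'
#' Frontal pole (FP), left posterior superior temporal sulcus (pSTS),
#' posterior cingulate cortex/precuneus (PCC) and rostral anterior cingulate
#' cortex (rACC).
#'
#' @return Character vector of the four node labels.
#' @export
moral_network_nodes <- function() c("FP", "pSTS", "PCC", "rACC")

#' Reference condition networks of the moral-sensitivity study
#'
#' Path-coefficient matrices of the best-fitting four-node effective
#' connectivity models for the neutral, care and justice conditions of the
#' moral-sensitivity task. Matrices are oriented `B[target, source]`, i.e.
#' `B["pSTS", "FP"]` is the FP -> pSTS path. The neutral network has 6 paths,
#' the care and justice networks 7 paths each. Note that a 7-path model on
#' 4 nodes has q = 11 free parameters against only 10 covariance moments and
#' is therefore under-identified; these matrices are intended as descriptive
#' references and (after stabilisation) as generating truth for simulation,
#' not as directly fittable topologies.
#'
#' @return Named list with one element per condition, each a list with the
#'   coefficient matrix `B` and the corresponding [path_model()] `model`.
#' @seealso [stabilize_paths()], [default_generating_model()]
#' @export
condition_models <- function() {
  nodes <- moral_network_nodes()
  mk <- function(entries) {
    B <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
    for (e in entries) B[e[[2L]], e[[1L]]] <- e[[3L]]
    list(B = B, model = path_model(nodes, b_edges(B)))
  }
  list(
    neutral = mk(list(
      list("pSTS", "FP", -0.062), list("rACC", "FP", 1.04),
      list("FP", "pSTS", 0.913),
      list("FP", "PCC", 0.205), list("pSTS", "PCC", 0.943),
      list("pSTS", "rACC", 1.11))),
    care = mk(list(
      list("pSTS", "FP", 1.09),
      list("FP", "pSTS", 0.918),
      list("FP", "PCC", 0.185), list("pSTS", "PCC", 0.965),
      list("FP", "rACC", 0.885), list("pSTS", "rACC", -0.205),
      list("PCC", "rACC", 0.299))),
    justice = mk(list(
      list("pSTS", "FP", 1.08),
      list("FP", "pSTS", 3.72), list("PCC", "pSTS", 1.36),
      list("rACC", "pSTS", -4.18),
      list("pSTS", "PCC", 0.945), list("rACC", "PCC", 0.201),
      list("pSTS", "rACC", 1.1))))
}

# edges (from, to) implied by the nonzero entries of B[target, source]
b_edges <- function(B) {
  idx <- which(B != 0, arr.ind = TRUE)
  cbind(from = colnames(B)[idx[, "col"]], to = rownames(B)[idx[, "row"]])
}

#' Stabilise a path-coefficient matrix
#'
#' Reference coefficient matrices estimated with reciprocal (feedback) paths
#' can imply loop gains at or above 1, making `I - B` singular or the implied
#' system non-stationary. This helper first shrinks both members of every
#' reciprocal pair by `reciprocal_shrink`, then, if the spectral radius of
#' `B` still exceeds `target_radius`, rescales the whole matrix so the
#' spectral radius equals `target_radius`. Zero entries (absent paths) are
#' never touched, so the topology is preserved.
#'
#' @param B Square path-coefficient matrix, `B[target, source]`.
#' @param reciprocal_shrink Multiplier applied to reciprocal pairs
#'   (default 0.7).
#' @param target_radius Maximum admissible spectral radius (default 0.85).
#' @return The stabilised matrix.
#' @export
stabilize_paths <- function(B, reciprocal_shrink = 0.7, target_radius = 0.85) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  p <- nrow(B)
  out <- B
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (out[i, j] != 0 && out[j, i] != 0) {
        out[i, j] <- out[i, j] * reciprocal_shrink
        out[j, i] <- out[j, i] * reciprocal_shrink
      }
    }
  }
  rho <- spectral_radius(out)
  if (rho > target_radius) out <- out * (target_radius / rho)
  out
}

#' Construct a generating model for synthetic cohorts
#'
#' The generating model is a linear structural system per condition:
#' innovations `e ~ N(0, diag(Psi_c))` drive the neural signal
#' `x = (I - B_c)^-1 e`, which is convolved with the canonical HRF and
#' observed with additive measurement noise. Subjects differ by Gaussian
#' jitter on the nonzero path coefficients; a behaviour score is a linear
#' function of selected subject-level path strengths plus noise.
#'
#' @param nodes Character ROI labels.
#' @param B_by_condition Named list of square coefficient matrices
#'   (`B[target, source]`), one per condition, zero diagonal.
#' @param Psi_by_condition Named list of residual-variance vectors (default:
#'   unit variances for every condition).
#' @param noise_sd Standard deviation of BOLD measurement noise (default 0.5).
#' @param subject_sd Between-subject SD of path-coefficient jitter
#'   (default 0.25).
#' @param behavior_link List of links, each
#'   `list(condition=, from=, to=, slope=)`, mapping a subject's path
#'   strength to the behaviour score.
#' @param score_base,score_sd Mean and residual SD of the behaviour score
#'   (defaults 350 and 20, an mMJI-like scale).
#' @return An object of class `generating_model`.
#' @export
generating_model <- function(nodes, B_by_condition, Psi_by_condition = NULL,
                             noise_sd = 0.5, subject_sd = 0.25,
                             behavior_link = list(),
                             score_base = 350, score_sd = 20) {
  stopifnot(is.character(nodes), length(nodes) >= 2,
            is.list(B_by_condition), length(B_by_condition) >= 1)
  if (is.null(names(B_by_condition))) stop_("B_by_condition must be named")
  p <- length(nodes)
  if (is.null(Psi_by_condition)) {
    Psi_by_condition <- lapply(B_by_condition, function(B) rep(1, p))
  }
  for (cond in names(B_by_condition)) {
    B <- B_by_condition[[cond]]
    if (!is.matrix(B) || any(dim(B) != p)) {
      stop_("B for condition '%s' must be %d x %d", cond, p, p)
    }
    if (any(diag(B) != 0)) stop_("B diagonal must be zero (no self-loops)")
    if (!check_invertible(B)) {
      stop_("I - B is numerically singular for condition '%s'", cond)
    }
    dimnames(B_by_condition[[cond]]) <- list(nodes, nodes)
    psi <- Psi_by_condition[[cond]]
    if (length(psi) != p || any(psi <= 0)) {
      stop_("Psi for condition '%s' must be %d positive variances", cond, p)
    }
  }
  for (link in behavior_link) {
    stopifnot(all(c("condition", "from", "to", "slope") %in% names(link)))
    if (!link$condition %in% names(B_by_condition)) {
      stop_("behavior_link condition '%s' unknown", link$condition)
    }
  }
  structure(list(nodes = nodes, B_by_condition = B_by_condition,
                 Psi_by_condition = Psi_by_condition, noise_sd = noise_sd,
                 subject_sd = subject_sd, behavior_link = behavior_link,
                 score_base = score_base, score_sd = score_sd),
            class = "generating_model")
}

#' @export
print.generating_model <- function(x, ...) {
  cat(sprintf("generating_model: %d nodes (%s), conditions: %s\n",
              length(x$nodes), paste(x$nodes, collapse = ", "),
              paste(names(x$B_by_condition), collapse = ", ")))
  cat(sprintf("  noise_sd %g, subject_sd %g, score %g +/- %g, %d behavior link(s)\n",
              x$noise_sd, x$subject_sd, x$score_base, x$score_sd,
              length(x$behavior_link)))
  invisible(x)
}

#' Default generating model for the moral-sensitivity cohort
#'
#' Uses the stabilised reference networks of [condition_models()] as
#' generating truth for the neutral, care and justice conditions, with unit
#' innovation variances. The behaviour score is linked to the subject-level
#' justice pSTS -> PCC path with a slope chosen so that, at the default
#' between-subject jitter and score noise, the path accounts for 60% of the
#' score variance (`slope = sqrt(0.6/0.4) * score_sd / subject_sd`).
#'
#' @param stabilize Stabilise reference coefficients via [stabilize_paths()]
#'   (default TRUE; the raw care and justice matrices imply loop gains >= 1
#'   and are not usable as generating truth).
#' @param noise_sd,subject_sd,score_sd See [generating_model()].
#' @return A `generating_model`.
#' @export
default_generating_model <- function(stabilize = TRUE, noise_sd = 0.5,
                                     subject_sd = 0.25, score_sd = 20) {
  ref <- condition_models()
  Bs <- lapply(ref, function(m) if (stabilize) stabilize_paths(m$B) else m$B)
  # non-moral control conditions: no structured network, baseline dynamics
  zero <- matrix(0, 4, 4, dimnames = dimnames(Bs$neutral))
  Bs$strategic <- zero
  Bs$tactical <- zero
  slope <- sqrt(0.6 / 0.4) * score_sd / subject_sd
  generating_model(
    nodes = moral_network_nodes(), B_by_condition = Bs,
    noise_sd = noise_sd, subject_sd = subject_sd,
    behavior_link = list(list(condition = "justice", from = "pSTS",
                              to = "PCC", slope = slope)),
    score_sd = score_sd)
}

#' Identified justice-network variant for recovery simulations
#'
#' The full 7-path justice network is under-identified on a 4-node
#' covariance (11 free parameters versus 10 moments), and its purely
#' reciprocal feedback loops are locally non-identified even at df >= 0
#' (no exogenous instruments: distinct coefficient sets imply the same
#' covariance). Neither property can be "fixed" by a fitter; a generating
#' truth for recovery studies must itself be identified. This variant keeps
#' the maximal recursive (acyclic) subnetwork of the justice model -- the
#' convergent inputs FP -> pSTS, rACC -> pSTS and the PCC inputs
#' pSTS -> PCC, rACC -> PCC (4 paths, df = 2) -- whose Markov-equivalence
#' class is a singleton, so the topology is recoverable in principle from
#' its covariance.
#'
#' @return List with the coefficient matrix `B` and the [path_model()]
#'   `model`.
#' @export
justice_recovery_model <- function() {
  B <- condition_models()$justice$B
  B["FP", "pSTS"] <- 0   # drop feedback paths: pSTS->FP,
  B["rACC", "pSTS"] <- 0 # pSTS->rACC,
  B["pSTS", "PCC"] <- 0  # PCC->pSTS
  B <- stabilize_paths(B)
  list(B = B, model = path_model(moral_network_nodes(), b_edges(B)))
}

# jitter nonzero coefficients, redrawing if the perturbed system is unstable
jitter_B <- function(B, sd, max_radius = 0.95, max_tries = 100L) {
  if (sd == 0) return(B)
  idx <- which(B != 0)
  if (length(idx) == 0L) return(B)
  for (k in seq_len(max_tries)) {
    Bj <- B
    Bj[idx] <- B[idx] + stats::rnorm(length(idx), sd = sd)
    if (spectral_radius(Bj) < max_radius && check_invertible(Bj)) return(Bj)
  }
  stop_("could not draw a stable subject coefficient matrix in %d tries",
        max_tries)
}

#' Simulate one subject's ROI BOLD acquisition
#'
#' For each scan, innovations are drawn from the active condition's
#' structural system (scans outside any segment use the neutral innovation
#' variances with all paths off), solved to the neural signal
#' `x = (I - B)^-1 e`, convolved per node with the canonical HRF sampled at
#' `tr`, and observed with additive Gaussian measurement noise. The
#' behaviour score is `score_base + sum(slope * subject path value) + noise`.
#'
#' @param model A [generating_model()].
#' @param paradigm A [paradigm()]; its categories must be a subset of the
#'   model's conditions (plus implicit baseline).
#' @param seed Integer seed; identical seeds give bit-identical records.
#' @param subject_id Subject identifier string.
#' @param hrf Optional HRF kernel sampled at the paradigm `tr`.
#' @return An object of class `subject_record`: `subject_id`, `timeseries`
#'   (scans x ROIs BOLD matrix), `neural` (pre-convolution signal), `score`,
#'   `true_paths` (per-condition subject coefficient matrices), `paradigm`.
#' @export
simulate_subject <- function(model, paradigm, seed = 1,
                             subject_id = "sub-01", hrf = NULL) {
  stopifnot(inherits(model, "generating_model"), inherits(paradigm, "paradigm"))
  conds <- unique(paradigm$segments$category)
  unknown <- setdiff(conds, names(model$B_by_condition))
  if (length(unknown)) {
    stop_("paradigm categories not in model: %s",
          paste(unknown, collapse = ", "))
  }
  p <- length(model$nodes)
  hrf <- hrf %||% canonical_hrf(paradigm$tr)
  base_psi <- model$Psi_by_condition[["neutral"]] %||% rep(1, p)

  with_seed(seed, {
    Bsub <- lapply(model$B_by_condition, jitter_B, sd = model$subject_sd)
    scan_cond <- condition_at_scans(paradigm)
    n <- paradigm$n_scans
    x <- matrix(0, n, p, dimnames = list(NULL, model$nodes))
    # innovations scan-by-scan are iid within condition: draw per run block
    runs <- rle(scan_cond)
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      cond <- runs$values[k]
      rows <- seq.int(pos, length.out = len)
      if (cond == "baseline") {
        e <- matrix(stats::rnorm(len * p), len, p) *
          rep(sqrt(base_psi), each = len)
        x[rows, ] <- e
      } else {
        psi <- model$Psi_by_condition[[cond]]
        e <- matrix(stats::rnorm(len * p), len, p) *
          rep(sqrt(psi), each = len)
        A <- diag(p) - Bsub[[cond]]
        x[rows, ] <- t(solve(A, t(e)))
      }
      pos <- pos + len
    }
    y <- apply(x, 2L, convolve_causal, kernel = hrf)
    if (model$noise_sd > 0) {
      y <- y + matrix(stats::rnorm(n * p, sd = model$noise_sd), n, p)
    }
    colnames(y) <- model$nodes
    score <- model$score_base
    for (link in model$behavior_link) {
      score <- score + link$slope * Bsub[[link$condition]][link$to, link$from]
    }
    if (model$score_sd > 0) score <- score + stats::rnorm(1, sd = model$score_sd)
    structure(list(subject_id = subject_id, timeseries = y, neural = x,
                   score = score, true_paths = Bsub, paradigm = paradigm),
              class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("subject_record %s: %d scans x %d ROIs, score %.1f\n",
              x$subject_id, nrow(x$timeseries), ncol(x$timeseries), x$score))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Subjects are independent draws from [simulate_subject()], each with its
#' own per-subject coefficient jitter; sub-seeds are derived deterministically
#' from `seed`.
#'
#' @param model A [generating_model()].
#' @param paradigm A [paradigm()].
#' @param n_subjects Number of subjects (default 17, the implied sample of
#'   the study design).
#' @param seed Master integer seed.
#' @return List of `subject_record` objects.
#' @export
simulate_cohort <- function(model, paradigm, n_subjects = 17, seed = 1) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(model, paradigm,
                     seed = derive_seed(seed, sprintf("subject-%04d", i)),
                     subject_id = sprintf("sub-%02d", i))
  })
}
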