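#' Build and validate a pipeline run configuration
#'
#' A run is a pure function of its configuration and master seed: every
#' stage derives its own sub-seed deterministically, so two runs with the
#' same configuration produce byte-identical reports.
#'
#' @param design_counts Segment counts per category (default: the standard
#'   41-segment design).
#' @param segment_duration,tr Paradigm timing in seconds.
#' @param n_subjects Cohort size (default 17).
#' @param seed Master integer seed.
#' @param model A [generating_model()] (default
#'   [default_generating_model()]).
#' @param conditions Task conditions analysed against the control condition
#'   (default care and justice).
#' @param control Control condition label (default "neutral").
#' @param rank_by,max_edges,require_df_nonneg,restarts SEM search settings
#'   (see [exploratory_search()]).
#' @param shift,drop_head,drop_tail Block extraction settings (see
#'   [extract_condition_blocks()]).
#' @param p_in,p_out Stepwise thresholds.
#' @param alpha Family-wise level for pathwise comparisons.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(design_counts = c(care = 6, justice = 6, neutral = 17,
                                         strategic = 6, tactical = 6),
                       segment_duration = 15, tr = 2, n_subjects = 17,
                       seed = 1, model = NULL,
                       conditions = c("care", "justice"), control = "neutral",
                       rank_by = "aic", max_edges = NULL,
                       require_df_nonneg = TRUE, restarts = 2,
                       shift = 6, drop_head = 2, drop_tail = 1,
                       p_in = 0.05, p_out = 0.10, alpha = 0.05) {
  rank_by <- tryCatch(
    match.arg(rank_by, c("aic", "rmsea", "chisq", "srmr", "fml")),
    error = function(e) stop_("unknown rank criterion '%s'", rank_by))
  model <- model %||% default_generating_model()
  stopifnot(inherits(model, "generating_model"))
  bad <- setdiff(c(conditions, control), names(model$B_by_condition))
  if (length(bad)) stop_("condition(s) missing from model: %s",
                         paste(bad, collapse = ", "))
  if (p_in <= 0 || p_in >= 1 || p_out <= 0 || p_out >= 1 || p_in > p_out) {
    stop_("need 0 < p_in <= p_out < 1")
  }
  structure(list(design_counts = design_counts,
                 segment_duration = segment_duration, tr = tr,
                 n_subjects = n_subjects, seed = seed, model = model,
                 conditions = conditions, control = control,
                 rank_by = rank_by, max_edges = max_edges,
                 require_df_nonneg = require_df_nonneg, restarts = restarts,
                 shift = shift, drop_head = drop_head, drop_tail = drop_tail,
                 p_in = p_in, p_out = p_out, alpha = alpha),
            class = "run_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[roisem] ", fmt), ...))
}

run_stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  stage_log(verbose, "stage %-12s done (%.1f s)", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Run the full effective-connectivity pipeline
#'
#' Composes every analysis stage on a simulated cohort: paradigm and cohort
#' generation, ROI GLM contrasts with brain-behaviour correlation and
#' median-split comparison, seed-target PPI with group paired tests,
#' condition-block extraction, exploratory SEM search per condition,
#' cross-condition pathwise comparisons, per-subject confirmatory fits of
#' the group model for the last task condition, and stepwise regression of
#' those path coefficients onto the behaviour scores. All reports are
#' written under `out_dir` together with a deterministic manifest (config
#' hash, seeds, file checksums).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress and timings (default TRUE).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$model
  nodes <- model$nodes

  par_ <- run_stage("paradigm", verbose, {
    make_paradigm(config$design_counts, config$segment_duration, config$tr,
                  seed = derive_seed(config$seed, "paradigm"))
  })
  write_events(par_, file.path(out_dir, "events.tsv"))

  cohort <- run_stage("simulate", verbose, {
    simulate_cohort(model, par_, config$n_subjects,
                    seed = derive_seed(config$seed, "cohort"))
  })
  ts_files <- vapply(cohort, function(s) {
    f <- file.path(out_dir, sprintf("%s_timeseries.tsv", s$subject_id))
    write_timeseries(s$timeseries, f)
    basename(f)
  }, "")
  write_cohort_manifest(cohort, file.path(out_dir, "cohort.json"),
                        files = ts_files, seed = config$seed)
  scores <- vapply(cohort, `[[`, 0, "score")

  hrf <- canonical_hrf(config$tr)
  design <- build_design_matrix(par_, hrf)
  contrasts <- stats::setNames(
    lapply(config$conditions, function(cond) {
      stats::setNames(c(1, -1), c(cond, config$control))
    }),
    paste0(config$conditions, "_gt_", config$control))

  glm_res <- run_stage("glm", verbose, {
    rows <- list()
    for (s in cohort) {
      for (roi in nodes) {
        fit <- fit_glm(s$timeseries[, roi], design, contrasts)
        rows[[length(rows) + 1L]] <-
          cbind(subject_id = s$subject_id, roi = roi, fit$contrasts)
      }
    }
    do.call(rbind, rows)
  })
  write_tsv(glm_res, file.path(out_dir, "glm_contrasts.tsv"))

  # brain-behaviour coupling for the last task condition's contrast in each ROI
  behav_contrast <- utils::tail(names(contrasts), 1)
  corr_res <- run_stage("behaviour", verbose, {
    out <- lapply(nodes, function(roi) {
      v <- glm_res$estimate[glm_res$roi == roi &
                              glm_res$contrast == behav_contrast]
      cc <- group_contrast_correlation(v, scores)
      ms <- median_split_compare(scores, v)
      list(roi = roi, correlation = cc, median_split = ms)
    })
    stats::setNames(out, nodes)
  })
  jsonlite::write_json(
    lapply(corr_res, function(x) list(roi = x$roi, r = x$correlation$r,
                                      r_squared = x$correlation$r_squared,
                                      p = x$correlation$p,
                                      split_t = x$median_split$t,
                                      split_p = x$median_split$p)),
    file.path(out_dir, "behaviour.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  ppi_res <- run_stage("ppi", verbose, {
    drift <- design$matrix[, grep("^drift_", colnames(design$matrix)),
                           drop = FALSE]
    rows <- list()
    betas <- list()
    for (cond in config$conditions) {
      for (seed_roi in nodes) {
        for (target_roi in setdiff(nodes, seed_roi)) {
          b <- vapply(cohort, function(s) {
            regs <- build_ppi_regressors(s$timeseries[, seed_roi], par_,
                                         c(cond, config$control), hrf = hrf)
            r <- fit_ppi(s$timeseries[, target_roi], regs, confounds = drift)
            r$beta
          }, 0)
          betas[[paste(cond, seed_roi, target_roi, sep = "|")]] <- b
          tt <- stats::t.test(b)
          rows[[length(rows) + 1L]] <- data.frame(
            seed = seed_roi, target = target_roi,
            contrast = paste0(cond, "_gt_", config$control),
            beta = mean(b), t = unname(tt$statistic),
            df = unname(tt$parameter), p = tt$p.value,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(table = do.call(rbind, rows), betas = betas)
  })
  write_tsv(ppi_res$table, file.path(out_dir, "ppi_results.tsv"))

  all_conditions <- unique(c(config$control, config$conditions))
  blocks <- run_stage("blocks", verbose, {
    out <- lapply(all_conditions, function(cond) {
      per_subject <- lapply(cohort, function(s) {
        extract_condition_blocks(s$timeseries, par_, cond, config$shift,
                                 config$drop_head, config$drop_tail)
      })
      pooled <- do.call(rbind, lapply(per_subject, `[[`, "samples"))
      list(per_subject = per_subject, pooled_S = stats::cov(pooled),
           pooled_n = nrow(pooled))
    })
    stats::setNames(out, all_conditions)
  })

  searches <- run_stage("semsearch", verbose, {
    out <- lapply(all_conditions, function(cond) {
      exploratory_search(blocks[[cond]]$pooled_S, blocks[[cond]]$pooled_n,
                         nodes = nodes, max_edges = config$max_edges,
                         require_df_nonneg = config$require_df_nonneg,
                         rank_by = config$rank_by, restarts = config$restarts,
                         seed = derive_seed(config$seed, paste0("search-", cond)))
    })
    stats::setNames(out, all_conditions)
  })
  for (cond in all_conditions) {
    write_tsv(searches[[cond]]$table[, setdiff(colnames(searches[[cond]]$table),
                                               "reason")],
              file.path(out_dir, sprintf("search_%s.tsv", cond)))
    write_sem_fit(searches[[cond]]$best,
                  file.path(out_dir, sprintf("best_model_%s.json", cond)))
  }

  comparisons <- run_stage("compare", verbose, {
    if (length(config$conditions) < 2) return(NULL)
    ca <- config$conditions[1]
    cb <- config$conditions[2]
    fits_a <- confirmatory_fit_cohort(blocks[[ca]]$per_subject,
                                      searches[[ca]]$best_model,
                                      restarts = config$restarts,
                                      seed = derive_seed(config$seed, "confirm-a"))
    fits_b <- confirmatory_fit_cohort(blocks[[cb]]$per_subject,
                                      searches[[cb]]$best_model,
                                      restarts = config$restarts,
                                      seed = derive_seed(config$seed, "confirm-b"))
    shared <- count_shared_paths(list(searches[[ca]]$best_model,
                                      searches[[cb]]$best_model))
    cmp <- compare_paths(fits_a$coefficients, fits_b$coefficients,
                         alpha = config$alpha)
    list(shared = shared, table = cmp)
  })
  if (!is.null(comparisons)) {
    write_tsv(comparisons$table, file.path(out_dir, "path_comparisons.tsv"))
  }

  stepwise <- run_stage("stepwise", verbose, {
    cond <- utils::tail(config$conditions, 1)
    conf <- confirmatory_fit_cohort(blocks[[cond]]$per_subject,
                                    searches[[cond]]$best_model,
                                    restarts = config$restarts,
                                    seed = derive_seed(config$seed, "confirm-step"))
    sw <- stepwise_regress(conf$coefficients, scores,
                           p_in = config$p_in, p_out = config$p_out)
    list(confirmatory = conf, result = sw)
  })
  write_tsv(as.data.frame(stepwise$confirmatory$coefficients),
            file.path(out_dir, "confirmatory_coefficients.tsv"))
  jsonlite::write_json(
    list(selected = stepwise$result$selected,
         steps = stepwise$result$steps,
         r_squared = stepwise$result$r_squared),
    file.path(out_dir, "stepwise.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows")

  manifest <- run_stage("manifest", verbose, {
    cfg <- config
    cfg$model <- list(nodes = model$nodes,
                      conditions = names(model$B_by_condition),
                      noise_sd = model$noise_sd, subject_sd = model$subject_sd)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    m <- list(package = "roisem",
              version = as.character(utils::packageVersion("roisem")),
              seed = config$seed,
              config_hash = unname(tools::md5sum(cfg_path)),
              files = data.frame(
                file = files,
                md5 = unname(tools::md5sum(file.path(out_dir, files))),
                stringsAsFactors = FALSE))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    m
  })

  invisible(list(paradigm = par_, cohort = cohort, glm = glm_res,
                 behaviour = corr_res, ppi = ppi_res, blocks = blocks,
                 searches = searches, comparisons = comparisons,
                 stepwise = stepwise, manifest = manifest))
}
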