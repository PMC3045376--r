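# TSV dialect: tab separator, dot decimal, LF endings, UTF-8, no quoting.
# Numerics are written with %.17g so writer/reader pairs round-trip exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a paradigm as a BIDS-style events table
#'
#' Columns `onset`, `duration`, `trial_type`; seconds with dot decimals,
#' tab-separated, LF endings.
#'
#' @param paradigm A [paradigm()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "paradigm"))
  df <- data.frame(onset = paradigm$segments$onset,
                   duration = paradigm$segments$duration,
                   trial_type = paradigm$segments$category,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a BIDS-style events table as a paradigm
#'
#' @param path Events TSV with header `onset`, `duration`, `trial_type`.
#' @param tr Repetition time in seconds (not part of the events format).
#' @param n_scans Scan count; default: smallest count covering the last
#'   segment.
#' @param categories Allowed trial types; unknown values are rejected with
#'   their line number.
#' @return A [paradigm()].
#' @export
read_events <- function(path, tr = 2,
                        n_scans = NULL,
                        categories = c("care", "justice", "neutral",
                                       "strategic", "tactical")) {
  df <- read_tsv(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% colnames(df))) {
    stop_("events file must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_("events file has no data rows")
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_("malformed numeric '%s' at line %d of %s", col, bad[1] + 1, path)
    }
    df[[col]] <- v
  }
  bad <- which(!df$trial_type %in% categories)
  if (length(bad)) {
    stop_("unknown trial_type '%s' at line %d of %s",
          df$trial_type[bad[1]], bad[1] + 1, path)
  }
  n_scans <- n_scans %||%
    ceiling((df$onset[nrow(df)] + df$duration[nrow(df)]) / tr)
  paradigm(df$onset, df$duration, df$trial_type, tr, n_scans)
}

#' Write / read an ROI time-series table
#'
#' TSV with a header row of ROI labels and one row per scan.
#'
#' @param ts Scans x ROIs numeric matrix with column names.
#' @param path File path.
#' @return `write_timeseries`: the path, invisibly. `read_timeseries`: the
#'   matrix.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(is.matrix(ts), !is.null(colnames(ts)))
  write_tsv(as.data.frame(ts), path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_("non-numeric values in time-series file %s", path)
  m
}

#' Write / read a labelled covariance matrix
#'
#' Square TSV with ROI labels as header and first column. Reading checks
#' symmetry: asymmetry above 1e-10 is an error, below it the matrix is
#' symmetrised.
#'
#' @param S Square labelled covariance matrix.
#' @param path File path.
#' @return `write_cov`: the path, invisibly. `read_cov`: the matrix.
#' @export
write_cov <- function(S, path) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  df <- data.frame(roi = rownames(S), as.data.frame(S), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_cov
#' @export
read_cov <- function(path) {
  df <- read_tsv(path)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (!identical(sort(labels), sort(colnames(m)))) {
    stop_("row labels {%s} do not match column labels {%s} in %s",
          paste(labels, collapse = ","), paste(colnames(m), collapse = ","),
          path)
  }
  m <- m[, labels, drop = FALSE]
  asym <- max(abs(m - t(m)))
  if (asym > 1e-10) {
    stop_("covariance in %s is asymmetric (max |S - t(S)| = %.3g)", path, asym)
  }
  (m + t(m)) / 2
}

#' Write / read a path model as JSON
#'
#' Format: `{"nodes": [...], "edges": [["FP","pSTS"], ...]}` with edges as
#' (source, target) pairs.
#'
#' @param model A [path_model()].
#' @param path File path.
#' @return `write_model`: the path, invisibly. `read_model`: a
#'   [path_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "path_model"))
  edges <- lapply(seq_len(nrow(model$edges)),
                  function(i) unname(model$edges[i, ]))
  jsonlite::write_json(list(nodes = model$nodes, edges = edges), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$nodes)) stop_("model JSON %s lacks 'nodes'", path)
  edges <- obj$edges
  if (!is.null(edges) && length(edges)) {
    if (!is.matrix(edges)) edges <- do.call(rbind, edges)
  } else {
    edges <- NULL
  }
  path_model(as.character(obj$nodes), edges)
}

#' Write an SEM fit (parameter table and index panel) as JSON
#'
#' @param fit A [fit_sem()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_sem_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sem_fit"))
  obj <- list(nodes = fit$model$nodes,
              edges = lapply(seq_len(nrow(fit$model$edges)),
                             function(i) unname(fit$model$edges[i, ])),
              parameters = fit$params,
              fml = fit$fml, chisq = fit$chisq, df = fit$df, n = fit$n,
              q = fit$q, converged = fit$converged, stability = fit$stability,
              indices = fit$indices)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Write a cohort manifest as JSON
#'
#' @param cohort List of `subject_record` objects.
#' @param files Named list/vector of per-subject time-series file paths
#'   (optional).
#' @param seed Master seed used for the simulation.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path, files = NULL, seed = NULL) {
  obj <- list(
    subjects = data.frame(
      subject_id = vapply(cohort, `[[`, "", "subject_id"),
      score = vapply(cohort, `[[`, 0, "score"),
      file = if (is.null(files)) NA_character_ else unlist(files),
      stringsAsFactors = FALSE),
    seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
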