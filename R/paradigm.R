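#' Construct a block-design paradigm
#'
#' A paradigm is an ordered set of non-overlapping stimulus segments, each
#' with an onset (seconds from first scan), a duration and a category label,
#' plus the acquisition parameters (`tr`, `n_scans`) that tie segment timing
#' to scan indices.
#'
#' @param onset Numeric vector of segment onsets in seconds, strictly
#'   increasing.
#' @param duration Numeric vector of segment durations in seconds (> 0).
#' @param category Character vector of segment category labels.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans; `n_scans * tr` must cover the last segment.
#' @return An object of class `paradigm`: a list with a `segments` data frame
#'   (`onset`, `duration`, `category`) and scalars `tr`, `n_scans`.
#' @seealso [make_paradigm()] for generating the standard interleaved design.
#' @export
paradigm <- function(onset, duration, category, tr, n_scans) {
  stopifnot(length(onset) == length(duration),
            length(onset) == length(category))
  if (length(onset) == 0L) stop_("a paradigm needs at least one segment")
  if (any(duration <= 0)) stop_("every segment duration must be > 0")
  if (is.unsorted(onset, strictly = TRUE)) {
    stop_("segment onsets must be strictly increasing")
  }
  if (length(onset) > 1L &&
      any(onset[-1L] < (onset + duration)[-length(onset)] - 1e-9)) {
    stop_("segments overlap")
  }
  if (tr <= 0) stop_("tr must be > 0")
  last_end <- onset[length(onset)] + duration[length(duration)]
  if (n_scans * tr < last_end - 1e-9) {
    stop_("n_scans * tr (%.1f s) does not cover the last segment (ends %.1f s)",
          n_scans * tr, last_end)
  }
  structure(
    list(segments = data.frame(onset = as.numeric(onset),
                               duration = as.numeric(duration),
                               category = as.character(category),
                               stringsAsFactors = FALSE),
         tr = as.numeric(tr), n_scans = as.integer(n_scans)),
    class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("paradigm: %d segments, %.0f s of stimulus, tr = %g s, %d scans\n",
              nrow(x$segments),
              sum(x$segments$duration), x$tr, x$n_scans))
  print(table(x$segments$category))
  invisible(x)
}

#' Generate the interleaved moral-sensitivity block design
#'
#' Builds the standard story-segment paradigm: non-neutral categories are
#' presented as adjacent same-category pairs, consecutive pairs are separated
#' by a single neutral segment, and any neutral segments beyond the mandatory
#' separators are placed deterministically under the seed (the first two
#' surplus segments go to the sequence start and end, the remainder are
#' inserted at randomly chosen separator slots). The default counts give the
#' 41-segment design: 6 care, 6 justice, 6 strategic, 6 tactical and 17
#' neutral segments of 15 s each (615 s of stimulus).
#'
#' @param design_counts Named integer vector of segments per category. Must
#'   contain even counts for every non-neutral category.
#' @param segment_duration Duration of each segment in seconds.
#' @param tr Repetition time in seconds (default 2).
#' @param seed Integer seed controlling pair order and neutral placement.
#' @return A [paradigm()] object.
#' @examples
#' p <- make_paradigm()
#' table(p$segments$category)
#' @export
make_paradigm <- function(design_counts = c(care = 6, justice = 6, neutral = 17,
                                            strategic = 6, tactical = 6),
                          segment_duration = 15, tr = 2, seed = 1) {
  if (is.null(names(design_counts)) || any(!nzchar(names(design_counts)))) {
    stop_("design_counts must be a named vector of category counts")
  }
  if (any(design_counts < 0)) stop_("category counts must be non-negative")
  if (segment_duration <= 0) stop_("segment_duration must be > 0")
  if (tr <= 0) stop_("tr must be > 0")

  n_neutral <- unname(design_counts["neutral"])
  if (is.na(n_neutral)) n_neutral <- 0L
  nn <- design_counts[setdiff(names(design_counts), "neutral")]
  nn <- nn[nn > 0]
  if (any(nn %% 2 != 0)) {
    stop_("non-neutral categories must have even counts (got %s)",
          paste(sprintf("%s=%d", names(nn)[nn %% 2 != 0],
                        nn[nn %% 2 != 0]), collapse = ", "))
  }
  n_pairs <- sum(nn) %/% 2
  n_sep <- max(n_pairs - 1L, 0L)
  if (n_neutral < n_sep) {
    stop_("need at least %d neutral separator segments for %d pairs, have %d",
          n_sep, n_pairs, n_neutral)
  }
  surplus <- n_neutral - n_sep

  cats <- with_seed(seed, {
    pair_cats <- rep(names(nn), nn %/% 2)
    if (length(pair_cats) > 1L) pair_cats <- sample(pair_cats)
    seq_cats <- character(0)
    for (i in seq_along(pair_cats)) {
      if (i > 1L) seq_cats <- c(seq_cats, "neutral")
      seq_cats <- c(seq_cats, rep(pair_cats[i], 2L))
    }
    if (surplus > 0L) {
      sides <- if (stats::runif(1) < 0.5) c("start", "end") else c("end", "start")
      k <- min(surplus, 2L)
      for (side in sides[seq_len(k)]) {
        seq_cats <- if (side == "start") c("neutral", seq_cats)
                    else c(seq_cats, "neutral")
      }
      remaining <- surplus - k
      if (remaining > 0L) {
        sep_at <- which(seq_cats == "neutral")
        for (j in seq_len(remaining)) {
          at <- sep_at[sample.int(length(sep_at), 1L)]
          seq_cats <- append(seq_cats, "neutral", after = at)
          sep_at <- which(seq_cats == "neutral")
        }
      }
    }
    seq_cats
  })

  n_seg <- length(cats)
  onsets <- (seq_len(n_seg) - 1) * segment_duration
  n_scans <- ceiling(n_seg * segment_duration / tr)
  paradigm(onsets, rep(segment_duration, n_seg), cats, tr, n_scans)
}

#' Scan times of a paradigm
#'
#' @param p A [paradigm()] object.
#' @return Numeric vector of scan acquisition times in seconds (first scan
#'   at time 0).
#' @export
scan_times <- function(p) {
  stopifnot(inherits(p, "paradigm"))
  (seq_len(p$n_scans) - 1) * p$tr
}

#' Active condition at each scan
#'
#' @param p A [paradigm()] object.
#' @param baseline Label used for scans falling outside every segment.
#' @return Character vector of length `n_scans`.
#' @export
condition_at_scans <- function(p, baseline = "baseline") {
  t <- scan_times(p)
  out <- rep(baseline, p$n_scans)
  for (i in seq_len(nrow(p$segments))) {
    s <- p$segments[i, ]
    out[t >= s$onset - 1e-9 & t < s$onset + s$duration - 1e-9] <- s$category
  }
  out
}
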