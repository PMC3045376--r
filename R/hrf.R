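#' Canonical double-gamma haemodynamic response function
#'
#' Samples the standard canonical HRF -- the difference of two gamma
#' densities, one modelling the positive response peaking near 5 s and one
#' modelling the late undershoot near 15-16 s -- at the acquisition interval
#' `tr`, scaled to unit peak. With unit dispersions the gamma shapes equal
#' the peak and undershoot delays.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param length Kernel support in seconds (>= `tr`, default 32).
#' @param peak_delay,peak_disp Delay (s) and dispersion of the response gamma
#'   (defaults 6 and 1).
#' @param undershoot_delay,undershoot_disp Delay (s) and dispersion of the
#'   undershoot gamma (defaults 16 and 1).
#' @param undershoot_ratio Relative amplitude of the undershoot (default 1/6).
#' @return Numeric kernel sampled at `0, tr, 2 tr, ...` up to `length`,
#'   with attribute `times`.
#' @examples
#' h <- canonical_hrf(0.5)
#' attr(h, "times")[which.max(h)]   # peak near 5 s
#' @export
canonical_hrf <- function(tr, length = 32, peak_delay = 6, peak_disp = 1,
                          undershoot_delay = 16, undershoot_disp = 1,
                          undershoot_ratio = 1 / 6) {
  if (tr <= 0) stop_("tr must be > 0")
  if (length < tr) stop_("kernel length must be at least one tr")
  t <- seq(0, length, by = tr)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                    scale = undershoot_disp)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}
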