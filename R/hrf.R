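#' Canonical double-gamma hemodynamic response function
#'
#' The BOLD response to a brief neural event is modeled as the difference of
#' two gamma densities: a positive lobe peaking about 5 s after the event
#' and a negative undershoot around 15 s.  The returned curve is scaled to a
#' peak of 1 so that downstream percent-signal-change amplitudes are read
#' directly off the regressor.
#'
#' @param t Time in seconds (vector, `t >= 0`).
#' @param peak_shape,peak_rate Shape/rate of the positive gamma lobe
#'   (defaults peak at `(peak_shape - 1) / peak_rate` = 5 s).
#' @param under_shape,under_rate Shape/rate of the undershoot lobe
#'   (defaults bottom near 15 s).
#' @param under_ratio Relative amplitude of the undershoot (default 1/6).
#' @return Numeric vector of HRF values, peak normalized to 1.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, peak_rate = 1,
                             under_shape = 16, under_rate = 1,
                             under_ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = peak_shape, rate = peak_rate) -
    under_ratio * stats::dgamma(t, shape = under_shape, rate = under_rate)
  ref <- stats::dgamma((peak_shape - 1) / peak_rate,
                       shape = peak_shape, rate = peak_rate) -
    under_ratio * stats::dgamma((peak_shape - 1) / peak_rate,
                                shape = under_shape, rate = under_rate)
  h / ref
}

# HRF sampled at the scan grid, covering `span_s` seconds.
hrf_samples <- function(tr_seconds, span_s = 32, ...) {
  hrf_double_gamma(seq(0, span_s, by = tr_seconds), ...)
}

#' Convolve a per-scan indicator with the canonical HRF
#'
#' @param indicator 0/1 vector marking the scans of one condition.
#' @param tr_seconds Repetition time in seconds.
#' @param normalize If `TRUE` (default) the output is scaled so that the
#'   response to a single sustained block of `block_len` scans peaks at 1;
#'   this makes a planted effect of `e` percent produce a peak percent
#'   change of `e`.
#' @param block_len Block length in scans used for normalization; defaults
#'   to the longest run of 1s in `indicator`.
#' @return Numeric vector, same length as `indicator`.
#' @export
convolve_hrf <- function(indicator, tr_seconds, normalize = TRUE,
                         block_len = NULL) {
  n <- length(indicator)
  h <- hrf_samples(tr_seconds)
  x <- stats::convolve(c(indicator, rep(0, length(h))), rev(h),
                       type = "open")[seq_len(n)]
  if (normalize) {
    if (is.null(block_len)) {
      r <- rle(indicator > 0)
      block_len <- if (any(r$values)) max(r$lengths[r$values]) else 1L
    }
    ref <- stats::convolve(c(rep(1, block_len), rep(0, 3 * length(h))),
                           rev(h), type = "open")
    x <- x / max(ref)
  }
  x
}
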