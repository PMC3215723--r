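#' Smoothness-priors detrending
#'
#' Removes the low-frequency trend of a time series with the
#' regularized-least-squares ("smoothness priors") estimator
#' `trend = (I + lambda^2 D2'D2)^-1 z`, where `D2` is the second-difference
#' operator, returning `z - trend`.  Constant and linear components lie in
#' the null space of `D2` and are removed exactly; `lambda = 0` returns all
#' zeros (the trend equals the data).  At feedback time this is re-applied
#' to the full available series (localizer plus feedback so far) at every
#' new scan.
#'
#' @param z Numeric vector, or a scans x voxels matrix detrended
#'   column-wise with a single factorization.
#' @param lambda Nonnegative smoothing parameter (default 500).
#' @return Detrended vector or matrix of the same shape.
#' @export
detrend_sp <- function(z, lambda = 500) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  vec <- is.null(dim(z))
  zm <- if (vec) matrix(z, ncol = 1) else as.matrix(z)
  n <- nrow(zm)
  if (n < 3) stop("series must have length >= 3", call. = FALSE)
  if (lambda == 0) {
    out <- zm * 0
  } else {
    A <- detrend_operator(n, lambda)
    out <- zm - as.matrix(Matrix::solve(A, zm))
  }
  if (vec) as.numeric(out) else out
}

detrend_operator <- function(n, lambda) {
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2),
                                            rep(-2, n - 2),
                                            rep(1, n - 2)))
  Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
}

#' Percent-signal-change control signal
#'
#' The per-scan control signal is the percent change of the right ROI from
#' its baseline minus the percent change of the left ROI from its
#' baseline: `CS = 100 (S_R - B_R) / B_R - 100 (S_L - B_L) / B_L`.
#' Contralateral activation and ipsilateral deactivation therefore add.
#' Optionally each percent term is divided by its localizer-derived
#' standard deviation before subtraction, giving a laterally more
#' symmetric signal.
#'
#' @param s_r,s_l ROI-averaged signal values (vectorized).
#' @param baseline_r,baseline_l Strictly positive baselines.
#' @param normalize_sd Divide each percent term by its standard deviation.
#' @param sd_r,sd_l Localizer-derived SDs of the two percent terms
#'   (required when `normalize_sd = TRUE`).
#' @return Control signal value(s).
#' @export
control_signal <- function(s_r, s_l, baseline_r, baseline_l,
                           normalize_sd = FALSE, sd_r = NULL, sd_l = NULL) {
  if (baseline_r <= 0 || baseline_l <= 0) {
    stop("baselines must be strictly positive", call. = FALSE)
  }
  pr <- 100 * (s_r - baseline_r) / baseline_r
  pl <- 100 * (s_l - baseline_l) / baseline_l
  if (normalize_sd) {
    if (is.null(sd_r) || is.null(sd_l) || sd_r <= 0 || sd_l <= 0) {
      stop("normalize_sd requires positive sd_r and sd_l", call. = FALSE)
    }
    pr <- pr / sd_r
    pl <- pl / sd_l
  }
  pr - pl
}

#' Classification thresholds
#'
#' Three ascending thresholds above zero for rightward control and three
#' descending below zero for leftward control.  The fixed scheme is
#' `(1.5, 2.5, 4)` and `(-1.5, -2.5, -4)`.
#'
#' @param pos Ascending numeric triple.
#' @param neg Descending numeric triple.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(pos = c(1.5, 2.5, 4), neg = c(-1.5, -2.5, -4)) {
  stopifnot(length(pos) == 3, length(neg) == 3)
  if (!(pos[1] < pos[2] && pos[2] < pos[3])) {
    stop("positive thresholds must be strictly ascending", call. = FALSE)
  }
  if (!(neg[1] > neg[2] && neg[2] > neg[3])) {
    stop("negative thresholds must be strictly descending", call. = FALSE)
  }
  structure(list(pos = pos, neg = neg), class = "threshold_set")
}

#' Classify one control-signal value into a feedback state and color
#'
#' Magnitude-banded: beyond the second threshold is "strong", between the
#' first and second "weak", inside the first pair "off".  The feedback
#' color is a green tone when the state matches the instruction (or the
#' signal is near baseline during CENTER), a red tone otherwise; exact
#' screen tones are out of scope, the color is an enumerated label.
#'
#' @param cs Control-signal value.
#' @param condition_context `"ATTENTION"` or `"CENTER"`.
#' @param instructed_side `"LEFT"` or `"RIGHT"` (ignored for CENTER).
#' @param thresholds A [threshold_set()].
#' @return List with `state` (one of `STRONG_R`, `WEAK_R`, `OFF`,
#'   `WEAK_L`, `STRONG_L`) and `color` (`green_dark`, `green_light`,
#'   `red_light`, `red_dark`).
#' @export
classify_cs <- function(cs, condition_context = c("ATTENTION", "CENTER"),
                        instructed_side = NULL, thresholds = threshold_set()) {
  condition_context <- match.arg(condition_context)
  th <- thresholds
  state <- if (cs > th$pos[2]) "STRONG_R"
  else if (cs > th$pos[1]) "WEAK_R"
  else if (cs < th$neg[2]) "STRONG_L"
  else if (cs < th$neg[1]) "WEAK_L"
  else "OFF"
  color <- if (condition_context == "CENTER") {
    if (state == "OFF") "green_light"
    else if (state %in% c("STRONG_R", "STRONG_L")) "red_dark" else "red_light"
  } else {
    correct <- switch(state,
                      STRONG_R = , WEAK_R = identical(instructed_side, "RIGHT"),
                      STRONG_L = , WEAK_L = identical(instructed_side, "LEFT"),
                      OFF = FALSE)
    if (correct) {
      if (state %in% c("STRONG_R", "STRONG_L")) "green_dark" else "green_light"
    } else {
      if (state %in% c("STRONG_R", "STRONG_L")) "red_dark" else "red_light"
    }
  }
  list(state = state, color = color)
}

#' Adaptive FPR-constrained thresholds from localizer data
#'
#' Estimates the first threshold pair from the retrospective localizer
#' control signal: with instruction labels shifted by `shift_trs` scans,
#' the rightward threshold is the smallest observed CS value such that the
#' fraction of LEFT-or-CENTER scans with CS strictly above it is at most
#' `target_fpr` (the empirical FPR is a step function of the threshold, so
#' searching the observed values is exact); mirrored for leftward.  The
#' second and third levels are scaled from the first by the fixed-scheme
#' ratios 2.5/1.5 and 4/1.5 (for a non-positive first threshold, where
#' ratio scaling would invert the ordering, the fixed-scheme gaps 1.0 and
#' 2.5 are added instead).
#'
#' @param localizer_cs Per-scan retrospective control signal.
#' @param schedule Localizer schedule aligned to `localizer_cs` (or a
#'   per-scan label vector).
#' @param target_fpr Training false-positive-rate bound (default 0.2).
#' @param shift_trs Hemodynamic instruction shift in scans (default 3).
#' @return A [threshold_set()] with attributes `fpr_r`, `fpr_l` (achieved
#'   training FPRs at the first thresholds).
#' @export
adaptive_thresholds <- function(localizer_cs, schedule, target_fpr = 0.2,
                                shift_trs = 3L) {
  labels <- if (is.character(schedule)) schedule else schedule_labels(schedule)
  stopifnot(length(labels) == length(localizer_cs))
  lab <- shift_labels(labels, shift_trs)
  use <- !is.na(lab)
  cs <- localizer_cs[use]
  lab <- lab[use]

  pick <- function(negatives, beyond) {
    cand <- sort(unique(cs))
    fprs <- vapply(cand, function(th) mean(beyond(cs[negatives], th)),
                   numeric(1))
    ok <- which(fprs <= target_fpr)
    if (length(ok) == 0) return(list(th = Inf, fpr = 0))
    list(th = cand[ok[1]], fpr = fprs[ok[1]])
  }
  r <- pick(lab %in% c("LEFT", "CENTER"), function(x, th) x > th)
  # leftward: smallest |threshold| i.e. the largest (least negative) value
  cand_l <- sort(unique(cs), decreasing = TRUE)
  neg_l <- lab %in% c("RIGHT", "CENTER")
  fprs_l <- vapply(cand_l, function(th) mean(cs[neg_l] < th), numeric(1))
  okl <- which(fprs_l <= target_fpr)
  l <- if (length(okl) == 0) list(th = -Inf, fpr = 0)
  else list(th = cand_l[okl[1]], fpr = fprs_l[okl[1]])

  scale_up <- function(t1) {
    if (t1 > 0) c(t1, t1 * 2.5 / 1.5, t1 * 4 / 1.5) else t1 + c(0, 1, 2.5)
  }
  scale_dn <- function(t1) {
    if (t1 < 0) c(t1, t1 * 2.5 / 1.5, t1 * 4 / 1.5) else t1 - c(0, 1, 2.5)
  }
  out <- threshold_set(scale_up(r$th), scale_dn(l$th))
  attr(out, "fpr_r") <- r$fpr
  attr(out, "fpr_l") <- l$fpr
  out
}

# SDs of the localizer percent-change terms, for the SD-normalized control
# signal variant.
localizer_pct_sd <- function(detrended_mean_r, detrended_mean_l,
                             baseline_r, baseline_l) {
  list(sd_r = stats::sd(100 * detrended_mean_r / baseline_r),
       sd_l = stats::sd(100 * detrended_mean_l / baseline_l))
}

#' Retrospective control signal on localizer data
#'
#' Detrends the stored per-voxel localizer series of both ROIs (full
#' series, single pass), averages voxels per ROI, anchors the ROI level at
#' the localizer baseline, and applies the control-signal definition to
#' every localizer scan.
#'
#' @param pair A [compute_baselines()]-completed `roi_pair`.
#' @param lambda Detrending parameter (default 500).
#' @param normalize_sd Use the SD-normalized control-signal variant.
#' @return Numeric control-signal vector (one value per localizer scan),
#'   with attributes `sd_r`, `sd_l`.
#' @export
localizer_cs <- function(pair, lambda = 500, normalize_sd = FALSE) {
  stopifnot(!is.null(pair$localizer_series))
  d_r <- rowMeans(detrend_sp(pair$localizer_series$r, lambda))
  d_l <- rowMeans(detrend_sp(pair$localizer_series$l, lambda))
  sds <- localizer_pct_sd(d_r, d_l, pair$baseline_r, pair$baseline_l)
  cs <- control_signal(pair$baseline_r + d_r, pair$baseline_l + d_l,
                       pair$baseline_r, pair$baseline_l,
                       normalize_sd = normalize_sd,
                       sd_r = sds$sd_r, sd_l = sds$sd_l)
  attr(cs, "sd_r") <- sds$sd_r
  attr(cs, "sd_l") <- sds$sd_l
  cs
}

#' Run the real-time feedback loop
#'
#' For every feedback scan, appends the new ROI voxel values to the series
#' available so far (localizer included), re-detrends each voxel's full
#' series, averages per ROI, forms the control signal against the
#' localizer baselines, and classifies it against the thresholds.  The
#' detrended deviations are anchored at the localizer baselines (the
#' smoothness-priors residual is zero-mean by construction).
#'
#' @param feedback_series scans x voxels matrix of ALL feedback-scan values
#'   for the union of ROI voxels, ordered `c(pair$roi_r, pair$roi_l)`; or a
#'   `volume_series` covering the feedback scans.
#' @param pair A [compute_baselines()]-completed `roi_pair`.
#' @param schedule_fb Feedback schedule.
#' @param thresholds A [threshold_set()].
#' @param lambda Detrending parameter (default 500).
#' @param shift_trs Hemodynamic shift used for the stored shifted labels.
#' @param context_labels Optional labels of the scans directly preceding
#'   the feedback part (used to shift labels across the part boundary).
#' @param normalize_sd Use the SD-normalized control-signal variant.
#' @return A `control_trace` data frame: `scan`, `cs`, `condition`,
#'   `shifted_condition`, `state`, `color`.
#' @export
run_feedback <- function(feedback_series, pair, schedule_fb,
                         thresholds = threshold_set(), lambda = 500,
                         shift_trs = 3L, context_labels = NULL,
                         normalize_sd = FALSE) {
  voxels <- c(pair$roi_r, pair$roi_l)
  n_r <- length(pair$roi_r)
  if (inherits(feedback_series, "volume_series")) {
    feedback_series <- roi_series(feedback_series, voxels)
  }
  stopifnot(ncol(feedback_series) == length(voxels))
  n_fb <- attr(schedule_fb, "n_scans_total")
  stopifnot(nrow(feedback_series) >= n_fb)
  loc <- cbind(pair$localizer_series$r, pair$localizer_series$l)
  n_loc <- nrow(loc)

  sds <- if (normalize_sd) {
    cs0 <- localizer_cs(pair, lambda, normalize_sd = FALSE)
    list(sd_r = attr(cs0, "sd_r"), sd_l = attr(cs0, "sd_l"))
  } else list(sd_r = NULL, sd_l = NULL)

  labels <- schedule_labels(schedule_fb)
  shifted <- shift_labels(c(context_labels, labels),
                          shift_trs)[length(context_labels) + seq_len(n_fb)]

  cs <- numeric(n_fb)
  states <- colors <- character(n_fb)
  for (t in seq_len(n_fb)) {
    avail <- rbind(loc, feedback_series[seq_len(t), , drop = FALSE])
    det <- detrend_sp(avail, lambda)
    last <- det[n_loc + t, ]
    s_r <- pair$baseline_r + mean(last[seq_len(n_r)])
    s_l <- pair$baseline_l + mean(last[n_r + seq_len(length(pair$roi_l))])
    cs[t] <- control_signal(s_r, s_l, pair$baseline_r, pair$baseline_l,
                            normalize_sd = normalize_sd,
                            sd_r = sds$sd_r, sd_l = sds$sd_l)
    ctx <- if (labels[t] == "CENTER") "CENTER" else "ATTENTION"
    cl <- classify_cs(cs[t], ctx,
                      instructed_side = if (ctx == "ATTENTION") labels[t],
                      thresholds = thresholds)
    states[t] <- cl$state
    colors[t] <- cl$color
  }
  off <- attr(schedule_fb, "onset_offset_scans") %||% 0L
  structure(data.frame(scan = off + seq_len(n_fb), cs = cs,
                       condition = labels, shifted_condition = shifted,
                       state = states, color = colors,
                       stringsAsFactors = FALSE),
            tr_seconds = attr(schedule_fb, "tr_seconds"),
            shift_trs = as.integer(shift_trs),
            class = c("control_trace", "data.frame"))
}

#' Write a control trace as a tab-delimited table
#' @param trace A `control_trace`.
#' @param path Output path.
#' @export
write_control_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
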