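#' Shifted per-scan true/false positive rates
#'
#' With instruction labels shifted by `shift_trs` scans to account for the
#' hemodynamic delay, the per-side TPR is the fraction of that side's
#' attention scans whose control signal lies beyond the first threshold in
#' the correct direction, and the per-side FPR is the fraction of
#' non-that-side scans beyond that threshold.  CENTER scans can be
#' excluded from the FPR denominator (the post-block BOLD undershoot can
#' rebound the signal across the opposite threshold during CENTER).
#'
#' @param trace A `control_trace` (columns `cs`, `condition`, optionally
#'   `shifted_condition`).
#' @param thresholds A [threshold_set()].
#' @param shift_trs Label shift in scans, used when the trace carries no
#'   `shifted_condition` column (default 3).
#' @param exclude_center Drop CENTER scans from the FPR denominators.
#' @return Named list `tpr_l`, `tpr_r`, `fpr_l`, `fpr_r`.
#' @export
classification_rates <- function(trace, thresholds, shift_trs = 3L,
                                 exclude_center = FALSE) {
  lab <- if (!is.null(trace$shifted_condition)) trace$shifted_condition
  else shift_labels(trace$condition, shift_trs)
  cs <- trace$cs
  use <- !is.na(lab)
  cs <- cs[use]; lab <- lab[use]
  pos_r <- cs > thresholds$pos[1]
  pos_l <- cs < thresholds$neg[1]
  den_tpr_r <- lab == "RIGHT"
  den_tpr_l <- lab == "LEFT"
  den_fpr_r <- if (exclude_center) lab == "LEFT" else lab != "RIGHT"
  den_fpr_l <- if (exclude_center) lab == "RIGHT" else lab != "LEFT"
  for (d in list(den_tpr_r, den_tpr_l, den_fpr_r, den_fpr_l)) {
    if (!any(d)) stop("empty rate denominator", call. = FALSE)
  }
  list(tpr_l = mean(pos_l[den_tpr_l]), tpr_r = mean(pos_r[den_tpr_r]),
       fpr_l = mean(pos_l[den_fpr_l]), fpr_r = mean(pos_r[den_fpr_r]))
}

#' ROC sweep over classification thresholds
#'
#' Evaluates [classification_rates()] over a grid of first thresholds per
#' side (defaults: -1 to 5 for rightward, 1 to -5 for leftward) and
#' returns the (threshold, fpr, tpr) points per side, sorted by threshold.
#'
#' @param trace A `control_trace`.
#' @param threshold_grid_r,threshold_grid_l Threshold grids.
#' @param shift_trs Label shift in scans (default 3).
#' @param exclude_center Drop CENTER scans from the FPR denominator.
#' @return Data frame with columns `side`, `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(trace,
                      threshold_grid_r = seq(-1, 5, by = 0.1),
                      threshold_grid_l = seq(1, -5, by = -0.1),
                      shift_trs = 3L, exclude_center = FALSE) {
  eval_side <- function(grid, side) {
    pts <- lapply(grid, function(th) {
      ts <- if (side == "R") threshold_set(th + c(0, 1, 2.5),
                                           c(-1.5, -2.5, -4))
      else threshold_set(c(1.5, 2.5, 4), th - c(0, 1, 2.5))
      r <- classification_rates(trace, ts, shift_trs, exclude_center)
      if (side == "R") c(r$fpr_r, r$tpr_r) else c(r$fpr_l, r$tpr_l)
    })
    m <- do.call(rbind, pts)
    data.frame(side = side, threshold = grid, fpr = m[, 1], tpr = m[, 2])
  }
  out <- rbind(eval_side(sort(threshold_grid_r), "R"),
               eval_side(sort(threshold_grid_l), "L"))
  out[order(out$side, out$threshold), ]
}

#' Single-time-point trial classification accuracy
#'
#' Classifies each feedback trial three ways from the single scan at a
#' given within-trial index (no hemodynamic shift): control signal above
#' the rightward first threshold predicts RIGHT, below the leftward first
#' threshold predicts LEFT, otherwise CENTER.  Returns the fraction of
#' correctly classified trials per condition.
#'
#' @param trace A `control_trace` covering the feedback schedule.
#' @param schedule_fb Feedback schedule (fixed trial length).
#' @param thresholds A [threshold_set()].
#' @param timepoint Within-trial scan index (1-based).
#' @return Named list `acc_l`, `acc_r`, `acc_c` plus `predictions`.
#' @export
trial_accuracy_by_timepoint <- function(trace, schedule_fb, thresholds,
                                        timepoint = 5L) {
  len <- unique(schedule_fb$length_scans)
  stopifnot(length(len) == 1)
  if (timepoint < 1 || timepoint > len) {
    stop("timepoint exceeds the trial length", call. = FALSE)
  }
  scan_at <- schedule_fb$onset_scan + timepoint - 1L
  cs <- trace$cs[match(scan_at, trace$scan)]
  if (any(is.na(cs))) stop("trace does not cover the schedule", call. = FALSE)
  pred <- ifelse(cs > thresholds$pos[1], "RIGHT",
                 ifelse(cs < thresholds$neg[1], "LEFT", "CENTER"))
  truth <- schedule_fb$condition
  acc <- function(side) mean(pred[truth == side] == side)
  list(acc_l = acc("LEFT"), acc_r = acc("RIGHT"), acc_c = acc("CENTER"),
       predictions = data.frame(condition = truth, predicted = pred,
                                stringsAsFactors = FALSE))
}

#' Wolpaw information transfer rate
#'
#' Bits per trial `log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`
#' (with the `P = 0` and `P = 1` limits taken by continuity), scaled to
#' bits per minute by `60 / trial_seconds`.
#'
#' @param accuracy Classification accuracy `P` in `[0, 1]`.
#' @param n_classes Number of classes `N >= 2`.
#' @param trial_seconds Seconds per decision.
#' @return Bits per minute.
#' @export
wolpaw_bitrate <- function(accuracy, n_classes, trial_seconds) {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must be in [0, 1]",
                                         call. = FALSE)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (trial_seconds <= 0) stop("trial_seconds must be > 0", call. = FALSE)
  P <- accuracy
  N <- n_classes
  bits <- log2(N) +
    (if (P > 0) P * log2(P) else 0) +
    (if (P < 1) (1 - P) * log2((1 - P) / (N - 1)) else 0)
  bits * 60 / trial_seconds
}

#' Dice overlap of two voxel sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both sets are
#' empty.
#'
#' @param set_a,set_b Vectors of voxel indices.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Write a flat performance report
#' @param report Named list of scalars.
#' @param path Output path.
#' @export
write_perf_report <- function(report, path) {
  flat <- unlist(report)
  utils::write.table(data.frame(key = names(flat), value = as.numeric(flat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
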