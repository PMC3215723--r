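# Shared fixture builders; everything is generated in code at test time.

# Smooth multi-blob phantom with angular structure (for registration).
smooth_phantom <- function(d = c(16L, 16L, 16L)) {
  ctr <- (d + 1) / 2
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  exp(-((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2) / (2 * (d[1] / 4)^2)) +
    0.8 * exp(-((i - ctr[1] - d[1] / 4)^2 + (j - ctr[2])^2 +
                  (k - ctr[3])^2) / (2 * (d[1] / 8)^2)) +
    0.6 * exp(-((i - ctr[1])^2 + (j - ctr[2] - d[2] / 4)^2 +
                  (k - ctr[3] + d[3] / 8)^2) / (2 * (d[1] / 8)^2))
}

# Small phantom spec with hand-placed voxel sets on a tiny grid.
tiny_phantom <- function(noise_sd = 0, drift = 0, effect = 2, deact = -1,
                         cosine = 0) {
  d <- c(10L, 10L, 6L)
  lin <- function(i, j, k) i + d[1] * (j - 1L) + d[1] * d[2] * (k - 1L)
  phantom_spec(grid_shape = d,
               roi_truth_right = c(lin(3, 5, 3), lin(4, 5, 3)),
               roi_truth_left = c(lin(7, 5, 3), lin(8, 5, 3)),
               deact_right = lin(5, 5, 2), deact_left = lin(6, 5, 2),
               effect_pct = effect, deact_pct = deact,
               drift_pct_per_min = drift, cosine_drift_pct = cosine,
               noise_sd = noise_sd)
}

# Short schedule for quick runs.
tiny_schedule <- function(seed = 1, n = 2L, len = 4L, ...) {
  make_schedule(n, len, seed = seed, ...)
}

# Synthetic localizer control-signal trace: HRF-shaped differential
# response plus white noise, aligned to a localizer schedule.
synthetic_cs_trace <- function(schedule, amplitude = 2, noise_sd = 0.5,
                               seed = 1) {
  lab <- schedule_labels(schedule)
  tr <- attr(schedule, "tr_seconds")
  cs <- amplitude * convolve_hrf(as.numeric(lab == "RIGHT"), tr) -
    amplitude * convolve_hrf(as.numeric(lab == "LEFT"), tr)
  boldbci:::with_seed(seed, cs + stats::rnorm(length(cs), sd = noise_sd))
}

# Exhaustive threshold-sweep oracle for the adaptive threshold estimator:
# loops over every observed value, recomputes the FPR directly.
brute_force_threshold <- function(cs, labels, target_fpr, shift_trs,
                                  side = c("R", "L")) {
  side <- match.arg(side)
  lab <- boldbci:::shift_labels(labels, shift_trs)
  keep <- !is.na(lab)
  cs <- cs[keep]; lab <- lab[keep]
  if (side == "R") {
    neg <- cs[lab %in% c("LEFT", "CENTER")]
    cands <- sort(unique(cs))
    for (th in cands) if (mean(neg > th) <= target_fpr) return(th)
  } else {
    neg <- cs[lab %in% c("RIGHT", "CENTER")]
    cands <- sort(unique(cs), decreasing = TRUE)
    for (th in cands) if (mean(neg < th) <= target_fpr) return(th)
  }
  NA_real_
}

# Hand-made control trace with explicit per-scan control signal.
hand_trace <- function(cs, conditions, shift_trs = 0L) {
  structure(data.frame(scan = seq_along(cs), cs = cs,
                       condition = conditions,
                       stringsAsFactors = FALSE),
            class = c("control_trace", "data.frame"))
}
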