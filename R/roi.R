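#' Build the brain mask
#'
#' Smooths a (mean) volume with a Gaussian, thresholds it, fills enclosed
#' cavities morphologically, and removes the two most anterior coronal
#' slices to exclude registration boundary artifacts.  The default
#' threshold is 30% of the 98th intensity percentile of the smoothed
#' volume.
#'
#' @param mean_volume 3D array (e.g. the mean localizer volume).
#' @param blur_sigma Gaussian sigma in voxels (default 1).
#' @param threshold Absolute intensity threshold; default
#'   `0.3 * quantile(smoothed, 0.98)`.
#' @param coronal_axis Axis of the coronal slices (default 3).
#' @param anterior_high If `TRUE` (default) anterior is at high indices of
#'   `coronal_axis`.
#' @param n_exclude_slices Anterior slices to drop (default 2).
#' @return A logical 3D `brain_mask` array.
#' @export
make_mask <- function(mean_volume, blur_sigma = 1, threshold = NULL,
                      coronal_axis = 3L, anterior_high = TRUE,
                      n_exclude_slices = 2L) {
  stop_if_not_finite(mean_volume, "mean volume")
  sm <- gaussian_blur3(mean_volume, blur_sigma)
  if (is.null(threshold)) {
    threshold <- 0.3 * stats::quantile(sm, 0.98, names = FALSE)
  }
  mask <- sm > threshold
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  mask <- fill_holes3(mask)
  d <- dim(mask)
  slices <- if (anterior_high) {
    (d[coronal_axis] - n_exclude_slices + 1L):d[coronal_axis]
  } else {
    seq_len(n_exclude_slices)
  }
  idx <- lapply(d, seq_len)
  idx[[coronal_axis]] <- slices
  mask[idx[[1]], idx[[2]], idx[[3]]] <- FALSE
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  structure(mask, class = c("brain_mask", class(mask)))
}

#' Select the two differential-contrast ROIs
#'
#' Per side, restricts the t-map to the brain mask, keeps the `k` voxels
#' with the highest t-values (ties broken by ascending linear voxel index),
#' then removes 6-connected clusters smaller than `min_cluster` voxels.
#' The t-value at the k-th voxel is recorded as the selection threshold.
#'
#' @param tmap_r T-map of the right-minus-left contrast (3D).
#' @param tmap_l T-map of the left-minus-right contrast (3D).
#' @param mask A [make_mask()] brain mask.
#' @param k Voxels to keep per side before cluster filtering (default 500).
#' @param min_cluster Minimum cluster size retained (default 5).
#' @return A `roi_pair` list: `roi_r`, `roi_l` (linear voxel indices),
#'   `threshold_t_r`, `threshold_t_l`, `dims`; baselines and stored
#'   localizer series are filled in by [compute_baselines()].
#' @export
select_rois <- function(tmap_r, tmap_l, mask, k = 500L, min_cluster = 5L) {
  dims <- dim(mask)
  stopifnot(identical(dim(tmap_r), dims), identical(dim(tmap_l), dims))
  masked_idx <- which(as.vector(mask))
  if (length(masked_idx) < k) {
    stop("masked voxel count is smaller than k", call. = FALSE)
  }
  one_side <- function(tmap) {
    tv <- as.numeric(tmap)[masked_idx]
    ord <- order(-tv, masked_idx)      # ties: ascending voxel index
    top <- masked_idx[ord[seq_len(k)]]
    thr <- tv[ord[k]]
    labs <- label_components6(top, dims)
    sizes <- tabulate(labs)
    keep <- top[sizes[labs] >= min_cluster]
    if (length(keep) == 0) {
      warning("all clusters smaller than the minimum size; ROI is empty",
              call. = FALSE)
    }
    list(roi = sort(keep), threshold = thr)
  }
  r <- one_side(tmap_r)
  l <- one_side(tmap_l)
  structure(list(roi_r = r$roi, roi_l = l$roi,
                 threshold_t_r = r$threshold, threshold_t_l = l$threshold,
                 baseline_r = NULL, baseline_l = NULL,
                 localizer_series = NULL, dims = dims),
            class = "roi_pair")
}

# Scans usable for the ROI baselines: all CENTER scans except the first
# `n_exclude` scans of CENTER trials directly preceded by an attention
# trial (the BOLD response needs time to return to baseline).
baseline_scans <- function(schedule, n_exclude = 3L, relative = TRUE) {
  off <- if (relative) attr(schedule, "onset_offset_scans") %||% 0L else 0L
  keep <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    if (schedule$condition[i] != "CENTER") next
    a <- schedule$onset_scan[i] - off
    scans <- a:(a + schedule$length_scans[i] - 1L)
    preceded <- i > 1 && schedule$condition[i - 1] %in% c("LEFT", "RIGHT")
    if (preceded) scans <- scans[-seq_len(min(n_exclude, length(scans)))]
    keep <- c(keep, scans)
  }
  keep
}

#' Compute per-ROI baselines from localizer data
#'
#' The baseline of each ROI is the mean raw signal over its voxels and over
#' the qualifying CENTER-condition scans (the first `n_exclude` scans of
#' any CENTER trial preceded by an attention trial are excluded; an initial
#' CENTER trial keeps all its scans).  The per-voxel localizer series of
#' both ROIs are stored for feedback-time detrending.
#'
#' @param series Localizer `volume_series`.
#' @param schedule Localizer schedule.
#' @param pair A [select_rois()] `roi_pair`.
#' @param n_exclude Scans dropped at the start of post-attention CENTER
#'   trials (default 3).
#' @return The `roi_pair` with `baseline_r`, `baseline_l` and
#'   `localizer_series` filled in.
#' @export
compute_baselines <- function(series, schedule, pair, n_exclude = 3L) {
  n <- attr(schedule, "n_scans_total")
  stopifnot(dim(series)[4] >= n)
  keep <- baseline_scans(schedule, n_exclude)
  if (length(keep) == 0) {
    stop("no qualifying CENTER scans for the baseline", call. = FALSE)
  }
  ser_r <- roi_series(series, pair$roi_r, seq_len(n))
  ser_l <- roi_series(series, pair$roi_l, seq_len(n))
  pair$baseline_r <- mean(ser_r[keep, , drop = FALSE])
  pair$baseline_l <- mean(ser_l[keep, , drop = FALSE])
  if (!is.null(pair$baseline_r) && pair$baseline_r <= 0 ||
      !is.null(pair$baseline_l) && pair$baseline_l <= 0) {
    stop("baselines must be strictly positive", call. = FALSE)
  }
  pair$localizer_series <- list(r = ser_r, l = ser_l)
  pair
}

#' Write ROI masks as binary NIfTI volumes
#' @param pair A `roi_pair`.
#' @param path_r,path_l Output paths for the two masks.
#' @export
write_roi_masks <- function(pair, path_r, path_l) {
  m <- array(0L, dim = pair$dims)
  m[pair$roi_r] <- 1L
  RNifti::writeNifti(RNifti::asNifti(m), path_r)
  m <- array(0L, dim = pair$dims)
  m[pair$roi_l] <- 1L
  RNifti::writeNifti(RNifti::asNifti(m), path_l)
  invisible(c(path_r, path_l))
}
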