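#' Specify a synthetic BOLD phantom
#'
#' A phantom is an ellipsoidal "brain" of uniform baseline intensity inside
#' a dark background, with planted voxel sets: two contralateral activation
#' sites (`roi_truth_right` responds during RIGHT attention,
#' `roi_truth_left` during LEFT) and two ipsilateral occipital-pole
#' deactivation sites (`deact_right` responds negatively during LEFT,
#' `deact_left` during RIGHT).  All per-scan modulations are expressed in
#' percent of the baseline intensity.
#'
#' @param grid_shape 3 positive integers (default `c(32, 32, 16)`; the
#'   third axis is the coronal/slice axis with anterior at high indices).
#' @param roi_truth_left,roi_truth_right Linear voxel indices of the
#'   activation sites.
#' @param deact_left,deact_right Linear voxel indices of the deactivation
#'   sites (may be empty).
#' @param effect_pct Peak percent BOLD change of the activations (> 0).
#' @param deact_pct Peak percent change of the deactivations (<= 0).
#' @param drift_pct_per_min Linear drift slope, percent per minute.
#' @param cosine_drift_pct Amplitude of an optional slow cosine drift with
#'   per-voxel random phase (percent); gives the detrender a nonlinear
#'   target.
#' @param noise_sd Per-scan Gaussian noise standard deviation, percent.
#' @param motion_series Optional list of [rigid_transform()]s, one per scan.
#' @param baseline Baseline intensity inside the brain ellipsoid.
#' @param voxel_size_mm Voxel size (mm), default `c(1.848, 1.848, 2)`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 16L),
                         roi_truth_left = NULL, roi_truth_right = NULL,
                         deact_left = integer(0), deact_right = integer(0),
                         effect_pct = 2, deact_pct = -1,
                         drift_pct_per_min = 1, cosine_drift_pct = 0,
                         noise_sd = 3, motion_series = NULL,
                         baseline = 1000,
                         voxel_size_mm = c(1.848, 1.848, 2)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  stop_if_not_finite(c(effect_pct, deact_pct, drift_pct_per_min,
                       cosine_drift_pct, noise_sd, baseline),
                     "phantom parameters")
  if (effect_pct <= 0) stop("effect_pct must be > 0", call. = FALSE)
  if (deact_pct > 0) stop("deact_pct must be <= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  nvox <- prod(grid_shape)
  if (is.null(roi_truth_left) || is.null(roi_truth_right)) {
    blobs <- default_phantom_blobs(grid_shape)
    if (is.null(roi_truth_left)) roi_truth_left <- blobs$truth_left
    if (is.null(roi_truth_right)) roi_truth_right <- blobs$truth_right
    if (length(deact_left) == 0) deact_left <- blobs$deact_left
    if (length(deact_right) == 0) deact_right <- blobs$deact_right
  }
  sets <- list(roi_truth_left, roi_truth_right, deact_left, deact_right)
  all_idx <- unlist(sets)
  if (any(all_idx < 1 | all_idx > nvox)) {
    stop("voxel sets must lie inside the grid", call. = FALSE)
  }
  truth <- c(roi_truth_left, roi_truth_right)
  deact <- c(deact_left, deact_right)
  if (length(intersect(truth, deact)) > 0) {
    stop("truth and deactivation sets must be disjoint", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 roi_truth_left = as.integer(roi_truth_left),
                 roi_truth_right = as.integer(roi_truth_right),
                 deact_left = as.integer(deact_left),
                 deact_right = as.integer(deact_right),
                 effect_pct = effect_pct, deact_pct = deact_pct,
                 drift_pct_per_min = drift_pct_per_min,
                 cosine_drift_pct = cosine_drift_pct,
                 noise_sd = noise_sd, motion_series = motion_series,
                 baseline = baseline, voxel_size_mm = voxel_size_mm),
            class = "phantom_spec")
}

# Ellipsoidal brain support of a grid (semi-axes ~ 0.45 * dim).
brain_support <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  ax <- 0.45 * d
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  ((i - ctr[1]) / ax[1])^2 + ((j - ctr[2]) / ax[2])^2 +
    ((k - ctr[3]) / ax[3])^2 <= 1
}

# Compact rectangular blobs inside the ellipsoid: activations lateral in
# each hemisphere (axis 1 = left-right), deactivations near the posterior
# pole (low indices of the coronal axis 3).
default_phantom_blobs <- function(grid_shape) {
  d <- grid_shape
  supp <- brain_support(d)
  block <- function(xr, yr, zr) {
    g <- expand.grid(i = xr, j = yr, k = zr)
    idx <- g$i + d[1] * (g$j - 1L) + d[1] * d[2] * (g$k - 1L)
    idx[supp[cbind(g$i, g$j, g$k)]]
  }
  cy <- round(d[2] / 2); cz <- max(2L, round(d[3] * 0.45))
  wx <- max(2L, round(d[1] / 6)); wy <- max(2L, round(d[2] / 6))
  wz <- max(2L, round(d[3] / 4))
  xl <- round(d[1] * 0.22); xr <- round(d[1] * 0.78)
  truth_right <- block(xl:(xl + wx - 1L), (cy - wy %/% 2):(cy + wy %/% 2),
                       cz:(cz + wz - 1L))
  truth_left <- block((xr - wx + 1L):xr, (cy - wy %/% 2):(cy + wy %/% 2),
                      cz:(cz + wz - 1L))
  dz <- max(2L, round(d[3] * 0.2)); dw <- max(2L, round(d[1] / 9))
  xdl <- round(d[1] * 0.38); xdr <- round(d[1] * 0.62)
  deact_right <- block(xdl:(xdl + dw - 1L), (cy - 1L):(cy + 1L),
                       dz:(dz + 1L))
  deact_left <- block((xdr - dw + 1L):xdr, (cy - 1L):(cy + 1L),
                      dz:(dz + 1L))
  list(truth_left = truth_left, truth_right = truth_right,
       deact_left = setdiff(deact_left, c(truth_left, truth_right)),
       deact_right = setdiff(deact_right, c(truth_left, truth_right)))
}

#' Simulate a 4D BOLD run from a phantom and a schedule
#'
#' Each voxel's series is `baseline * (1 + drift + response + noise)`, all
#' terms in fractional units: a linear (plus optional cosine) drift, the
#' condition indicators convolved with the canonical double-gamma HRF and
#' scaled to the planted percent effects, and white Gaussian noise.
#' Activation sites respond to their contralateral attention condition;
#' deactivation sites respond negatively to the opposite side.  Optional
#' rigid motion is applied per scan.  Reproducible for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param schedule A [make_schedule()] schedule.
#' @param seed Integer seed for the noise (and drift phases).
#' @return A `volume_series`: 4D array (x, y, z, scan) with attributes
#'   `voxel_size_mm`, `coronal_axis` (3; anterior = high index),
#'   `tr_seconds`.
#' @export
simulate_bold <- function(spec, schedule, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- attr(schedule, "n_scans_total")
  tr <- attr(schedule, "tr_seconds")
  d <- spec$grid_shape
  nvox <- prod(d)
  lab <- schedule_labels(schedule)
  resp_r <- convolve_hrf(as.numeric(lab == "RIGHT"), tr)
  resp_l <- convolve_hrf(as.numeric(lab == "LEFT"), tr)

  base_vol <- ifelse(brain_support(d), spec$baseline, 0)

  with_seed(seed, {
    # fractional per-voxel, per-scan modulation
    minutes <- (seq_len(n) - 1) * tr / 60
    drift <- spec$drift_pct_per_min / 100 * minutes
    pct <- matrix(rep(drift, each = nvox), nrow = nvox)
    if (spec$cosine_drift_pct > 0) {
      phase <- stats::runif(nvox, 0, 2 * pi)
      tmin <- max(minutes[n], 1e-9)
      pct <- pct + (spec$cosine_drift_pct / 100) *
        cos(outer(phase, pi * minutes / tmin, `+`))
    }
    add_resp <- function(pct, vox, amp_pct, resp) {
      if (length(vox) > 0 && amp_pct != 0) {
        pct[vox, ] <- pct[vox, ] +
          (amp_pct / 100) * matrix(rep(resp, each = length(vox)),
                                   nrow = length(vox))
      }
      pct
    }
    pct <- add_resp(pct, spec$roi_truth_right, spec$effect_pct, resp_r)
    pct <- add_resp(pct, spec$roi_truth_left, spec$effect_pct, resp_l)
    pct <- add_resp(pct, spec$deact_right, spec$deact_pct, resp_l)
    pct <- add_resp(pct, spec$deact_left, spec$deact_pct, resp_r)
    if (spec$noise_sd > 0) {
      pct <- pct + (spec$noise_sd / 100) * matrix(stats::rnorm(nvox * n),
                                                  nrow = nvox)
    }
    series <- array(as.vector(base_vol) * (1 + pct), dim = c(d, n))
    if (!is.null(spec$motion_series)) {
      stopifnot(length(spec$motion_series) == n)
      for (t in seq_len(n)) {
        series[, , , t] <- apply_transform(series[, , , t],
                                           spec$motion_series[[t]],
                                           interpolation = "linear")
      }
    }
    volume_series(series, voxel_size_mm = spec$voxel_size_mm,
                  tr_seconds = tr)
  })
}

#' Construct a volume series container
#'
#' @param data 4D array (x, y, z, scan).
#' @param voxel_size_mm Voxel size in mm.
#' @param coronal_axis Array axis of the coronal (slice) direction;
#'   anterior is at high indices.
#' @param tr_seconds Repetition time.
#' @return A `volume_series` object.
#' @export
volume_series <- function(data, voxel_size_mm = c(1.848, 1.848, 2),
                          coronal_axis = 3L, tr_seconds = 1.62) {
  stopifnot(length(dim(data)) == 4)
  stop_if_not_finite(data, "volume intensities")
  structure(data, voxel_size_mm = voxel_size_mm,
            coronal_axis = as.integer(coronal_axis),
            tr_seconds = tr_seconds,
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("volume series: %dx%dx%d grid, %d scans, TR %.2f s\n",
              d[1], d[2], d[3], d[4], attr(x, "tr_seconds")))
  invisible(x)
}

#' Extract one scan of a volume series as a 3D array
#' @param series A `volume_series`.
#' @param t Scan index.
#' @export
get_scan <- function(series, t) {
  array(series[, , , t], dim = dim(series)[1:3])
}

#' Per-voxel time series of a voxel set
#'
#' @param series A `volume_series`.
#' @param voxels Linear voxel indices into one scan's 3D grid.
#' @param scans Scan indices (default all).
#' @return Matrix, scans x voxels.
#' @export
roi_series <- function(series, voxels, scans = NULL) {
  d <- dim(series)
  if (is.null(scans)) scans <- seq_len(d[4])
  flat <- matrix(series, nrow = prod(d[1:3]))
  t(flat[voxels, scans, drop = FALSE])
}

#' Write / read a volume series as 4D NIfTI-1
#' @param series A `volume_series` (or 3D array for masks/t-maps).
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_volume_series <- function(series, path) {
  vs <- attr(series, "voxel_size_mm") %||% c(1, 1, 1)
  tr <- attr(series, "tr_seconds") %||% 1
  img <- RNifti::asNifti(unclass(series),
                         pixdim = c(vs, tr)[seq_len(length(dim(series)))])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  volume_series(array(as.array(img), dim = dim(img)),
                voxel_size_mm = pd[1:3],
                tr_seconds = if (length(pd) >= 4) pd[4] else 1.62)
}
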