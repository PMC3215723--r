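#' Build the localizer design matrix
#'
#' Four columns: a right-attention regressor, a left-attention regressor, a
#' centered linear drift term, and an intercept.  The attention regressors
#' are the condition indicators, by default convolved with the canonical
#' double-gamma HRF (a raw-boxcar mode is available).
#'
#' @param schedule A [make_schedule()] schedule.
#' @param hrf Convolve the attention indicators with the HRF (default TRUE).
#' @return Numeric matrix (scans x 4) with columns
#'   `right`, `left`, `drift`, `intercept`.
#' @export
build_design <- function(schedule, hrf = TRUE) {
  lab <- schedule_labels(schedule)
  n <- length(lab)
  tr <- attr(schedule, "tr_seconds")
  right <- as.numeric(lab == "RIGHT")
  left <- as.numeric(lab == "LEFT")
  if (hrf) {
    right <- convolve_hrf(right, tr)
    left <- convolve_hrf(left, tr)
  }
  drift <- seq_len(n) / n - (n + 1) / (2 * n)
  cbind(right = right, left = left, drift = drift, intercept = 1)
}

#' Default differential contrasts
#'
#' `right - left` and `left - right` on the two attention columns of the
#' default design.
#' @export
contrast_right_minus_left <- function() c(1, -1, 0, 0)
#' @rdname contrast_right_minus_left
#' @export
contrast_left_minus_right <- function() c(-1, 1, 0, 0)

#' Initialize incremental GLM sufficient statistics
#'
#' The mass-univariate GLM is accumulated one scan at a time through the
#' sufficient statistics X'X (p x p), X'y (p x voxels) and y'y (voxels),
#' so per-scan cost does not grow with the number of scans and, after n
#' updates, the state equals the batch statistics of those n scans exactly.
#'
#' @param n_voxels Number of voxels.
#' @param n_regressors Number of design columns (default 4).
#' @return A `glm_state` object.
#' @export
glm_init <- function(n_voxels, n_regressors = 4L) {
  structure(list(xtx = matrix(0, n_regressors, n_regressors),
                 xty = matrix(0, n_regressors, n_voxels),
                 yty = numeric(n_voxels),
                 n_scans = 0L),
            class = "glm_state")
}

#' Add one scan to the incremental GLM
#'
#' @param state A [glm_init()] state.
#' @param row Design row (length-p numeric vector) for this scan.
#' @param volume 3D array or numeric vector of voxel intensities.
#' @return Updated `glm_state`.
#' @export
glm_update <- function(state, row, volume) {
  y <- as.numeric(volume)
  if (length(y) != ncol(state$xty)) {
    stop("volume shape does not match the GLM state", call. = FALSE)
  }
  if (length(row) != nrow(state$xty)) {
    stop("design row length does not match the model", call. = FALSE)
  }
  state$xtx <- state$xtx + tcrossprod(row)
  state$xty <- state$xty + outer(as.numeric(row), y)
  state$yty <- state$yty + y^2
  state$n_scans <- state$n_scans + 1L
  state
}

# Shared t computation from sufficient statistics.  Zero-variance voxels
# get t = 0; zero-residual voxels with a nonzero contrast estimate get a
# signed large finite cap so the ROI ranking stays total.
t_from_stats <- function(xtx, xty, yty, n, contrast, t_cap = 1e6) {
  p <- nrow(xtx)
  qrx <- qr(xtx)
  rk <- qrx$rank
  if (rk < p) stop("design is rank-deficient", call. = FALSE)
  if (n <= rk) stop("need more scans than regressors", call. = FALSE)
  beta <- solve(xtx, xty)
  rss <- pmax(yty - colSums(beta * xty), 0)
  dof <- n - rk
  cb <- as.numeric(crossprod(contrast, beta))
  cvar <- as.numeric(crossprod(contrast, solve(xtx, contrast)))
  sigma2 <- rss / dof
  scale_ref <- mean(yty) / max(n, 1)
  tiny <- 1e-12 * max(scale_ref, 1e-300)
  denom <- sqrt(sigma2 * cvar)
  t <- ifelse(denom > sqrt(tiny * cvar),
              cb / denom,
              ifelse(abs(cb) > sqrt(tiny) * 1e-3, sign(cb) * t_cap, 0))
  if (all(contrast == 0)) t <- rep(0, length(t))
  list(t = t, beta = beta, rss = rss, dof = dof)
}

#' Voxelwise t-map from the incremental GLM state
#'
#' Computes `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` with `s2 = RSS / (n - rank)`
#' per voxel.  Zero-variance voxels and the all-zero contrast yield t = 0;
#' zero-residual voxels with a nonzero effect are capped at a large finite
#' value, keeping the ranking used for ROI selection total.
#'
#' @param state A `glm_state` after at least rank+1 updates.
#' @param contrast Contrast weight vector (default right - left).
#' @param dims Optional 3D dims to reshape the map.
#' @return A `t_map`: numeric vector (or 3D array) with attributes
#'   `contrast` and `dof`.
#' @export
glm_tmap <- function(state, contrast = contrast_right_minus_left(),
                     dims = NULL) {
  res <- t_from_stats(state$xtx, state$xty, state$yty, state$n_scans,
                      contrast)
  t <- res$t
  if (!is.null(dims)) t <- array(t, dim = dims)
  structure(t, contrast = contrast, dof = res$dof, class = "t_map")
}

#' Batch ("full data") GLM reference fit
#'
#' Fits the stacked design by QR decomposition and returns the same t-map
#' as [glm_tmap()] computed non-incrementally.  This is the reference path
#' used for incremental/batch equivalence checks and the Dice overlap
#' comparison of the two ROI routes.
#'
#' @param design Full design matrix (scans x p).
#' @param series Matrix scans x voxels (or a `volume_series`).
#' @param contrast Contrast weight vector.
#' @param dims Optional 3D dims to reshape the map.
#' @return A `t_map`.
#' @export
glm_batch_fit <- function(design, series,
                          contrast = contrast_right_minus_left(),
                          dims = NULL) {
  if (inherits(series, "volume_series")) {
    d <- dim(series)
    if (is.null(dims)) dims <- d[1:3]
    series <- t(matrix(series, nrow = prod(d[1:3])))
  }
  series <- as.matrix(series)
  stopifnot(nrow(series) == nrow(design))
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    stop("design is rank-deficient", call. = FALSE)
  }
  beta <- qr.coef(qrx, series)
  resid <- series - design %*% beta
  rss <- colSums(resid^2)
  dof <- nrow(design) - qrx$rank
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)
  cvar <- as.numeric(t(contrast) %*% xtx_inv %*% contrast)
  cb <- as.numeric(crossprod(contrast, beta))
  sigma2 <- rss / dof
  scale_ref <- mean(colSums(series^2)) / max(nrow(series), 1)
  tiny <- 1e-12 * max(scale_ref, 1e-300)
  denom <- sqrt(sigma2 * cvar)
  t <- ifelse(denom > sqrt(tiny * cvar),
              cb / denom,
              ifelse(abs(cb) > sqrt(tiny) * 1e-3, sign(cb) * 1e6, 0))
  if (all(contrast == 0)) t <- rep(0, length(t))
  if (!is.null(dims)) t <- array(t, dim = dims)
  structure(t, contrast = contrast, dof = dof, class = "t_map")
}

#' Run the incremental GLM over a volume series
#'
#' Convenience driver: one [glm_update()] per scan.
#'
#' @param series A `volume_series` (or scans x voxels matrix).
#' @param design Design matrix with one row per scan.
#' @param scans Scan indices to stream (default all rows of `design`).
#' @return Final `glm_state`.
#' @export
glm_stream <- function(series, design, scans = NULL) {
  if (inherits(series, "volume_series")) {
    d <- dim(series)
    series <- t(matrix(series, nrow = prod(d[1:3])))
  }
  if (is.null(scans)) scans <- seq_len(nrow(design))
  state <- glm_init(ncol(series), ncol(design))
  for (t in scans) {
    state <- glm_update(state, design[t, ], series[t, ])
  }
  state
}

#' Write a t-map as a 3D NIfTI volume
#' @param tmap A `t_map` with 3D dims.
#' @param path Output path.
#' @param voxel_size_mm Voxel size in mm.
#' @export
write_tmap <- function(tmap, path, voxel_size_mm = c(1.848, 1.848, 2)) {
  stopifnot(length(dim(tmap)) == 3)
  img <- RNifti::asNifti(array(as.numeric(tmap), dim = dim(tmap)),
                         pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
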