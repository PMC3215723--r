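ellipsoid_volume <- function(d = c(20L, 20L, 12L), cavity = FALSE) {
  ctr <- (d + 1) / 2
  ax <- 0.4 * d
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  r2 <- ((i - ctr[1]) / ax[1])^2 + ((j - ctr[2]) / ax[2])^2 +
    ((k - ctr[3]) / ax[3])^2
  vol <- ifelse(r2 <= 1, 1000, 0)
  if (cavity) vol[r2 <= 0.05] <- 0
  vol
}

test_that("the brain mask recovers an ellipsoid minus two anterior slices", {
  d <- c(20L, 20L, 12L)
  vol <- ellipsoid_volume(d)
  # half-intensity threshold: the unbiased boundary for a binary object
  mask <- make_mask(vol, blur_sigma = 0.8, threshold = 500)
  truth <- vol > 0
  truth[, , 11:12] <- FALSE                  # anterior = high slice indices
  expect_true(all(!mask[, , 11:12]))
  expect_gt(dice(which(mask), which(truth)), 0.95)
  # voxels deep inside / far outside are classified exactly
  ctr <- (d + 1) / 2
  expect_true(mask[ctr[1], ctr[2], ctr[3]])
  expect_false(mask[1, 1, 1])
})

test_that("enclosed cavities are filled and empty volumes rejected", {
  vol <- ellipsoid_volume(cavity = TRUE)
  d <- dim(vol)
  ctr <- round((d + 1) / 2)
  expect_equal(vol[ctr[1], ctr[2], ctr[3]], 0)   # cavity is dark
  mask <- make_mask(vol, blur_sigma = 0.5)
  expect_true(mask[ctr[1], ctr[2], ctr[3]])      # but inside the mask
  expect_error(make_mask(array(0, c(8, 8, 8))), "empty")
})

test_that("top-k ROI selection matches a sorting oracle and keeps one blob", {
  d <- c(16L, 16L, 10L)
  set.seed(21)
  tmap <- array(stats::rnorm(prod(d), sd = 0.1), dim = d)
  blob <- as.vector(slice.index(tmap, 1) %in% 4:13 &
                      slice.index(tmap, 2) %in% 4:11 &
                      slice.index(tmap, 3) %in% 3:9)   # 560 voxels
  tmap[blob] <- 10 + stats::rnorm(sum(blob), sd = 0.1)
  mask <- array(TRUE, d)
  pair <- select_rois(tmap, tmap, mask, k = 500, min_cluster = 5)
  # oracle: sort on t with index tie-break
  tv <- as.numeric(tmap)
  expected_top <- order(-tv, seq_along(tv))[1:500]
  expect_setequal(pair$roi_r, expected_top)
  expect_true(all(pair$roi_r %in% which(blob)))
  expect_equal(pair$threshold_t_r, sort(tv, decreasing = TRUE)[500])
  # all 500 form one 6-connected cluster
  expect_equal(max(boldbci:::label_components6(pair$roi_r, d)), 1L)
})

test_that("clusters below the minimum size are removed", {
  d <- c(12L, 12L, 8L)
  tmap <- array(0, dim = d)
  # ten disjoint 4-voxel blobs (2x2x1), spaced apart
  origins <- expand.grid(i = c(2, 6, 10), j = c(2, 6, 10), k = c(2, 6))[1:10, ]
  for (r in seq_len(10)) {
    tmap[origins$i[r] + 0:1, origins$j[r] + 0:1, origins$k[r]] <- 5
  }
  mask <- array(TRUE, d)
  expect_warning(expect_warning(
    pair <- select_rois(tmap, tmap, mask, k = 40, min_cluster = 5),
    "smaller than the minimum"))   # one warning per side
  expect_length(pair$roi_r, 0)
  # with the filter disabled the selection is exactly the top-k set
  pair1 <- select_rois(tmap, tmap, mask, k = 40, min_cluster = 1)
  tv <- as.numeric(tmap)
  expect_setequal(pair1$roi_r, order(-tv, seq_along(tv))[1:40])
})

test_that("selection refuses when the mask has fewer voxels than k", {
  d <- c(6L, 6L, 4L)
  mask <- array(FALSE, d); mask[1:3, 1, 1] <- TRUE
  expect_error(select_rois(array(1, d), array(1, d), mask, k = 10),
               "smaller than k")
})

test_that("baselines average CENTER scans with post-attention exclusion", {
  # hand-enumerated schedule: CENTER(4) LEFT(4) CENTER(4) RIGHT(4) CENTER(4)
  sched <- structure(data.frame(
    condition = c("CENTER", "LEFT", "CENTER", "RIGHT", "CENTER"),
    onset_scan = c(1L, 5L, 9L, 13L, 17L),
    length_scans = 4L, stringsAsFactors = FALSE),
    tr_seconds = 1.62, n_scans_total = 20L, onset_offset_scans = 0L,
    class = c("bci_schedule", "data.frame"))
  d <- c(4L, 4L, 4L)
  vals <- rep(100, 20)
  # first 3 scans of post-attention CENTER trials carry a poison value
  vals[c(9, 10, 11, 17, 18, 19)] <- 999
  ser <- volume_series(array(rep(vals, each = prod(d)), dim = c(d, 20)))
  pair <- structure(list(roi_r = 1:3, roi_l = 10:12, dims = d),
                    class = "roi_pair")
  pair <- compute_baselines(ser, sched, pair, n_exclude = 3)
  expect_equal(pair$baseline_r, 100)
  expect_equal(pair$baseline_l, 100)
  expect_equal(dim(pair$localizer_series$r), c(20L, 3L))
  # the initial CENTER trial (not preceded by attention) keeps all scans:
  # poisoning its start must change the baseline
  vals2 <- vals; vals2[1:3] <- 50
  ser2 <- volume_series(array(rep(vals2, each = prod(d)), dim = c(d, 20)))
  pair2 <- compute_baselines(ser2, sched,
                             structure(list(roi_r = 1:3, roi_l = 10:12,
                                            dims = d), class = "roi_pair"),
                             n_exclude = 3)
  expect_lt(pair2$baseline_r, 100)
  # constant series: baseline equals the constant
  ser3 <- volume_series(array(100, dim = c(d, 20)))
  pair3 <- compute_baselines(ser3, sched,
                             structure(list(roi_r = 1:3, roi_l = 10:12,
                                            dims = d), class = "roi_pair"))
  expect_equal(pair3$baseline_r, 100)
})

test_that("planted activation sites are recovered by the localizer chain", {
  spec <- phantom_spec(grid_shape = c(24L, 24L, 12L), noise_sd = 2)
  sch <- make_schedule(6, 8, seed = 31, extra_initial_center = TRUE)
  ser <- simulate_bold(spec, sch, seed = 32)
  X <- build_design(sch)
  dims <- dim(ser)[1:3]
  flat <- t(matrix(ser, nrow = prod(dims)))
  st <- glm_stream(flat, X)
  tr <- glm_tmap(st, contrast_right_minus_left(), dims)
  tl <- glm_tmap(st, contrast_left_minus_right(), dims)
  mask <- make_mask(array(rowMeans(matrix(ser, nrow = prod(dims))), dims))
  pair <- select_rois(tr, tl, mask, k = 200, min_cluster = 5)
  rec_r <- mean(spec$roi_truth_right %in% pair$roi_r)
  rec_l <- mean(spec$roi_truth_left %in% pair$roi_l)
  expect_gte(rec_r, 0.8)
  expect_gte(rec_l, 0.8)
  jac <- length(intersect(pair$roi_r, spec$roi_truth_right)) /
    length(union(pair$roi_r, spec$roi_truth_right))
  expect_gte(jac, 0.3)
})
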