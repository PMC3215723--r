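test_that("smoothness-priors detrending removes constants and lines exactly", {
  expect_lt(max(abs(detrend_sp(rep(5, 50), 500))), 1e-10)
  ramp <- seq(0, 100, length.out = 80)
  expect_lt(max(abs(detrend_sp(ramp, 500))), 0.01 * diff(range(ramp)))
  # lambda = 0: the trend equals the data
  expect_equal(detrend_sp(stats::rnorm(30), 0), rep(0, 30))
  # matrix input detrends each column like the vector path
  z <- matrix(stats::rnorm(120), 40, 3)
  dm <- detrend_sp(z, 500)
  expect_equal(dm[, 2], detrend_sp(z[, 2], 500))
  expect_error(detrend_sp(1:10, -1), "lambda")
  expect_error(detrend_sp(1:2, 10), "length")
})

test_that("detrending matches a dense direct linear solve", {
  set.seed(40)
  n <- 60
  z <- cumsum(stats::rnorm(n)) + 0.1 * seq_len(n)
  lambda <- 300
  D2 <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D2[i, i:(i + 2)] <- c(1, -2, 1)
  trend <- solve(diag(n) + lambda^2 * crossprod(D2), z)
  expect_equal(detrend_sp(z, lambda), z - trend, tolerance = 1e-8)
})

test_that("the control signal implements the differential percent change", {
  expect_equal(control_signal(100, 200, 100, 200), 0)
  expect_equal(control_signal(102, 200, 100, 200), 2)
  expect_equal(control_signal(101, 99, 100, 100), 2)   # effects add
  expect_error(control_signal(1, 1, 0, 1), "positive")
  # SD normalization divides each percent term by its own spread
  expect_equal(control_signal(102, 100, 100, 100, normalize_sd = TRUE,
                              sd_r = 2, sd_l = 1), 1)
  expect_error(control_signal(1, 1, 1, 1, normalize_sd = TRUE), "sd_r")
})

test_that("control-signal values map to the expected feedback states", {
  th <- threshold_set(c(1.5, 2.5, 4), c(-1.5, -2.5, -4))
  r <- classify_cs(3.0, "ATTENTION", "RIGHT", th)
  expect_equal(r$state, "STRONG_R")
  expect_equal(r$color, "green_dark")
  r <- classify_cs(0, "CENTER", thresholds = th)
  expect_equal(r$state, "OFF")
  expect_equal(r$color, "green_light")
  r <- classify_cs(-2.0, "ATTENTION", "RIGHT", th)
  expect_equal(r$state, "WEAK_L")
  expect_match(r$color, "^red")
  r <- classify_cs(2.0, "ATTENTION", "RIGHT", th)
  expect_equal(r$state, "WEAK_R")
  expect_equal(r$color, "green_light")
  r <- classify_cs(3.0, "CENTER", thresholds = th)
  expect_equal(r$color, "red_dark")
})

test_that("threshold sets enforce their ordering", {
  expect_error(threshold_set(c(2, 1, 4), c(-1, -2, -3)), "ascending")
  expect_error(threshold_set(c(1, 2, 3), c(-2, -1, -3)), "descending")
  th <- threshold_set()
  expect_equal(th$pos, c(1.5, 2.5, 4))
})

test_that("adaptive thresholds match an exhaustive sweep oracle", {
  sch <- make_schedule(8, 8, seed = 50, extra_initial_center = TRUE)
  labels <- schedule_labels(sch)
  for (seed in 1:25) {
    cs <- synthetic_cs_trace(sch, amplitude = 2, noise_sd = 0.6, seed = seed)
    th <- adaptive_thresholds(cs, sch, target_fpr = 0.2, shift_trs = 3)
    expect_equal(th$pos[1],
                 brute_force_threshold(cs, labels, 0.2, 3, "R"))
    expect_equal(th$neg[1],
                 brute_force_threshold(cs, labels, 0.2, 3, "L"))
    # the training FPR bound holds by construction
    lab <- boldbci:::shift_labels(labels, 3)
    keep <- !is.na(lab)
    expect_lte(mean(cs[keep][lab[keep] %in% c("LEFT", "CENTER")] > th$pos[1]),
               0.2)
    expect_lte(mean(cs[keep][lab[keep] %in% c("RIGHT", "CENTER")] < th$neg[1]),
               0.2)
    expect_equal(attr(th, "fpr_r"),
                 mean(cs[keep][lab[keep] %in% c("LEFT", "CENTER")] >
                        th$pos[1]))
  }
})

test_that("adaptive threshold degenerate bounds behave", {
  # zero CS on all non-target scans, positive on target scans
  lab <- c(rep("CENTER", 4), rep("RIGHT", 4), rep("CENTER", 4),
           rep("LEFT", 4), rep("CENTER", 4))
  cs <- ifelse(lab == "RIGHT", 3, ifelse(lab == "LEFT", -3, 0))
  th <- adaptive_thresholds(cs, lab, target_fpr = 0.2, shift_trs = 0)
  expect_equal(th$pos[1], 0)          # smallest value with zero FPR above it
  expect_equal(attr(th, "fpr_r"), 0)
  # target_fpr = 1 admits everything: the minimum observed value
  th1 <- adaptive_thresholds(cs, lab, target_fpr = 1, shift_trs = 0)
  expect_equal(th1$pos[1], min(cs))
})

test_that("raising the first threshold never increases the training FPR", {
  sch <- make_schedule(8, 8, seed = 60, extra_initial_center = TRUE)
  labels <- schedule_labels(sch)
  cs <- synthetic_cs_trace(sch, seed = 3)
  lab <- boldbci:::shift_labels(labels, 3)
  keep <- !is.na(lab)
  neg <- cs[keep][lab[keep] %in% c("LEFT", "CENTER")]
  fprs <- vapply(sort(unique(cs)), function(th) mean(neg > th), numeric(1))
  expect_true(all(diff(fprs) <= 0))
})

test_that("the feedback loop reproduces a clean planted response", {
  spec <- tiny_phantom(noise_sd = 0, drift = 1, effect = 2)
  loc <- make_schedule(3, 6, seed = 70, extra_initial_center = TRUE)
  n_loc <- attr(loc, "n_scans_total")
  fb <- make_schedule(2, 8, seed = 71, onset_offset_scans = n_loc)
  full <- structure(rbind(as.data.frame(loc), as.data.frame(fb)),
                    tr_seconds = 1.62,
                    n_scans_total = n_loc + attr(fb, "n_scans_total"),
                    onset_offset_scans = 0L,
                    class = c("bci_schedule", "data.frame"))
  ser <- simulate_bold(spec, full, seed = 72)
  pair <- structure(list(roi_r = spec$roi_truth_right,
                         roi_l = spec$roi_truth_left,
                         dims = spec$grid_shape), class = "roi_pair")
  loc_ser <- volume_series(array(unclass(ser)[, , , seq_len(n_loc)],
                                 dim = c(spec$grid_shape, n_loc)))
  pair <- compute_baselines(loc_ser, loc, pair)
  fbs <- roi_series(ser, c(pair$roi_r, pair$roi_l),
                    n_loc + seq_len(attr(fb, "n_scans_total")))
  trace <- run_feedback(fbs, pair, fb, thresholds = threshold_set(),
                        lambda = 500, shift_trs = 3,
                        context_labels = schedule_labels(loc))
  expect_equal(nrow(trace), attr(fb, "n_scans_total"))
  expect_false(anyNA(trace$cs))
  # control signal is positive late in RIGHT trials, negative in LEFT
  lab <- boldbci:::shift_labels(c(schedule_labels(loc), schedule_labels(fb)),
                                3)[n_loc + seq_len(nrow(trace))]
  expect_gt(mean(trace$cs[lab == "RIGHT"]), 1)
  expect_lt(mean(trace$cs[lab == "LEFT"]), -1)
  expect_lt(abs(mean(trace$cs[lab == "CENTER"])), 1)
  # states are consistent with the thresholds at every scan
  th <- threshold_set()
  for (i in seq_len(nrow(trace))) {
    ctx <- if (trace$condition[i] == "CENTER") "CENTER" else "ATTENTION"
    side <- if (ctx == "ATTENTION") trace$condition[i]
    expect_equal(trace$state[i],
                 classify_cs(trace$cs[i], ctx, side, th)$state)
  }
})
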