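test_that("band power isolates in-band and out-of-band sinusoids", {
  fs <- 512
  t <- seq_len(5 * fs) / fs
  mk_trials <- function(freq) {
    x <- matrix(0, 4, length(t))
    x[1, ] <- sin(2 * pi * freq * t)
    x
  }
  # 80 Hz tone: nearly all power inside 65-95 Hz
  p80 <- bandpower(mk_trials(80), fs, band = c(65, 95))
  total80 <- bandpower(mk_trials(80), fs, band = c(1, fs / 2))
  expect_gte(p80[1] / total80[1], 0.95)
  # 30 Hz tone: almost nothing in the gamma band
  p30 <- bandpower(mk_trials(30), fs, band = c(65, 95))
  total30 <- bandpower(mk_trials(30), fs, band = c(1, fs / 2))
  expect_lte(p30[1] / total30[1], 0.05)
  # zero signal has zero power; short trials are rejected
  expect_equal(unname(bandpower(matrix(0, 2, 4 * fs), fs)), c(0, 0))
  expect_error(bandpower(matrix(0, 2, fs), fs, window_seconds = 4),
               "shorter")
})

test_that("common-average referencing removes a shared component", {
  fs <- 512
  t <- seq_len(4 * fs) / fs
  shared <- sin(2 * pi * 80 * t)
  x <- matrix(shared, nrow = 8, ncol = length(t), byrow = TRUE)
  p <- bandpower(x, fs)
  expect_lt(max(p), 1e-20)
  p_nocar <- bandpower(x, fs, car = FALSE)
  expect_gt(min(p_nocar), 0.1)
})

test_that("channel selection follows the margin and amplitude rules", {
  # build features with exact class means via large samples
  build <- function(means, n = 600, seed = 1) {
    labs <- rep(ATTN <- c("RIGHT", "LEFT", "CENTER"), each = n)
    boldbci:::with_seed(seed, {
      f <- matrix(stats::rnorm(3 * n * nrow(means), sd = 0.05),
                  ncol = nrow(means))
      for (ci in seq_len(3)) {
        f[labs == ATTN[ci], ] <-
          sweep(f[labs == ATTN[ci], , drop = FALSE], 2, means[, ci], `+`)
      }
      list(f = f, labs = labs)
    })
  }
  # channel 1: (R, L, C) means (2, 0, 0); channel 2: (1, -1, 0);
  # channel 3: equal means
  means <- rbind(c(2, 0, 0), c(1, -1, 0), c(0.5, 0.5, 0.5))
  d <- build(means)
  sets <- select_channels(d$f, d$labs, margin_threshold = 0.8)
  expect_equal(sets$sets$RIGHT$channel, c(1L, 2L))
  expect_equal(sets$sets$RIGHT$sign, c(1, 1))
  expect_equal(sets$sets$LEFT$channel, 2L)    # deactivation for LEFT
  expect_equal(sets$sets$LEFT$sign, -1)
  expect_equal(nrow(sets$sets$CENTER), 0L)
  # equal-mean channels are never selected at any positive margin
  expect_false(3L %in% unlist(lapply(sets$sets, `[[`, "channel")))
  # margin larger than every gap empties the selection
  sets_hi <- select_channels(d$f, d$labs, margin_threshold = 10)
  expect_equal(sum(vapply(sets_hi$sets, nrow, integer(1))), 0L)
})

test_that("channel selection is monotone in the margin", {
  es <- simulate_ecog(seed = 90)
  st <- boldbci:::ecog_norm_stats(es$features, seq_len(79))
  fn <- boldbci:::ecog_apply_norm(es$features, st)
  prev <- NULL
  for (m in seq(0, 2, by = 0.25)) {
    sets <- select_channels(fn, es$labels, m)
    if (!is.null(prev)) {
      for (d in names(sets$sets)) {
        expect_true(all(sets$sets[[d]]$channel %in% prev[[d]]$channel))
      }
    }
    prev <- sets$sets
  }
})

test_that("trial classification scores sign-adjusted set means", {
  sets <- structure(list(sets = list(
    RIGHT = data.frame(channel = 1L, sign = 1),
    LEFT = data.frame(channel = 2L, sign = -1),
    CENTER = data.frame(channel = 3L, sign = 1)),
    margin_threshold = 0), class = "channel_sets")
  expect_equal(classify_trial(c(3, 0, 0), sets), "RIGHT")
  # strongly negative value on a deactivation channel supports its class
  expect_equal(classify_trial(c(0, -4, 1), sets), "LEFT")
  # exhaustive score check on a 3-channel case
  x <- c(1.2, 0.4, 0.9)
  scores <- c(RIGHT = x[1], LEFT = -x[2], CENTER = x[3])
  expect_equal(classify_trial(x, sets), names(which.max(scores)))
  # ties resolve CENTER > RIGHT > LEFT
  sets_tie <- structure(list(sets = list(
    RIGHT = data.frame(channel = 1L, sign = 1),
    LEFT = data.frame(channel = 1L, sign = 1),
    CENTER = data.frame(channel = 1L, sign = 1)),
    margin_threshold = 0), class = "channel_sets")
  expect_equal(classify_trial(c(2, 0, 0), sets_tie), "CENTER")
  # all sets empty: the training-majority class is returned
  empty <- structure(list(sets = list(
    RIGHT = data.frame(channel = integer(0), sign = numeric(0)),
    LEFT = data.frame(channel = integer(0), sign = numeric(0)),
    CENTER = data.frame(channel = integer(0), sign = numeric(0))),
    margin_threshold = 0), class = "channel_sets")
  expect_equal(classify_trial(c(1, 2, 3), empty, majority_class = "LEFT"),
               "LEFT")
})

test_that("the vectorized training classifier agrees with classify_trial", {
  es <- simulate_ecog(seed = 91)
  st <- boldbci:::ecog_norm_stats(es$features, seq_len(79))
  fn <- boldbci:::ecog_apply_norm(es$features, st)
  sets <- select_channels(fn, es$labels, 0.3)
  pred_m <- boldbci:::classify_matrix(fn, sets, "CENTER")
  pred_s <- vapply(seq_len(nrow(fn)),
                   function(i) classify_trial(fn[i, ], sets, "CENTER"),
                   character(1))
  expect_equal(pred_m, pred_s)
})

test_that("leave-one-out normalization never uses the held-out trial", {
  es <- simulate_ecog(n_channels = 8,
                      class_channel_map = list(
                        RIGHT = list(channels = 1:2, shifts = 1),
                        LEFT = list(channels = 3:4, shifts = 1),
                        CENTER = list(channels = 5:6, shifts = 1)),
                      n_per_class = c(LEFT = 4, RIGHT = 4, CENTER = 6),
                      seed = 92)
  res <- ecog_loocv(es, margin_grid = c(0.2, 0.5))
  for (i in seq_len(nrow(es$features))) {
    train <- setdiff(seq_len(nrow(es$features)), i)
    expect_equal(res$fold_details[[i]]$mean,
                 colMeans(es$features[train, ]))
    expect_equal(res$fold_details[[i]]$sd,
                 apply(es$features[train, ], 2, stats::sd))
  }
})

test_that("a cleanly separable trial set is classified perfectly", {
  map <- list(RIGHT = list(channels = 1:3, shifts = 6),
              LEFT = list(channels = 5:7, shifts = 6),
              CENTER = list(channels = 9:11, shifts = 6))
  es <- simulate_ecog(n_channels = 12, class_channel_map = map,
                      n_per_class = c(LEFT = 6, RIGHT = 6, CENTER = 10),
                      seed = 93)
  res <- ecog_loocv(es)
  expect_equal(unname(res$tpr), c(1, 1, 1))
  expect_equal(sum(res$confusion), 22)
  expect_equal(unname(rowSums(res$confusion)), c(6, 6, 10))
})

test_that("with moderate signal the high-prior CENTER class is easiest", {
  grid <- seq(0, 1.5, length.out = 15)
  tprs <- t(vapply(1:6, function(s) {
    map <- list(RIGHT = list(channels = 1:4, shifts = 0.85),
                LEFT = list(channels = 9:12, shifts = 0.85),
                CENTER = list(channels = 17:20, shifts = 0.85))
    ecog_loocv(simulate_ecog(class_channel_map = map, seed = s),
               margin_grid = grid)$tpr
  }, numeric(3)))
  expect_gt(mean(tprs[, "CENTER"]),
            mean(c(tprs[, "LEFT"], tprs[, "RIGHT"])))
})

test_that("degenerate label sets are rejected", {
  expect_error(ecog_loocv(matrix(stats::rnorm(40), 10, 4),
                          labels = rep("LEFT", 10)),
               "2 trials per class")
})
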