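#' High-gamma band power of one ECoG trial
#'
#' Re-references the trial to the common average across channels, then
#' estimates each channel's mean spectral power in the 65-95 Hz band over
#' the first `window_seconds` seconds with a Welch periodogram (1 s
#' segments, 50% overlap, Hann window).
#'
#' @param raw_trial channels x samples numeric matrix.
#' @param fs Sampling rate in Hz (default 512).
#' @param band Frequency band in Hz (default `c(65, 95)`).
#' @param window_seconds Analysis window from trial start (default 4).
#' @param segment_seconds Welch segment length (default 1).
#' @param overlap Segment overlap fraction (default 0.5).
#' @param car Apply the common average reference first (default TRUE).
#' @return Numeric vector of per-channel band power.
#' @export
bandpower <- function(raw_trial, fs = 512, band = c(65, 95),
                      window_seconds = 4, segment_seconds = 1,
                      overlap = 0.5, car = TRUE) {
  raw_trial <- as.matrix(raw_trial)
  n_need <- round(window_seconds * fs)
  if (ncol(raw_trial) < n_need) {
    stop("trial shorter than the analysis window", call. = FALSE)
  }
  x <- raw_trial[, seq_len(n_need), drop = FALSE]
  if (car) x <- sweep(x, 2, colMeans(x))
  apply(x, 1, function(ch) welch_band_power(ch, fs, band,
                                            segment_seconds, overlap))
}

# Welch PSD estimate; returns mean power in `band` (sum of the mean
# periodogram over the band bins).
welch_band_power <- function(x, fs, band, segment_seconds, overlap) {
  nseg <- round(segment_seconds * fs)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  freqs <- (seq_len(nseg) - 1L) * fs / nseg
  half <- seq_len(floor(nseg / 2) + 1L)
  psd <- rep(0, length(half))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    X <- stats::fft(seg)
    psd <- psd + Mod(X[half])^2 / (u * fs)
  }
  psd <- psd / length(starts)
  inband <- freqs[half] >= band[1] & freqs[half] <= band[2]
  sum(psd[inband]) * fs / nseg
}

#' Build an ECoG trial set from band-power features
#'
#' @param features trials x channels numeric matrix of band-power values.
#' @param labels Per-trial condition in `LEFT`, `RIGHT`, `CENTER`.
#' @param fs_hz Sampling rate metadata (default 512).
#' @return An `ecog_trial_set`.
#' @export
ecog_trial_set <- function(features, labels, fs_hz = 512) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% ATTN_CONDITIONS))
  structure(list(features = features, labels = labels, fs_hz = fs_hz,
                 n_channels = ncol(features)),
            class = "ecog_trial_set")
}

#' Simulate an ECoG band-power trial set
#'
#' Channel features are unit-variance Gaussians whose means shift by a
#' known amount for the classes listed in `class_channel_map`; channels
#' outside all subsets have identical means across classes.  The default
#' composition matches the paradigm's localizer (20 LEFT, 20 RIGHT,
#' 39 CENTER) on a 64-channel grid with +-1 shifts on small disjoint
#' channel subsets (including deactivation channels).
#'
#' @param n_channels Number of channels (default 64).
#' @param class_channel_map Named list (per class) of `list(channels,
#'   shifts)`; `shifts` recycles over `channels`.
#' @param n_per_class Named trial counts (default `c(LEFT = 20, RIGHT =
#'   20, CENTER = 39)`).
#' @param seed Integer seed.
#' @return An [ecog_trial_set()].
#' @export
simulate_ecog <- function(n_channels = 64L,
                          class_channel_map = default_ecog_map(),
                          n_per_class = c(LEFT = 20L, RIGHT = 20L,
                                          CENTER = 39L),
                          seed = NULL) {
  if (sum(n_per_class) < 1) stop("empty trial composition", call. = FALSE)
  for (cls in names(class_channel_map)) {
    ch <- class_channel_map[[cls]]$channels
    if (length(ch) > 0 && (min(ch) < 1 || max(ch) > n_channels)) {
      stop("channel subsets must lie within the channel range", call. = FALSE)
    }
  }
  labels <- rep(names(n_per_class), n_per_class)
  n <- length(labels)
  with_seed(seed, {
    labels <- sample(labels)
    feats <- matrix(stats::rnorm(n * n_channels), nrow = n)
    for (cls in names(class_channel_map)) {
      m <- class_channel_map[[cls]]
      if (length(m$channels) == 0) next
      rows <- which(labels == cls)
      shifts <- rep_len(m$shifts, length(m$channels))
      feats[rows, m$channels] <- feats[rows, m$channels] +
        matrix(rep(shifts, each = length(rows)), nrow = length(rows))
    }
    ecog_trial_set(feats, labels)
  })
}

#' @rdname simulate_ecog
#' @export
default_ecog_map <- function() {
  list(RIGHT = list(channels = c(1:4, 5:6), shifts = c(rep(1, 4), rep(-1, 2))),
       LEFT = list(channels = c(9:12, 13:14), shifts = c(rep(1, 4), rep(-1, 2))),
       CENTER = list(channels = 17:20, shifts = 1))
}

# Normalization statistics from training rows only.
ecog_norm_stats <- function(features, train_rows) {
  tr <- features[train_rows, , drop = FALSE]
  mu <- colMeans(tr)
  sd <- apply(tr, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}

ecog_apply_norm <- function(features, stats) {
  sweep(sweep(features, 2, stats$mean), 2, stats$sd, `/`)
}

#' Margin-based channel selection
#'
#' For each attention direction, a channel is selected if (i) its mean
#' normalized feature under that direction is higher (or lower, for a
#' deactivation) than under both other directions, with the difference to
#' the closest other mean exceeding `margin_threshold`, and (ii) the
#' magnitude of that mean exceeds half the channel's standard deviation
#' pooled over all training trials (option: the SD of the three class
#' means).  The sign of the effect is recorded; a channel may be selected
#' for two directions (activation in one, deactivation in the other).
#' Selection is monotone: sets shrink as the margin grows.
#'
#' @param train_features trials x channels matrix, already normalized with
#'   training statistics.
#' @param train_labels Per-trial labels.
#' @param margin_threshold Nonnegative margin.
#' @param sd_mode `"pooled"` (default) or `"class_means"`.
#' @return A `channel_sets` list: per direction a data frame
#'   (`channel`, `sign`), plus `margin_threshold`.
#' @export
select_channels <- function(train_features, train_labels, margin_threshold,
                            sd_mode = c("pooled", "class_means")) {
  sd_mode <- match.arg(sd_mode)
  st <- channel_stats(train_features, train_labels, sd_mode)
  sets_from_stats(st, margin_threshold)
}

# Per-channel class means and the reference SD; margin-independent, so the
# nested margin search computes them once per fold.
channel_stats <- function(train_features, train_labels,
                          sd_mode = "pooled") {
  cls <- ATTN_CONDITIONS
  means <- vapply(cls, function(d) {
    colMeans(train_features[train_labels == d, , drop = FALSE])
  }, numeric(ncol(train_features)))          # channels x 3
  sd_ref <- if (sd_mode == "pooled") {
    apply(train_features, 2, stats::sd)
  } else {
    apply(means, 1, stats::sd)
  }
  list(means = means, sd_ref = sd_ref)
}

sets_from_stats <- function(st, margin_threshold) {
  cls <- ATTN_CONDITIONS
  sets <- list()
  for (d in cls) {
    others <- st$means[, setdiff(cls, d), drop = FALSE]
    m_d <- st$means[, d]
    other_max <- pmax(others[, 1], others[, 2])
    other_min <- pmin(others[, 1], others[, 2])
    hi <- m_d > other_max & (m_d - other_max) > margin_threshold
    lo <- m_d < other_min & (other_min - m_d) > margin_threshold
    amp_ok <- abs(m_d) > 0.5 * st$sd_ref
    ch <- which((hi | lo) & amp_ok)
    sets[[d]] <- data.frame(channel = ch,
                            sign = ifelse(hi[ch], 1, -1))
  }
  structure(list(sets = sets, margin_threshold = margin_threshold),
            class = "channel_sets")
}

# Vectorized prediction of many trials at once; same rule as
# classify_trial (argmax of sign-adjusted set means, precedence
# CENTER > RIGHT > LEFT, majority fallback when all sets are empty).
classify_matrix <- function(features, sets, majority_class,
                            use_abs = FALSE) {
  prec <- c("CENTER", "RIGHT", "LEFT")
  scores <- vapply(prec, function(d) {
    s <- sets$sets[[d]]
    if (is.null(s) || nrow(s) == 0) return(rep(-Inf, nrow(features)))
    v <- features[, s$channel, drop = FALSE]
    if (use_abs) rowMeans(abs(v))
    else as.numeric(v %*% s$sign) / nrow(s)
  }, numeric(nrow(features)))
  scores <- matrix(scores, ncol = 3,
                   dimnames = list(NULL, prec))
  pred <- prec[max.col(scores, ties.method = "first")]
  pred[!is.finite(apply(scores, 1, max))] <- majority_class
  pred
}

#' Classify one trial from its channel sets
#'
#' The per-direction score is the mean of the sign-adjusted normalized
#' feature values over that direction's channels (absolute-value scoring
#' available as an option); the predicted direction is the argmax.  Empty
#' sets cannot win; if all sets are empty the training-majority class is
#' predicted, and exact ties resolve by the fixed precedence
#' CENTER > RIGHT > LEFT.
#'
#' @param test_features Per-channel normalized feature vector.
#' @param sets A [select_channels()] result.
#' @param majority_class Fallback when all sets are empty.
#' @param use_abs Score with absolute values instead of sign adjustment.
#' @return Predicted direction.
#' @export
classify_trial <- function(test_features, sets, majority_class = "CENTER",
                           use_abs = FALSE) {
  prec <- c("CENTER", "RIGHT", "LEFT")
  scores <- vapply(prec, function(d) {
    s <- sets$sets[[d]]
    if (is.null(s) || nrow(s) == 0) return(-Inf)
    v <- test_features[s$channel]
    if (use_abs) mean(abs(v)) else mean(s$sign * v)
  }, numeric(1))
  if (all(!is.finite(scores))) return(majority_class)
  prec[which.max(scores)]   # which.max takes the first maximum = precedence
}

#' Leave-one-out cross-validation with nested margin optimization
#'
#' For each left-out trial: normalize all features with statistics from
#' the remaining training trials only; for each margin in the grid, select
#' channels on the training trials and classify the training trials
#' themselves; keep the margin with the most training-correct
#' classifications (ties resolve to the smallest margin); classify the
#' held-out trial with that selection.  Aggregates per-class TPRs and the
#' confusion matrix over all folds.
#'
#' @param trial_set An [ecog_trial_set()] (or trials x channels matrix).
#' @param labels Labels when `trial_set` is a bare matrix.
#' @param margin_grid Margins to search; default 50 evenly spaced values
#'   from 0 to the 95th percentile of the between-class mean gaps of the
#'   training trials (computed per fold).
#' @param sd_mode Passed to [select_channels()].
#' @param use_abs Passed to [classify_trial()].
#' @return List with `tpr` (named per class), `confusion`
#'   (truth x prediction), `accuracy`, `fold_margins`, `fold_details`.
#' @export
ecog_loocv <- function(trial_set, labels = NULL, margin_grid = NULL,
                       sd_mode = "pooled", use_abs = FALSE) {
  if (inherits(trial_set, "ecog_trial_set")) {
    features <- trial_set$features
    labels <- trial_set$labels
  } else {
    features <- as.matrix(trial_set)
  }
  stopifnot(!is.null(labels), nrow(features) == length(labels))
  if (any(table(factor(labels, ATTN_CONDITIONS)) < 2)) {
    stop("need at least 2 trials per class", call. = FALSE)
  }
  n <- nrow(features)
  pred <- character(n)
  fold_margins <- numeric(n)
  fold_stats <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    st <- ecog_norm_stats(features, train)
    fn <- ecog_apply_norm(features, st)
    tr_f <- fn[train, , drop = FALSE]
    tr_l <- labels[train]
    grid <- sort(if (is.null(margin_grid)) default_margin_grid(tr_f, tr_l)
                 else margin_grid)
    maj <- names(which.max(table(tr_l)))
    st_ch <- channel_stats(tr_f, tr_l, sd_mode)
    best_correct <- -1L
    best_sets <- NULL
    best_margin <- NA_real_
    for (m in grid) {
      sets <- sets_from_stats(st_ch, m)
      correct <- sum(classify_matrix(tr_f, sets, maj, use_abs) == tr_l)
      if (correct > best_correct) {
        best_correct <- correct
        best_sets <- sets
        best_margin <- m
      }
    }
    pred[i] <- classify_trial(fn[i, ], best_sets, maj, use_abs)
    fold_margins[i] <- best_margin
    fold_stats[[i]] <- st
  }
  confusion <- table(truth = factor(labels, ATTN_CONDITIONS),
                     prediction = factor(pred, ATTN_CONDITIONS))
  tpr <- diag(confusion) / rowSums(confusion)
  list(tpr = tpr, confusion = confusion, accuracy = mean(pred == labels),
       fold_margins = fold_margins, fold_details = fold_stats,
       predictions = pred)
}

default_margin_grid <- function(train_features, train_labels) {
  cls <- ATTN_CONDITIONS
  means <- vapply(cls, function(d) {
    colMeans(train_features[train_labels == d, , drop = FALSE])
  }, numeric(ncol(train_features)))
  gaps <- c(abs(means[, 1] - means[, 2]), abs(means[, 1] - means[, 3]),
            abs(means[, 2] - means[, 3]))
  seq(0, stats::quantile(gaps, 0.95, names = FALSE), length.out = 50)
}

#' Write ECoG features / LOO report as delimited tables
#' @param trial_set An `ecog_trial_set`.
#' @param path Output path (TSV, label column first).
#' @export
write_ecog_features <- function(trial_set, path) {
  df <- data.frame(label = trial_set$labels, trial_set$features)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecog_features
#' @param result An [ecog_loocv()] result.
#' @export
write_ecog_report <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# accuracy=%.6f", result$accuracy), con)
  writeLines(sprintf("# tpr_%s=%.6f", tolower(names(result$tpr)),
                     result$tpr), con)
  utils::write.table(as.data.frame.matrix(result$confusion), con,
                     sep = "\t", quote = FALSE)
  invisible(path)
}
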