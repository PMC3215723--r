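#' Pipeline run configuration
#'
#' Bundles every tunable of the decoding pipeline with defaults equal to
#' the paradigm's stated constants: TR 1.62 s; localizer 8 trials per
#' condition (+1 initial CENTER) of 8 scans; feedback 10 trials per
#' condition of 10 scans; detrending lambda 500; fixed thresholds
#' (1.5, 2.5, 4) / (-1.5, -2.5, -4); adaptive target FPR 0.2; hemodynamic
#' shift 3 TRs; ROI size 500 with minimum cluster 5.
#'
#' @param tr_seconds Repetition time.
#' @param localizer_n,localizer_len Localizer trials per condition, scans
#'   per trial.
#' @param feedback_n,feedback_len Feedback trials per condition, scans per
#'   trial.
#' @param lambda Detrending parameter.
#' @param thresholds Fixed [threshold_set()].
#' @param target_fpr Adaptive-threshold FPR bound.
#' @param shift_trs Hemodynamic shift in scans.
#' @param roi_k,min_cluster ROI selection parameters.
#' @param grid_shape Phantom grid (default `c(32, 32, 16)`).
#' @param effect_pct,deact_pct,noise_sd,drift_pct_per_min Phantom signal
#'   parameters (percent units).
#' @param adaptive Use adaptive thresholds for feedback classification.
#' @param realign Motion-correct each scan to the first volume.
#' @param normalize_sd Use the SD-normalized control-signal variant.
#' @param seed Master seed.
#' @return A `bci_config` list.
#' @export
bci_config <- function(tr_seconds = 1.62,
                       localizer_n = 8L, localizer_len = 8L,
                       feedback_n = 10L, feedback_len = 10L,
                       lambda = 500,
                       thresholds = threshold_set(),
                       target_fpr = 0.2, shift_trs = 3L,
                       roi_k = 500L, min_cluster = 5L,
                       grid_shape = c(32L, 32L, 16L),
                       effect_pct = 2, deact_pct = -1,
                       noise_sd = 3, drift_pct_per_min = 1,
                       adaptive = TRUE, realign = FALSE,
                       normalize_sd = FALSE, seed = 1L) {
  structure(list(tr_seconds = tr_seconds,
                 localizer_n = localizer_n, localizer_len = localizer_len,
                 feedback_n = feedback_n, feedback_len = feedback_len,
                 lambda = lambda, thresholds = thresholds,
                 target_fpr = target_fpr, shift_trs = shift_trs,
                 roi_k = roi_k, min_cluster = min_cluster,
                 grid_shape = grid_shape, effect_pct = effect_pct,
                 deact_pct = deact_pct, noise_sd = noise_sd,
                 drift_pct_per_min = drift_pct_per_min,
                 adaptive = adaptive, realign = realign,
                 normalize_sd = normalize_sd, seed = seed),
            class = "bci_config")
}

#' Run the decoding pipeline
#'
#' Executes the stages in acquisition order on one continuous run
#' (localizer scans first, feedback scans directly after): `simulate`
#' generates schedules and the synthetic 4D run, `localize` fits the
#' incremental GLM and selects ROIs and baselines, `feedback` produces the
#' control trace, `score` computes the performance report (including both
#' FPR variants, single-time-point accuracies, the Wolpaw bit rate and
#' the incremental-vs-batch ROI Dice overlaps), and `ecog_cv` runs the
#' ECoG leave-one-out classifier on a synthetic trial set.  `mode =
#' "all"` chains simulate through score.  Artifacts and a provenance log
#' (config, seed, package version) are written under `out_dir`.
#'
#' @param config A [bci_config()].
#' @param mode One of `simulate`, `localize`, `feedback`, `score`,
#'   `ecog_cv`, `all`.
#' @param out_dir Run directory (created if missing).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = bci_config(),
                         mode = c("all", "simulate", "localize", "feedback",
                                  "score", "ecog_cv"),
                         out_dir = tempfile("bcirun")) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out_dir, "pipeline_state.rds")
  st <- if (file.exists(state_path)) readRDS(state_path) else list()

  provenance <- list(config = unclass(config)[setdiff(names(config),
                                                      "thresholds")],
                     seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("boldbci")))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  if (mode %in% c("all", "simulate")) {
    st$sched_loc <- make_schedule(config$localizer_n, config$localizer_len,
                                  seed = config$seed,
                                  extra_initial_center = TRUE,
                                  tr_seconds = config$tr_seconds)
    n_loc <- attr(st$sched_loc, "n_scans_total")
    st$sched_fb <- make_schedule(config$feedback_n, config$feedback_len,
                                 seed = config$seed + 1L,
                                 tr_seconds = config$tr_seconds,
                                 onset_offset_scans = n_loc)
    full <- rbind(as.data.frame(st$sched_loc), as.data.frame(st$sched_fb))
    st$sched_full <- structure(full, tr_seconds = config$tr_seconds,
                               n_scans_total = n_loc +
                                 attr(st$sched_fb, "n_scans_total"),
                               onset_offset_scans = 0L,
                               class = c("bci_schedule", "data.frame"))
    st$spec <- phantom_spec(grid_shape = config$grid_shape,
                            effect_pct = config$effect_pct,
                            deact_pct = config$deact_pct,
                            noise_sd = config$noise_sd,
                            drift_pct_per_min = config$drift_pct_per_min)
    st$series <- simulate_bold(st$spec, st$sched_full,
                               seed = config$seed + 2L)
    write_schedule(st$sched_loc, file.path(out_dir, "schedule_localizer.tsv"))
    write_schedule(st$sched_fb, file.path(out_dir, "schedule_feedback.tsv"))
    write_volume_series(st$series, file.path(out_dir, "bold_run.nii.gz"))
  }

  if (mode %in% c("all", "localize")) {
    stop_if_missing(st, c("series", "sched_loc"), "localize")
    n_loc <- attr(st$sched_loc, "n_scans_total")
    series <- st$series
    if (config$realign) {
      template <- get_scan(series, 1)
      logs <- vector("list", dim(series)[4])
      logs[[1]] <- rigid_transform()
      for (t in 2:dim(series)[4]) {
        reg <- register(get_scan(series, t), template)
        series[, , , t] <- reg$resampled
        logs[[t]] <- reg$transform
      }
      write_transform_log(logs, file.path(out_dir, "realignment.tsv"))
      st$series <- series
    }
    design <- build_design(st$sched_loc)
    flat <- t(matrix(series, nrow = prod(dim(series)[1:3])))
    st$glm <- glm_stream(flat[seq_len(n_loc), , drop = FALSE], design)
    dims <- dim(series)[1:3]
    st$tmap_r <- glm_tmap(st$glm, contrast_right_minus_left(), dims)
    st$tmap_l <- glm_tmap(st$glm, contrast_left_minus_right(), dims)
    mean_vol <- array(rowMeans(matrix(series, nrow = prod(dims))), dims)
    st$mask <- make_mask(mean_vol)
    st$pair <- select_rois(st$tmap_r, st$tmap_l, st$mask,
                           k = config$roi_k, min_cluster = config$min_cluster)
    loc_series <- volume_series(array(series[, , , seq_len(n_loc)],
                                      dim = c(dims, n_loc)),
                                tr_seconds = config$tr_seconds)
    st$pair <- compute_baselines(loc_series, st$sched_loc, st$pair)
    write_tmap(st$tmap_r, file.path(out_dir, "tmap_right_minus_left.nii.gz"))
    write_tmap(st$tmap_l, file.path(out_dir, "tmap_left_minus_right.nii.gz"))
    write_roi_masks(st$pair, file.path(out_dir, "roi_right.nii.gz"),
                    file.path(out_dir, "roi_left.nii.gz"))
  }

  if (mode %in% c("all", "feedback")) {
    stop_if_missing(st, c("series", "pair", "sched_loc", "sched_fb"),
                    "feedback")
    n_loc <- attr(st$sched_loc, "n_scans_total")
    st$loc_cs <- localizer_cs(st$pair, config$lambda,
                              normalize_sd = config$normalize_sd)
    st$adaptive_thresholds <- adaptive_thresholds(
      as.numeric(st$loc_cs), st$sched_loc,
      target_fpr = config$target_fpr, shift_trs = config$shift_trs)
    th <- if (config$adaptive) st$adaptive_thresholds else config$thresholds
    fb_scans <- n_loc + seq_len(attr(st$sched_fb, "n_scans_total"))
    fb_series <- roi_series(st$series, c(st$pair$roi_r, st$pair$roi_l),
                            fb_scans)
    loc_labels <- schedule_labels(st$sched_loc)
    st$trace <- run_feedback(fb_series, st$pair, st$sched_fb,
                             thresholds = th, lambda = config$lambda,
                             shift_trs = config$shift_trs,
                             context_labels = loc_labels,
                             normalize_sd = config$normalize_sd)
    write_control_trace(st$trace, file.path(out_dir, "control_trace.tsv"))
  }

  if (mode %in% c("all", "score")) {
    stop_if_missing(st, c("trace", "sched_fb", "pair", "glm"), "score")
    th <- if (config$adaptive) st$adaptive_thresholds else config$thresholds
    rates_all <- classification_rates(st$trace, th, config$shift_trs,
                                      exclude_center = FALSE)
    rates_exc <- classification_rates(st$trace, th, config$shift_trs,
                                      exclude_center = TRUE)
    acc5 <- trial_accuracy_by_timepoint(st$trace, st$sched_fb, th, 5L)
    # Wolpaw rate from left/right-only accuracy at the 5th time point
    lr <- acc5$predictions$condition %in% c("LEFT", "RIGHT")
    pred_lr <- ifelse(acc5$predictions$predicted == "LEFT", "LEFT", "RIGHT")
    acc_lr <- mean(pred_lr[lr] == acc5$predictions$condition[lr])
    bitrate <- wolpaw_bitrate(acc_lr, 2,
                              config$feedback_len * config$tr_seconds)
    # incremental vs batch ROI overlap on the localizer
    design <- build_design(st$sched_loc)
    n_loc <- attr(st$sched_loc, "n_scans_total")
    dims <- dim(st$series)[1:3]
    flat <- t(matrix(st$series, nrow = prod(dims)))
    bt_r <- glm_batch_fit(design, flat[seq_len(n_loc), , drop = FALSE],
                          contrast_right_minus_left(), dims)
    bt_l <- glm_batch_fit(design, flat[seq_len(n_loc), , drop = FALSE],
                          contrast_left_minus_right(), dims)
    pair_b <- select_rois(bt_r, bt_l, st$mask, k = config$roi_k,
                          min_cluster = config$min_cluster)
    st$report <- list(
      tpr_l = rates_all$tpr_l, tpr_r = rates_all$tpr_r,
      fpr_l = rates_all$fpr_l, fpr_r = rates_all$fpr_r,
      fpr_l_excl_center = rates_exc$fpr_l,
      fpr_r_excl_center = rates_exc$fpr_r,
      acc_timepoint5_l = acc5$acc_l, acc_timepoint5_r = acc5$acc_r,
      acc_timepoint5_lr_binary = acc_lr,
      bitrate_bits_per_min = bitrate,
      dice_r = dice(st$pair$roi_r, pair_b$roi_r),
      dice_l = dice(st$pair$roi_l, pair_b$roi_l),
      threshold_r = th$pos[1], threshold_l = th$neg[1])
    write_perf_report(st$report, file.path(out_dir, "perf_report.tsv"))
    st$roc <- roc_curve(st$trace, shift_trs = config$shift_trs)
    utils::write.table(st$roc, file.path(out_dir, "roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (mode == "ecog_cv") {
    es <- simulate_ecog(seed = config$seed + 10L)
    st$ecog <- ecog_loocv(es)
    write_ecog_features(es, file.path(out_dir, "ecog_features.tsv"))
    write_ecog_report(st$ecog, file.path(out_dir, "ecog_report.tsv"))
  }

  saveRDS(st, state_path)
  invisible(st)
}

stop_if_missing <- function(st, fields, stage) {
  missing <- fields[!fields %in% names(st)]
  if (length(missing) > 0) {
    stop(sprintf("stage '%s' requires earlier artifacts: %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}
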