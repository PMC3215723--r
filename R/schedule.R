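#' Generate a pseudo-random block-design attention schedule
#'
#' Produces an ordered sequence of LEFT / RIGHT / CENTER attention trials of
#' fixed length that tiles the run contiguously, with the constraint that no
#' two adjacent trials are attention trials to the same side.  The order is
#' drawn by sequential sampling with restarts, so any constraint-satisfying
#' order can occur; draws are reproducible for a fixed seed.
#'
#' Defaults reproduce the standard designs of the paradigm: a localizer of
#' 8 trials per condition plus one extra initial CENTER trial, each 8 scans
#' (25 trials, 200 scans), and a feedback run of 10 trials per condition,
#' each 10 scans (30 trials, 300 scans), at TR = 1.62 s.
#'
#' @param n_per_condition Trials per condition (>= 1).
#' @param trial_len_scans Scans per trial.
#' @param seed Integer seed (required for reproducibility; may be `NULL`).
#' @param extra_initial_center Prepend one extra CENTER trial.
#' @param tr_seconds Repetition time in seconds (default 1.62).
#' @param onset_offset_scans Added to all onsets, so a feedback schedule can
#'   be placed directly after a localizer within one continuous run.
#' @return A `bci_schedule`: data frame with columns `condition`,
#'   `onset_scan`, `length_scans` and attributes `tr_seconds`,
#'   `n_scans_total`.
#' @export
make_schedule <- function(n_per_condition, trial_len_scans = 8L,
                          seed = NULL, extra_initial_center = FALSE,
                          tr_seconds = 1.62, onset_offset_scans = 0L) {
  stopifnot(n_per_condition >= 1, trial_len_scans >= 1)
  counts <- c(LEFT = n_per_condition, RIGHT = n_per_condition,
              CENTER = n_per_condition)
  order <- with_seed(seed, sample_condition_order(counts))
  if (extra_initial_center) order <- c("CENTER", order)
  n_trials <- length(order)
  onsets <- onset_offset_scans + seq(1L, by = trial_len_scans,
                                     length.out = n_trials)
  sched <- data.frame(condition = order,
                      onset_scan = as.integer(onsets),
                      length_scans = as.integer(trial_len_scans),
                      stringsAsFactors = FALSE)
  structure(sched,
            tr_seconds = tr_seconds,
            n_scans_total = as.integer(n_trials * trial_len_scans),
            onset_offset_scans = as.integer(onset_offset_scans),
            class = c("bci_schedule", "data.frame"))
}

# Sequential constrained sampler: pick each slot uniformly among conditions
# with remaining count, forbidding a LEFT/RIGHT repeat of the previous
# trial; restart on dead ends.
sample_condition_order <- function(counts, max_restarts = 10000L) {
  for (attempt in seq_len(max_restarts)) {
    rem <- counts
    out <- character(sum(counts))
    prev <- ""
    ok <- TRUE
    for (i in seq_along(out)) {
      allowed <- names(rem)[rem > 0]
      if (prev %in% c("LEFT", "RIGHT")) allowed <- setdiff(allowed, prev)
      if (length(allowed) == 0) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1) allowed else
        sample(allowed, 1, prob = rem[allowed])
      out[i] <- pick
      rem[pick] <- rem[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("could not generate a constraint-satisfying trial order", call. = FALSE)
}

#' Per-scan condition labels of a schedule
#'
#' @param schedule A `bci_schedule`.
#' @param relative If `TRUE`, labels are indexed from the schedule's first
#'   scan (ignoring any onset offset).
#' @return Character vector, one condition per scan.
#' @export
schedule_labels <- function(schedule, relative = TRUE) {
  off <- attr(schedule, "onset_offset_scans") %||% 0L
  n <- attr(schedule, "n_scans_total")
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(schedule))) {
    a <- schedule$onset_scan[i] - (if (relative) off else 0L)
    lab[a:(a + schedule$length_scans[i] - 1L)] <- schedule$condition[i]
  }
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bci_schedule <- function(x, ...) {
  cat(sprintf("attention schedule: %d trials, %d scans, TR %.2f s\n",
              nrow(x), attr(x, "n_scans_total"), attr(x, "tr_seconds")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

#' Write / read a schedule as a tab-delimited table
#'
#' Three columns (condition, onset_scan, length_scans); TR and scan count
#' are stored in comment header lines.
#' @param schedule A `bci_schedule`.
#' @param path Output file path.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds=%g", attr(schedule, "tr_seconds")), con)
  writeLines(sprintf("# n_scans_total=%d", attr(schedule, "n_scans_total")), con)
  utils::write.table(as.data.frame(schedule), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 2)
  tr <- as.numeric(sub("# tr_seconds=", "", hdr[1]))
  ns <- as.integer(sub("# n_scans_total=", "", hdr[2]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(df, tr_seconds = tr, n_scans_total = ns,
            onset_offset_scans = as.integer(min(df$onset_scan) - 1L),
            class = c("bci_schedule", "data.frame"))
}
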