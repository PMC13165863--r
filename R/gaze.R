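#' Detect gaze fixations from ROI-labeled samples
#'
#' A fixation is a maximal run of consecutive samples sharing the same
#' non-null region of interest whose time span meets the minimum dwell
#' threshold (default 200 ms). Detection works on timestamps, not an
#' assumed sampling rate: the span of a run is the time between its
#' first and last sample. Runs shorter than the threshold emit nothing.
#'
#' Trackers drop samples routinely, so a short interruption does not
#' break a run: up to `gap_samples` consecutive null-ROI samples, or a
#' timestamp gap of at most `gap_seconds`, is bridged when the same ROI
#' resumes. A sample on a *different* ROI always terminates the run.
#'
#' @param samples Data frame with columns `time` (seconds, sorted
#'   ascending) and `roi` (object name, `NA` for off-screen/lost
#'   samples). Optional column `player` is carried through.
#' @param min_fixation Minimum dwell in seconds (default 0.200).
#' @param gap_samples Maximum consecutive null samples bridged inside a
#'   run (default 1).
#' @param gap_seconds Maximum bridged timestamp gap in seconds (default
#'   0.025); the effective tolerance is whichever of the two rules is
#'   more permissive.
#' @return Data frame of fixations: `player`, `roi`, `start`, `duration`
#'   (seconds), `n_samples`.
#' @export
detect_fixations <- function(samples, min_fixation = 0.200,
                             gap_samples = 1, gap_seconds = 0.025) {
  stopifnot(min_fixation > 0)
  empty <- data.frame(player = character(), roi = character(),
                      start = numeric(), duration = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  if (is.null(samples) || nrow(samples) == 0) return(empty)
  if (is.unsorted(samples$time, strictly = FALSE)) {
    stop("gaze samples must be sorted by time", call. = FALSE)
  }
  player <- if ("player" %in% names(samples)) as.character(samples$player[1]) else "P1"
  t <- samples$time
  roi <- as.character(samples$roi)

  fix <- list()
  run_roi <- NA_character_
  run_start <- NA_real_
  run_last <- NA_real_
  run_n <- 0L
  null_streak <- 0L

  close_run <- function() {
    if (!is.na(run_roi) && run_n > 0 && (run_last - run_start) >= min_fixation) {
      fix[[length(fix) + 1L]] <<- data.frame(
        player = player, roi = run_roi, start = run_start,
        duration = run_last - run_start, n_samples = run_n,
        stringsAsFactors = FALSE)
    }
    run_roi <<- NA_character_; run_start <<- NA_real_
    run_last <<- NA_real_; run_n <<- 0L; null_streak <<- 0L
  }

  for (i in seq_along(t)) {
    r <- roi[i]
    if (is.na(r) || !nzchar(r)) {
      if (!is.na(run_roi)) {
        null_streak <- null_streak + 1L
        gap <- t[i] - run_last
        if (null_streak > gap_samples && gap > gap_seconds) close_run()
      }
      next
    }
    if (is.na(run_roi)) {
      run_roi <- r; run_start <- t[i]; run_last <- t[i]; run_n <- 1L; null_streak <- 0L
    } else if (r == run_roi &&
               (null_streak <= gap_samples || (t[i] - run_last) <= gap_seconds)) {
      run_last <- t[i]; run_n <- run_n + 1L; null_streak <- 0L
    } else {
      close_run()
      run_roi <- r; run_start <- t[i]; run_last <- t[i]; run_n <- 1L
    }
  }
  close_run()
  if (!length(fix)) return(empty)
  out <- do.call(rbind, fix)
  rownames(out) <- NULL
  out
}

#' Categorize fixations into task, social and time gaze
#'
#' Resolves each fixation's region of interest through the ROI map and
#' tallies per-player fixation counts and total dwell in the three gaze
#' categories: task-related gaze (virtual objects, the default for
#' unmapped ROIs), social gaze (the partner's video-streaming window),
#' and time-related gaze (the timer bar).
#'
#' @param fixations Fixation data frame from [detect_fixations()].
#' @param roi_map Named character vector mapping ROI names to
#'   `"task"`, `"social"` or `"time"`; see [default_roi_map()].
#' @return Data frame with one row per player: fixation counts
#'   (`gaze_at_object`, `gaze_at_partner`, `gaze_at_timebar`,
#'   `count_total`) and dwell totals in seconds (`dwell_task`,
#'   `dwell_social`, `dwell_time`).
#' @export
categorize_gaze <- function(fixations, roi_map = default_roi_map()) {
  players <- unique(as.character(fixations$player))
  if (!length(players)) players <- character(0)
  cat_of <- function(roi) {
    hit <- unname(roi_map[roi])
    ifelse(is.na(hit), "task", hit)
  }
  rows <- lapply(players, function(p) {
    f <- fixations[fixations$player == p, , drop = FALSE]
    categ <- cat_of(f$roi)
    data.frame(player = p,
               gaze_at_object  = sum(categ == "task"),
               gaze_at_partner = sum(categ == "social"),
               gaze_at_timebar = sum(categ == "time"),
               count_total     = nrow(f),
               dwell_task   = sum(f$duration[categ == "task"]),
               dwell_social = sum(f$duration[categ == "social"]),
               dwell_time   = sum(f$duration[categ == "time"]),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(player = character(), gaze_at_object = numeric(),
                      gaze_at_partner = numeric(), gaze_at_timebar = numeric(),
                      count_total = numeric(), dwell_task = numeric(),
                      dwell_social = numeric(), dwell_time = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract one player's gaze sample stream from a session log
#'
#' @param log A `session_log`.
#' @param player Player identifier.
#' @return Data frame with `time`, `roi`, `player` for records carrying
#'   valid gaze coordinates; `roi` is the focused object (may be `NA`).
#' @export
gaze_samples <- function(log, player) {
  rec <- log$records
  r <- rec[rec$player == player & !is.na(rec$gaze_x) & !is.na(rec$gaze_y), , drop = FALSE]
  data.frame(time = r$timestamp, roi = r$focused_object,
             player = rep(player, nrow(r)), stringsAsFactors = FALSE)
}
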