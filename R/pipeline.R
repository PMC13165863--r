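#' Run the full analysis pipeline on a session log
#'
#' Chains every analysis stage: windowing, per-player behavior
#' timelines, utterance segmentation with dialogue-act labels and
#' initiation flags, fixation detection and gaze categorization, the
#' feedback state machine (training sessions only; assessment sessions
#' receive no feedback), feature extraction, and dimension scoring.
#'
#' @param log A `session_log`.
#' @param tick Behavior window length, seconds (default 1).
#' @param min_fixation Fixation dwell threshold, seconds (default 0.200).
#' @param silence_gap Utterance-segmentation silence, seconds (default 1).
#' @param initiation_gap Initiation silence threshold, seconds
#'   (default 30).
#' @param fsm_wait Feedback persistence requirement, seconds
#'   (default 30).
#' @param movement_epsilon Distance dead-band, scene units
#'   (default 0.05).
#' @param normalization Dimension-score normalization (default
#'   `"rate_per_minute"`).
#' @param task_events Optional task events for the feedback machine.
#' @param run_feedback Run the feedback machine (default: only when
#'   `log$group == "training"`).
#' @return List of class `session_analysis` with elements `windows`,
#'   `timelines` (named by player), `utterances`, `fixations`,
#'   `gaze_summary`, `features`, `profile`, `trace` (or `NULL`), and
#'   `params`.
#' @export
analyze_session <- function(log, tick = 1, min_fixation = 0.200,
                            silence_gap = 1, initiation_gap = 30,
                            fsm_wait = 30, movement_epsilon = 0.05,
                            normalization = "rate_per_minute",
                            task_events = NULL, run_feedback = NULL) {
  stopifnot(inherits(log, "session_log"))
  if (is.null(run_feedback)) run_feedback <- identical(log$group, "training")
  windows <- window_session(log, tick = tick)
  players <- sort(unique(windows$player))
  timelines <- lapply(players, function(p) {
    build_timeline(windows[windows$player == p, , drop = FALSE],
                   movement_epsilon = movement_epsilon)
  })
  names(timelines) <- players
  utterances <- session_utterances(log, silence_gap = silence_gap,
                                   silence_threshold = initiation_gap)
  fixations <- do.call(rbind, lapply(players, function(p) {
    detect_fixations(gaze_samples(log, p), min_fixation = min_fixation)
  }))
  gaze_summary <- categorize_gaze(fixations, log$roi_map)
  trace <- NULL
  if (run_feedback && length(players) == 2) {
    trace <- run_fsm(timelines[[1]], timelines[[2]],
                     task_events = task_events, wait = fsm_wait)
  }
  features <- extract_features(log, utterances = utterances,
                               fixations = fixations, windows = windows)
  profile <- score_dimensions(features, normalization = normalization)
  structure(list(windows = windows, timelines = timelines,
                 utterances = utterances, fixations = fixations,
                 gaze_summary = gaze_summary, features = features,
                 profile = profile, trace = trace,
                 params = list(tick = tick, min_fixation = min_fixation,
                               silence_gap = silence_gap,
                               initiation_gap = initiation_gap,
                               fsm_wait = fsm_wait,
                               movement_epsilon = movement_epsilon,
                               normalization = normalization)),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("<session_analysis> %d windows/player, %d utterances, %d fixations\n",
              sum(x$windows$player == x$windows$player[1]),
              nrow(x$utterances), nrow(x$fixations)))
  if (!is.null(x$trace)) print(x$trace)
  invisible(x)
}

#' Write the pipeline artifacts of a session analysis to a directory
#'
#' Emits one CSV per stage (timelines, utterances, fixations, gaze
#' summary, features, profile, feedback states and prompts when
#' present) plus a machine-readable `manifest.yaml` recording the
#' parameters and seed sufficient to reproduce the run.
#'
#' @param analysis A `session_analysis`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (optional).
#' @return Invisibly, the vector of written paths.
#' @export
write_analysis <- function(analysis, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  tl <- do.call(rbind, analysis$timelines)
  wr(tl, "timelines.csv")
  utt <- analysis$utterances
  wr(utt, "utterances.csv")
  wr(analysis$fixations, "fixations.csv")
  wr(analysis$gaze_summary, "gaze_summary.csv")
  wr(analysis$features, "features.csv")
  wr(as.data.frame(unclass(analysis$profile)), "profile.csv")
  if (!is.null(analysis$trace)) {
    wr(analysis$trace$states, "fsm_states.csv")
    wr(analysis$trace$prompts, "fsm_prompts.csv")
  }
  manifest <- c(analysis$params,
                list(seed = seed,
                     package_version = as.character(utils::packageVersion("dyadsense")),
                     r_version = R.version.string))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  paths <- c(paths, file.path(dir, "manifest.yaml"))
  invisible(paths)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `classify`, `feedback`,
#' `profile` and `demo` over the package pipeline. `simulate` renders a
#' preset scenario to a session CSV; `classify`, `feedback` and
#' `profile` run the corresponding pipeline stages on a session file;
#' `demo` chains simulate and the full analysis. Flags follow the
#' pattern `--seed`, `--out`, `--tick`, `--min-fixation-ms`,
#' `--silence-gap-s`, `--initiation-gap-s`, `--fsm-wait-s`,
#' `--scenario`, `--input`. Defaults are the platform's standard
#' constants (200 ms, 1 s, 15 s, 30 s, 30 s).
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success); errors signal with a
#'   diagnostic so wrapper scripts can exit nonzero.
#' @export
dyadsense_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: dyadsense <simulate|classify|feedback|profile|demo> [--flags]",
         call. = FALSE)
  }
  cmd <- args[1]
  rest <- args[-1]
  get_flag <- function(name, default) {
    hit <- grep(paste0("^--", name, "="), rest, value = TRUE)
    if (length(hit)) sub(paste0("^--", name, "="), "", hit[1])
    else {
      pos <- match(paste0("--", name), rest)
      if (!is.na(pos) && pos < length(rest)) rest[pos + 1] else default
    }
  }
  out_dir <- get_flag("out", "dyadsense_out")
  seed <- as.integer(get_flag("seed", "1"))
  tick <- as.numeric(get_flag("tick", "1"))
  min_fix <- as.numeric(get_flag("min-fixation-ms", "200")) / 1000
  silence_gap <- as.numeric(get_flag("silence-gap-s", "1"))
  init_gap <- as.numeric(get_flag("initiation-gap-s", "30"))
  fsm_wait <- as.numeric(get_flag("fsm-wait-s", "30"))
  scen_name <- get_flag("scenario", "observe_baseline")
  input <- get_flag("input", NA)

  load_input <- function() {
    if (is.na(input)) stop("--input <session file> is required", call. = FALSE)
    read_session(input)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  status <- switch(cmd,
    simulate = {
      presets <- preset_scenarios(seed = seed)
      if (!scen_name %in% names(presets)) {
        stop(sprintf("unknown scenario '%s'; presets: %s", scen_name,
                     paste(names(presets), collapse = ", ")), call. = FALSE)
      }
      sim <- simulate_session(presets[[scen_name]])
      write_session(sim$log, file.path(out_dir, "session.csv"))
      utils::write.csv(
        data.frame(player = rep(names(sim$truth$states),
                                lengths(sim$truth$states)),
                   window = unlist(lapply(sim$truth$states, seq_along)) - 1,
                   state = unlist(sim$truth$states)),
        file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
      0L
    },
    classify = ,
    feedback = ,
    profile = {
      log <- load_input()
      an <- analyze_session(log, tick = tick, min_fixation = min_fix,
                            silence_gap = silence_gap,
                            initiation_gap = init_gap, fsm_wait = fsm_wait,
                            run_feedback = cmd == "feedback")
      write_analysis(an, out_dir, seed = seed)
      0L
    },
    demo = {
      presets <- preset_scenarios(seed = seed)
      sim <- simulate_session(presets[[scen_name]])
      write_session(sim$log, file.path(out_dir, "session.csv"))
      an <- analyze_session(sim$log, tick = tick, min_fixation = min_fix,
                            silence_gap = silence_gap,
                            initiation_gap = init_gap, fsm_wait = fsm_wait,
                            task_events = presets[[scen_name]]$task_events,
                            run_feedback = TRUE)
      write_analysis(an, out_dir, seed = seed)
      0L
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  )
  invisible(status)
}
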