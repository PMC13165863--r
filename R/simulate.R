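#' Define a scripted dyad scenario
#'
#' A scenario scripts each participant's ground-truth behavior as a
#' sequence of (state, duration) segments and fixes the noise and
#' rendering parameters used to synthesize the raw multimodal log.
#' Rendering honors the inverse of the behavior decision tree, so a
#' noise-free scenario is recovered exactly by the classifier:
#' `Engaged` segments emit controller activity with the object moving
#' toward its target plus occasional utterances; `Waiting` segments
#' emit either gaze-only samples or controller activity with a
#' stationary object; `Struggling` segments emit controller activity
#' with the object drifting away, or total signal absence.
#'
#' @param p1,p2 Scripts: data frames (or lists of pairs) with columns
#'   `state` (`Engaged`/`Struggling`/`Waiting`) and `duration`
#'   (seconds > 0).
#' @param task_events Optional data frame `time`, `kind`
#'   (`"step"`/`"task"`).
#' @param gaze_dropout Probability an individual gaze sample is lost
#'   (default 0).
#' @param utterance_rate Mean utterances per second while `Engaged`
#'   (exponential inter-arrival; default 0.1).
#' @param distance_drift Object-distance change per second during
#'   `Engaged` (toward) and `Struggling` (away), scene units
#'   (default 0.5).
#' @param distance_jitter SD of Gaussian jitter added to each rendered
#'   distance (default 0; keep well below `distance_drift`).
#' @param waiting_mode `"gaze"` (gaze-only samples) or `"controller"`
#'   (active controller, stationary object).
#' @param struggling_mode `"controller"` (drifting away) or `"absent"`
#'   (no signals at all).
#' @param gaze_hz Gaze sampling rate, Hz (default 60, matching a 60 Hz
#'   display).
#' @param share_rate Mean piece-sharing events per second while
#'   `Engaged` (default 0.02).
#' @param seed Integer RNG seed; identical scenarios render identical
#'   logs.
#' @return An object of class `dyad_scenario`.
#' @export
scenario <- function(p1, p2, task_events = NULL,
                     gaze_dropout = 0, utterance_rate = 0.1,
                     distance_drift = 0.5, distance_jitter = 0,
                     waiting_mode = c("gaze", "controller"),
                     struggling_mode = c("controller", "absent"),
                     gaze_hz = 60, share_rate = 0.02, seed = 1L) {
  waiting_mode <- match.arg(waiting_mode)
  struggling_mode <- match.arg(struggling_mode)
  as_script <- function(s) {
    s <- as.data.frame(s)
    stopifnot(all(c("state", "duration") %in% names(s)))
    s$state <- as.character(s$state)
    if (!all(s$state %in% behavior_states())) stop("unknown behavior state in script", call. = FALSE)
    if (!all(s$duration > 0)) stop("script durations must be positive", call. = FALSE)
    s[c("state", "duration")]
  }
  stopifnot(gaze_dropout >= 0, gaze_dropout < 1, utterance_rate >= 0,
            distance_drift >= 0, distance_jitter >= 0, gaze_hz > 0, share_rate >= 0)
  structure(list(p1 = as_script(p1), p2 = as_script(p2),
                 task_events = task_events, gaze_dropout = gaze_dropout,
                 utterance_rate = utterance_rate, distance_drift = distance_drift,
                 distance_jitter = distance_jitter, waiting_mode = waiting_mode,
                 struggling_mode = struggling_mode, gaze_hz = gaze_hz,
                 share_rate = share_rate, seed = as.integer(seed)),
            class = "dyad_scenario")
}

# Expand a script into one state per whole-second window.
.script_windows <- function(script) {
  rep(script$state, times = ceiling(script$duration))
}

# Utterance templates drawn from the dialogue-act scheme's vocabulary.
.sim_utterances <- c("okay", "yeah I see it",
                     "try moving it more to the right",
                     "can you pass me the blue piece",
                     "mine says to select the small plate",
                     "good job", "thanks", "let me try this one",
                     "I think it goes on top", "what do you see")

#' Render a scenario into a raw multimodal session log
#'
#' Synthesizes the 15-parameter record stream for both participants from
#' their scripted behavior states, at one controller/heartbeat record
#' per second plus gaze samples at `gaze_hz` and utterance records at
#' the scripted rate. Deterministic given the scenario seed.
#'
#' @param scn A `dyad_scenario`.
#' @param dyad_id,group Session metadata.
#' @return List with `log` (a [session_log()]) and `truth` (the
#'   scripted ground truth: per-player window-state vectors, the
#'   expected feedback-condition runs with their prompt/escalation
#'   landmark times, and the scenario itself).
#' @export
simulate_session <- function(scn, dyad_id = "sim", group = "training") {
  stopifnot(inherits(scn, "dyad_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(scn$seed)

  win1 <- .script_windows(scn$p1)
  win2 <- .script_windows(scn$p2)
  n_win <- max(length(win1), length(win2))
  win1 <- c(win1, rep("Engaged", n_win - length(win1)))
  win2 <- c(win2, rep("Engaged", n_win - length(win2)))

  render_player <- function(player, states) {
    n <- length(states)
    # start far enough from target that Engaged windows never reach it
    dist0 <- scn$distance_drift * (sum(states != "Waiting") + 2) + 5
    dist <- dist0
    shared <- 0L
    rows <- list()
    add <- function(df) rows[[length(rows) + 1L]] <<- df
    # baseline distance reading at session start so the first window's
    # movement direction is well defined
    add(data.frame(timestamp = 0, player = player,
                   transcribed_text = NA_character_,
                   gaze_x = NA_real_, gaze_y = NA_real_,
                   focused_object = NA_character_,
                   total_score = 0, individual_score = 0,
                   piece_at_target = NA_character_, piece_shared = NA_character_,
                   shared_count = 0, piece_selected = NA_character_,
                   active_effort = NA_real_, game_duration = n,
                   object_distance = dist0, stringsAsFactors = FALSE))
    for (k in seq_len(n)) {
      t0 <- k - 1
      st <- states[k]
      absent <- st == "Struggling" && scn$struggling_mode == "absent"
      gaze_only_wait <- st == "Waiting" && scn$waiting_mode == "gaze"
      effort <- if (st == "Engaged" || st == "Struggling" && !absent ||
                    (st == "Waiting" && scn$waiting_mode == "controller")) 1 else 0
      if (absent) effort <- 0
      jitter <- if (scn$distance_jitter > 0) stats::rnorm(1, 0, scn$distance_jitter) else 0
      dist_new <- switch(st,
                         Engaged = dist - scn$distance_drift,
                         Struggling = dist + scn$distance_drift,
                         Waiting = dist)
      # heartbeat record: controller flag, distance, scores
      if (!absent) {
        piece <- if (st == "Engaged" && scn$share_rate > 0 &&
                     stats::runif(1) < scn$share_rate) {
          shared <<- shared + 1L
          sprintf("piece_%d", shared)
        } else NA_character_
        add(data.frame(timestamp = t0 + 0.5, player = player,
                       transcribed_text = NA_character_,
                       gaze_x = NA_real_, gaze_y = NA_real_,
                       focused_object = NA_character_,
                       total_score = round(100 * k / n, 2),
                       individual_score = round(100 * k / n, 2),
                       piece_at_target = NA_character_, piece_shared = piece,
                       shared_count = shared, piece_selected = NA_character_,
                       active_effort = effort, game_duration = n,
                       object_distance = max(dist_new + jitter, 0),
                       stringsAsFactors = FALSE))
      }
      dist <- dist_new
      # gaze samples across the window
      if (!absent) {
        ts <- t0 + seq(0, 1 - 1 / scn$gaze_hz, by = 1 / scn$gaze_hz)
        keep <- if (scn$gaze_dropout > 0) stats::runif(length(ts)) >= scn$gaze_dropout
                else rep(TRUE, length(ts))
        ts <- ts[keep]
        if (length(ts)) {
          add(data.frame(timestamp = ts, player = player,
                         transcribed_text = NA_character_,
                         gaze_x = 960 + round(stats::runif(length(ts), -50, 50), 1),
                         gaze_y = 540 + round(stats::runif(length(ts), -50, 50), 1),
                         focused_object = "task_object",
                         total_score = NA_real_, individual_score = NA_real_,
                         piece_at_target = NA_character_, piece_shared = NA_character_,
                         shared_count = shared, piece_selected = NA_character_,
                         active_effort = NA_real_, game_duration = n,
                         object_distance = NA_real_, stringsAsFactors = FALSE))
        }
      }
      # utterances while Engaged
      if (st == "Engaged" && scn$utterance_rate > 0 &&
          stats::runif(1) < 1 - exp(-scn$utterance_rate)) {
        add(data.frame(timestamp = t0 + round(stats::runif(1, 0.05, 0.95), 3),
                       player = player,
                       transcribed_text = sample(.sim_utterances, 1),
                       gaze_x = NA_real_, gaze_y = NA_real_,
                       focused_object = NA_character_,
                       total_score = NA_real_, individual_score = NA_real_,
                       piece_at_target = NA_character_, piece_shared = NA_character_,
                       shared_count = shared, piece_selected = NA_character_,
                       active_effort = NA_real_, game_duration = n,
                       object_distance = NA_real_, stringsAsFactors = FALSE))
      }
    }
    do.call(rbind, rows)
  }

  rec1 <- render_player("P1", win1)
  rec2 <- render_player("P2", win2)
  rec <- rbind(rec1, rec2)
  if (is.null(rec)) rec <- validate_records(data.frame(timestamp = numeric(), player = character()))
  log <- session_log(rec, dyad_id = dyad_id, group = group,
                     session_length = n_win)
  truth <- list(states = list(P1 = win1, P2 = win2),
                landmarks = expected_fsm_landmarks(win1, win2),
                scenario = scn)
  list(log = log, truth = truth)
}

#' Expected feedback landmark times from scripted states
#'
#' Computes, independently of the state-machine implementation, the
#' maximal runs of each non-Observe dyad condition and the times at
#' which a sustained condition should yield its first prompt
#' (onset + `wait`) and its escalation (onset + `2 * wait`).
#'
#' @param states1,states2 Per-window state vectors (1 s windows).
#' @param wait Persistence requirement in seconds (default 30).
#' @return Data frame: `condition`, `onset`, `end`, `first_prompt`,
#'   `escalation` (`NA` when the run is too short).
#' @export
expected_fsm_landmarks <- function(states1, states2, wait = 30) {
  n <- length(states1)
  stopifnot(length(states2) == n)
  if (n == 0) {
    return(data.frame(condition = character(), onset = numeric(), end = numeric(),
                      first_prompt = numeric(), escalation = numeric()))
  }
  keys <- vapply(seq_len(n), function(i) {
    tgt <- .fsm_target(states1[i], states2[i])
    .fsm_condition_key(tgt, states1[i], states2[i])
  }, character(1))
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(condition = sub(":.*", "", runs$values),
                    onset = starts - 1, end = ends,
                    stringsAsFactors = FALSE)
  out <- out[out$condition != "Observe", , drop = FALSE]
  len <- out$end - out$onset
  out$first_prompt <- ifelse(len > wait, out$onset + wait, NA_real_)
  out$escalation <- ifelse(len > 2 * wait, out$onset + 2 * wait, NA_real_)
  rownames(out) <- NULL
  out
}

#' Named preset scenarios
#'
#' Five canonical scenarios, each exercising one row of the feedback
#' machine: `observe_baseline` (both Engaged), `redirect_case` (one
#' participant Waiting for 90 s), `assist_case` (one Struggling for
#' 90 s), `intervene_case` (both Struggling for 90 s) and
#' `positive_case` (both Engaged with a step completion).
#'
#' @param seed Seed applied to every preset.
#' @return Named list of `dyad_scenario` objects.
#' @export
preset_scenarios <- function(seed = 1L) {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(state = m[, 1], duration = as.numeric(m[, 2]),
               stringsAsFactors = FALSE)
  }
  engaged90 <- seg("Engaged", 90)
  list(
    observe_baseline = scenario(engaged90, engaged90, seed = seed),
    redirect_case = scenario(seg("Waiting", 90), engaged90, seed = seed),
    assist_case = scenario(seg("Struggling", 90), engaged90, seed = seed),
    intervene_case = scenario(seg("Struggling", 90), seg("Struggling", 90), seed = seed),
    positive_case = scenario(seg("Engaged", 60), seg("Engaged", 60),
                             task_events = data.frame(time = 30, kind = "step"),
                             seed = seed)
  )
}
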