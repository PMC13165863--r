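#' Feedback machine states
#'
#' @return The five states of the feedback state machine.
#' @export
fsm_states <- function() {
  c("Observe", "Redirect", "Assist", "Intervene", "PositiveFeedback")
}

#' Default prompt catalogue
#'
#' Prompt texts keyed by template id, including the role-adapted
#' variants (a participant may be nudged to *initiate* communication or
#' to *check in* with their partner). The catalogue is plain data: it
#' can be edited, stored as YAML ([write_prompt_catalogue()]) and
#' reloaded ([read_prompt_catalogue()]).
#'
#' @return Named character vector of prompt templates.
#' @export
default_prompt_catalogue <- function() {
  c(redirect_waiting   = "Please wait for your partner to finish",
    redirect_partner   = "Your partner is waiting. Please update them on your progress.",
    redirect_escalate  = "Please ask the researcher for help.",
    assist_struggling  = "Try asking your partner for advice.",
    assist_partner     = "Your partner seems to be struggling, please assist them.",
    intervene_help     = "Please ask the researcher for help.",
    auto_complete      = "The current step has been completed for you.",
    positive_step      = "Good job!",
    positive_task      = "Well done on working together to complete the task!",
    positive_together  = "Great job working together!",
    role_initiate      = "Try starting a conversation with your partner.",
    role_checkin       = "Try checking in with your partner.")
}

#' Read / write a prompt catalogue as YAML
#'
#' @param path YAML file path.
#' @return `read_prompt_catalogue()` returns a named character vector;
#'   `write_prompt_catalogue()` returns `path` invisibly.
#' @export
read_prompt_catalogue <- function(path) {
  x <- yaml::read_yaml(path)
  unlist(x)
}

#' @rdname read_prompt_catalogue
#' @param catalogue Named character vector of prompt templates.
#' @export
write_prompt_catalogue <- function(catalogue, path) {
  yaml::write_yaml(as.list(catalogue), path)
  invisible(path)
}

# Map a dyad's pair of behavior states to the FSM target state.
# Struggling dominates Waiting (Assist addresses the greater breakdown);
# Intervene requires both Struggling; both-Waiting is the "both idle"
# branch of Redirect.
.fsm_target <- function(s1, s2) {
  pair <- c(s1, s2)
  n_str <- sum(pair == "Struggling")
  n_wai <- sum(pair == "Waiting")
  if (n_str == 2) return("Intervene")
  if (n_str == 1) return("Assist")
  if (n_wai >= 1) return("Redirect")
  "Observe"
}

# Identity of the triggering condition: target state plus which players
# drive it. Any change resets the 30 s timer.
.fsm_condition_key <- function(target, s1, s2) {
  trig <- switch(target,
                 Assist = paste(which(c(s1, s2) == "Struggling"), collapse = ","),
                 Redirect = paste(which(c(s1, s2) != "Engaged"), collapse = ","),
                 Intervene = "1,2",
                 "")
  paste(target, trig, sep = ":")
}

#' Run the feedback state machine over a dyad's behavior timelines
#'
#' Consumes the two participants' per-window behavior states plus task
#' events and produces the feedback trace: the timestamped state
#' trajectory, every emitted prompt, and automatic step completions.
#'
#' Transition rules: both participants `Engaged` keeps the machine in
#' `Observe`; exactly one `Waiting` (the other not `Struggling`) moves
#' to `Redirect`; exactly one `Struggling` moves to `Assist`; both
#' `Struggling` moves to `Intervene`; a step- or task-completion event
#' fires `PositiveFeedback` for one tick before returning to `Observe`.
#'
#' Timing: prompts fire only after the triggering condition has
#' persisted `wait` seconds continuously (default 30), and the
#' escalation fires after a further `wait` seconds — for `Redirect` a
#' help request to both participants, for `Assist` and `Intervene` an
#' automatic completion of the current task step, after which the
#' machine returns to `Observe` and all timers clear. Any change of the
#' triggering condition resets the timer.
#'
#' @param timeline1,timeline2 Behavior timelines for P1 and P2
#'   ([build_timeline()] rows for a single player each), sharing tick
#'   and length.
#' @param task_events Optional data frame of task events with columns
#'   `time` (seconds) and `kind` (`"step"` or `"task"`).
#' @param wait Breakdown persistence before a prompt, seconds
#'   (default 30); the escalation interval is the same length.
#' @param catalogue Prompt catalogue (named character vector).
#' @return A `feedback_trace`: list with `states` (data frame `time`,
#'   `state`), `prompts` (data frame `time`, `recipient`, `template_id`,
#'   `text`) and `auto_completions` (numeric times).
#' @export
run_fsm <- function(timeline1, timeline2, task_events = NULL, wait = 30,
                    catalogue = default_prompt_catalogue()) {
  stopifnot(wait > 0)
  n <- nrow(timeline1)
  if (n != nrow(timeline2)) stop("behavior timelines differ in length", call. = FALSE)
  tick <- attr(timeline1, "tick") %||% 1
  times <- if (n) timeline1$start else numeric(0)

  states <- character(0); state_times <- numeric(0)
  prompts <- list(); autocomp <- numeric(0)

  emit <- function(time, recipient, template_id) {
    prompts[[length(prompts) + 1L]] <<- data.frame(
      time = time, recipient = recipient, template_id = template_id,
      text = unname(catalogue[template_id]), stringsAsFactors = FALSE)
  }

  cur <- "Observe"
  cond_key <- "Observe:"
  cond_since <- 0
  prompted <- FALSE
  escalated <- FALSE
  suppressed_until <- -Inf   # after auto-completion, restart clean

  record_state <- function(time, st) {
    if (!length(states) || states[length(states)] != st) {
      states <<- c(states, st); state_times <<- c(state_times, time)
    }
  }
  record_state(0, "Observe")

  ev_times <- if (!is.null(task_events) && nrow(task_events)) task_events$time else numeric(0)
  ev_kinds <- if (!is.null(task_events) && nrow(task_events)) as.character(task_events$kind) else character(0)
  ev_done <- logical(length(ev_times))

  for (i in seq_len(n)) {
    t <- times[i]
    # task events due at or before this window boundary
    due <- which(!ev_done & ev_times <= t + tick - 1e-9 & ev_times >= t - 1e-9)
    if (length(due)) {
      ev_done[due] <- TRUE
      kind <- ev_kinds[due[1]]
      record_state(t, "PositiveFeedback")
      emit(t, "both", if (kind == "task") "positive_task" else "positive_step")
      cur <- "Observe"
      record_state(t + tick, "Observe")
      cond_key <- "Observe:"; cond_since <- t + tick
      prompted <- FALSE; escalated <- FALSE
      next
    }

    s1 <- timeline1$state[i]; s2 <- timeline2$state[i]
    target <- .fsm_target(s1, s2)
    key <- .fsm_condition_key(target, s1, s2)

    if (key != cond_key) {
      cond_key <- key
      cond_since <- t
      prompted <- FALSE
      escalated <- FALSE
    }
    if (cur != target) {
      cur <- target
      record_state(t, cur)
    }
    age <- t - cond_since
    if (cur %in% c("Redirect", "Assist", "Intervene") && t >= suppressed_until) {
      if (!prompted && age >= wait) {
        prompted <- TRUE
        if (cur == "Redirect") {
          waiting <- which(c(s1, s2) == "Waiting")
          if (length(waiting) == 1) {
            w <- paste0("P", waiting); o <- paste0("P", 3 - waiting)
            emit(t, w, "redirect_waiting")
            emit(t, o, "redirect_partner")
          } else {
            emit(t, "both", "redirect_escalate")
          }
        } else if (cur == "Assist") {
          strug <- which(c(s1, s2) == "Struggling")
          s <- paste0("P", strug); o <- paste0("P", 3 - strug)
          emit(t, s, "assist_struggling")
          emit(t, o, "assist_partner")
        } else {
          emit(t, "both", "intervene_help")
        }
      }
      if (prompted && !escalated && age >= 2 * wait) {
        escalated <- TRUE
        if (cur == "Redirect") {
          emit(t, "both", "redirect_escalate")
        } else {
          autocomp <- c(autocomp, t)
          emit(t, "both", "auto_complete")
          cur <- "Observe"
          record_state(t + tick, "Observe")
          cond_key <- "Observe:"; cond_since <- t + tick
          prompted <- FALSE; escalated <- FALSE
          suppressed_until <- t + tick
        }
      }
    }
  }

  prompts_df <- if (length(prompts)) do.call(rbind, prompts) else
    data.frame(time = numeric(), recipient = character(),
               template_id = character(), text = character(),
               stringsAsFactors = FALSE)
  rownames(prompts_df) <- NULL
  structure(list(states = data.frame(time = state_times, state = states,
                                     stringsAsFactors = FALSE),
                 prompts = prompts_df,
                 auto_completions = autocomp,
                 tick = tick, wait = wait),
            class = "feedback_trace")
}

#' @export
print.feedback_trace <- function(x, ...) {
  cat(sprintf("<feedback_trace> %d state changes, %d prompts, %d auto-completions\n",
              nrow(x$states), nrow(x$prompts), length(x$auto_completions)))
  invisible(x)
}

#' Export a feedback trace to CSV files
#'
#' Writes the state trajectory and the prompt events as two CSV files.
#'
#' @param trace A `feedback_trace`.
#' @param states_path,prompts_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_trace <- function(trace, states_path, prompts_path) {
  utils::write.csv(trace$states, states_path, row.names = FALSE)
  utils::write.csv(trace$prompts, prompts_path, row.names = FALSE)
  invisible(c(states_path, prompts_path))
}
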