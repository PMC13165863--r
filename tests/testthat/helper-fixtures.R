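# Frozen regression fixture: the labeled example phrases of the
# dialogue-act coding scheme. Every phrase must map to its coded label.
da_example_phrases <- function() {
  rbind(
    data.frame(text = c("I know", "You’re right", "Okay", "Yeah", "Yup",
                        "Cool", "uh-huh"),
               label = "Acks", stringsAsFactors = FALSE),
    data.frame(text = c("No, I don’t need this one",
                        "I don’t think this is the right one", "No",
                        "Um, I’m not sure", "I don’t think so", "Oh no"),
               label = "Neg", stringsAsFactors = FALSE),
    data.frame(text = c("Well done", "Good job"),
               label = "Pos", stringsAsFactors = FALSE),
    data.frame(text = c("What do you see?", "Can you try W?"),
               label = "Ques", stringsAsFactors = FALSE),
    data.frame(text = "Mine says to select the 8 gigabyte RAM",
               label = "Read", stringsAsFactors = FALSE),
    data.frame(text = c("Try moving it more to the right", "And then backward",
                        "Let’s see", "Mine has me moving", "Let me try",
                        "I think", "I feel", "I believe", "I mean",
                        "it wants you to put that into the CPU"),
               label = "Inform", stringsAsFactors = FALSE),
    data.frame(text = c("Thanks", "Thank you", "Sorry", "My bad"),
               label = "Conv", stringsAsFactors = FALSE),
    data.frame(text = c("The.", "It said an end then snow"),
               label = "Out", stringsAsFactors = FALSE)
  )
}

# Minimal valid record row; override fields as needed.
make_record <- function(timestamp, player = "P1", ...) {
  base <- data.frame(timestamp = timestamp, player = player,
                     transcribed_text = NA_character_, gaze_x = NA_real_,
                     gaze_y = NA_real_, focused_object = NA_character_,
                     total_score = NA_real_, individual_score = NA_real_,
                     piece_at_target = NA_character_, piece_shared = NA_character_,
                     shared_count = 0, piece_selected = NA_character_,
                     active_effort = NA_real_, game_duration = NA_real_,
                     object_distance = NA_real_, stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

make_records <- function(timestamps, player = "P1", ...) {
  df <- do.call(rbind, lapply(timestamps, make_record, player = player))
  dots <- list(...)
  for (nm in names(dots)) df[[nm]] <- dots[[nm]]
  df
}

# Regular gaze stream for one player: one ROI run embedded in a stream.
make_gaze_run <- function(n_on, roi = "CPU", hz = 60, t0 = 0) {
  data.frame(time = t0 + (seq_len(n_on) - 1) / hz, roi = rep(roi, n_on),
             stringsAsFactors = FALSE)
}

# Brute-force fixation oracle: enumerate maximal same-ROI runs (no gap
# bridging) and keep those spanning >= min_fixation.
oracle_fixations <- function(samples, min_fixation = 0.200) {
  if (nrow(samples) == 0) return(data.frame(roi = character(), start = numeric(),
                                            duration = numeric()))
  roi <- as.character(samples$roi)
  roi[is.na(roi)] <- ""
  r <- rle(roi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- nzchar(r$values)
  out <- do.call(rbind, lapply(which(keep), function(i) {
    span <- samples$time[ends[i]] - samples$time[starts[i]]
    if (span >= min_fixation) {
      data.frame(roi = r$values[i], start = samples$time[starts[i]],
                 duration = span, stringsAsFactors = FALSE)
    }
  }))
  if (is.null(out)) data.frame(roi = character(), start = numeric(),
                               duration = numeric()) else out
}

# Brute-force BH step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hand oracle for the behavior decision tree, transcribed independently
# of the implementation.
oracle_behavior <- function(speech, ctrl, movement, gaze) {
  if (speech) return("Engaged")
  if (ctrl) {
    if (movement == "away") return("Struggling")
    if (movement == "toward") return("Engaged")
    return("Waiting")
  }
  if (gaze) return("Waiting")
  "Struggling"
}

# Hand oracle for the dyad-state -> FSM-state priority table.
oracle_fsm_state <- function(s1, s2) {
  if (s1 == "Struggling" && s2 == "Struggling") return("Intervene")
  if (s1 == "Struggling" || s2 == "Struggling") return("Assist")
  if (s1 == "Waiting" || s2 == "Waiting") return("Redirect")
  "Observe"
}

# Constant-state behavior timeline for FSM tests.
make_timeline <- function(states, player = "P1", tick = 1) {
  out <- data.frame(player = rep(player, length(states)),
                    window = seq_along(states) - 1L,
                    start = (seq_along(states) - 1L) * tick, state = states,
                    stringsAsFactors = FALSE)
  attr(out, "tick") <- tick
  out
}
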