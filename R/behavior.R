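#' Behavior state labels
#'
#' @return The three per-window participant behavior states.
#' @export
behavior_states <- function() c("Engaged", "Struggling", "Waiting")

#' Classify one analysis window into a behavior state
#'
#' The interpretable decision tree used for real-time classification,
#' evaluated in order:
#' \enumerate{
#'   \item speech detected in the window → `Engaged`;
#'   \item else, controller input present: object moving *away* from its
#'     target → `Struggling`; moving *toward* the target → `Engaged`;
#'     stationary despite input → `Waiting`;
#'   \item else (no speech, no controller): gaze present → `Waiting`;
#'     gaze absent → `Struggling`.
#' }
#' Gaze is not consulted when controller input is present, and movement
#' is only meaningful when it is; the function is total and
#' deterministic over all input combinations.
#'
#' @param speech_present,controller_active,gaze_present Logicals
#'   (vectorized).
#' @param movement `"toward"`, `"away"` or `"none"` (vectorized;
#'   ignored when `controller_active` is `FALSE`).
#' @return Character vector of behavior states.
#' @export
classify_window <- function(speech_present, controller_active,
                            movement = "none", gaze_present = FALSE) {
  n <- max(length(speech_present), length(controller_active),
           length(movement), length(gaze_present))
  speech_present <- rep_len(as.logical(speech_present), n)
  controller_active <- rep_len(as.logical(controller_active), n)
  movement <- rep_len(as.character(movement), n)
  gaze_present <- rep_len(as.logical(gaze_present), n)
  stopifnot(all(movement %in% c("toward", "away", "none")))
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (isTRUE(speech_present[i])) {
      "Engaged"
    } else if (isTRUE(controller_active[i])) {
      switch(movement[i],
             away = "Struggling",
             toward = "Engaged",
             none = "Waiting")
    } else if (isTRUE(gaze_present[i])) {
      "Waiting"
    } else {
      "Struggling"
    }
  }
  out
}

#' Build a per-player behavior timeline from session windows
#'
#' Converts windowed channels ([window_session()]) into a behavior state
#' per window. Movement is derived from the signed object-distance
#' change across the window: a drop below `-movement_epsilon` is
#' movement toward the target, a rise above `+movement_epsilon` is
#' movement away, anything in between (or no distance signal) is
#' stationary.
#'
#' An optional width-3 majority filter smooths isolated one-window state
#' flips; it is off by default so that downstream feedback timing
#' reflects the raw classification.
#'
#' @param windows Window data frame from [window_session()] (one or both
#'   players; each player is processed independently).
#' @param movement_epsilon Dead-band for the distance delta, scene units
#'   (default 0.05).
#' @param smooth Apply the majority filter (default `FALSE`).
#' @return Data frame `player`, `window`, `start`, `state` of class
#'   `behavior_timeline`; `attr(x, "tick")` carries the window length.
#' @export
build_timeline <- function(windows, movement_epsilon = 0.05, smooth = FALSE) {
  stopifnot(movement_epsilon >= 0)
  delta <- windows$dist_delta
  movement <- ifelse(is.na(delta) | abs(delta) <= movement_epsilon, "none",
                     ifelse(delta < 0, "toward", "away"))
  movement[!windows$controller_active] <- "none"
  state <- classify_window(windows$speech_present, windows$controller_active,
                           movement, windows$gaze_present)
  out <- data.frame(player = windows$player, window = windows$window,
                    start = windows$start, state = state,
                    stringsAsFactors = FALSE)
  if (smooth) {
    for (p in unique(out$player)) {
      ix <- which(out$player == p)
      s <- out$state[ix]
      if (length(s) >= 3) {
        sm <- s
        for (k in 2:(length(s) - 1)) {
          trio <- s[(k - 1):(k + 1)]
          tab <- table(trio)
          sm[k] <- names(tab)[which.max(tab)]
        }
        out$state[ix] <- sm
      }
    }
  }
  attr(out, "tick") <- attr(windows, "tick") %||% 1
  class(out) <- c("behavior_timeline", class(out))
  out
}
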