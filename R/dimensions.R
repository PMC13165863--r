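#' The five dimensions of collaboration
#'
#' @return Character vector of dimension names.
#' @export
collaboration_dimensions <- function() {
  c("DialogueManagement", "InformationPooling", "ReciprocalInteraction",
    "TaskDivisionCoordination", "TimeManagement")
}

#' Feature-to-dimension incidence map
#'
#' The frozen mapping from sensed features to the five dimensions of
#' collaboration. Dialogue Management draws on conversational flow
#' (initiations and the Acks/Neg/Conv dialogue acts); Information
#' Pooling on information exchange (pieces shared and Ques/Read/Inform);
#' Reciprocal Interaction on contribution and reciprocity (active
#' effort and Pos/Acks); Task Division & Coordination on coordinated
#' action (task-object fixations, pieces shared, active effort, Inform);
#' Time Management solely on timer-bar fixations — time awareness is
#' tracked only through gaze.
#'
#' @return Named list: dimension → character vector of feature names.
#' @export
dimension_feature_map <- function() {
  list(
    DialogueManagement       = c("initiation_count", "da_Acks", "da_Neg", "da_Conv"),
    InformationPooling       = c("piece_shared_count", "da_Ques", "da_Read", "da_Inform"),
    ReciprocalInteraction    = c("active_effort_total", "da_Pos", "da_Acks"),
    TaskDivisionCoordination = c("gaze_at_object", "piece_shared_count",
                                 "active_effort_total", "da_Inform"),
    TimeManagement           = c("gaze_at_timebar")
  )
}

#' Extract the per-player feature vector from session artifacts
#'
#' Collects the multimodal features feeding the dimension scores:
#' initiation count, dialogue-act counts (the `Out` class is tallied but
#' excluded from every dimension), pieces shared, total active-effort
#' windows, per-category fixation counts, and the score/duration
#' parameters carried in the log.
#'
#' @param log A `session_log`.
#' @param utterances Labeled utterances from [session_utterances()]
#'   (computed from `log` when omitted).
#' @param fixations Fixations for both players (computed when omitted).
#' @param windows Window table from [window_session()] (computed when
#'   omitted).
#' @return Data frame with one row per player and one column per
#'   feature.
#' @export
extract_features <- function(log, utterances = NULL, fixations = NULL,
                             windows = NULL) {
  stopifnot(inherits(log, "session_log"))
  if (is.null(utterances)) utterances <- session_utterances(log)
  if (is.null(windows)) windows <- window_session(log)
  players <- sort(unique(c(log$records$player, "P1", "P2")))
  if (is.null(fixations)) {
    fixations <- do.call(rbind, lapply(players, function(p) {
      detect_fixations(gaze_samples(log, p))
    }))
  }
  gaze_sum <- categorize_gaze(fixations, log$roi_map)
  init_counts <- attr(utterances, "counts") %||% stats::setNames(integer(0), character(0))
  labels <- dialogue_act_labels()

  rows <- lapply(players, function(p) {
    rec <- log$records[log$records$player == p, , drop = FALSE]
    u <- utterances[utterances$player == p, , drop = FALSE]
    da <- vapply(labels, function(l) sum(u$label == l), numeric(1))
    names(da) <- paste0("da_", labels)
    g <- gaze_sum[gaze_sum$player == p, , drop = FALSE]
    shared <- if (nrow(rec)) max(c(rec$shared_count, 0), na.rm = TRUE) else 0
    shared_events <- sum(!is.na(rec$piece_shared) & nzchar(rec$piece_shared))
    w <- windows[windows$player == p, , drop = FALSE]
    cbind(data.frame(player = p,
                     initiation_count = unname(init_counts[p] %|na|% 0),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(da)),
          data.frame(
            piece_shared_count  = max(shared, shared_events),
            active_effort_total = sum(w$controller_active),
            gaze_at_object  = if (nrow(g)) g$gaze_at_object else 0,
            gaze_at_partner = if (nrow(g)) g$gaze_at_partner else 0,
            gaze_at_timebar = if (nrow(g)) g$gaze_at_timebar else 0,
            task_score = if (any(!is.na(rec$total_score)))
              rec$total_score[max(which(!is.na(rec$total_score)))] else 0,
            individual_score = if (any(!is.na(rec$individual_score)))
              rec$individual_score[max(which(!is.na(rec$individual_score)))] else 0,
            game_duration = log$session_length))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Score the five dimensions of collaboration
#'
#' Each dimension score is the unweighted mean of its normalized
#' constituent features (see [dimension_feature_map()]). Two
#' normalizations are offered: `"rate_per_minute"` divides count
#' features by the session length in minutes, so that doubling a
#' session with proportionally doubled counts leaves scores unchanged;
#' `"zscore"` standardizes each feature across the supplied cohort of
#' players (requires at least two rows with nonzero spread; zero-spread
#' features standardize to 0).
#'
#' @param features Feature data frame from [extract_features()] (one or
#'   more players, possibly pooled across sessions).
#' @param normalization `"rate_per_minute"` or `"zscore"`.
#' @return Data frame of class `collaboration_profile`: one row per
#'   player with the five dimension scores; `attr(x, "provenance")`
#'   records the contributing feature names per dimension.
#' @export
score_dimensions <- function(features, normalization = c("rate_per_minute", "zscore")) {
  normalization <- match.arg(normalization)
  fmap <- dimension_feature_map()
  feat_names <- unique(unlist(fmap))
  missing <- setdiff(feat_names, names(features))
  if (length(missing)) {
    stop(sprintf("features missing columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  norm <- features
  if (normalization == "rate_per_minute") {
    mins <- features$game_duration / 60
    mins[!is.finite(mins) | mins <= 0] <- NA
    for (f in feat_names) {
      norm[[f]] <- ifelse(is.na(mins), 0, features[[f]] / mins)
    }
  } else {
    for (f in feat_names) {
      v <- features[[f]]
      s <- stats::sd(v)
      norm[[f]] <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
  }
  scores <- data.frame(player = features$player, stringsAsFactors = FALSE)
  for (dim in names(fmap)) {
    cols <- fmap[[dim]]
    scores[[dim]] <- rowMeans(as.data.frame(norm[cols]))
  }
  attr(scores, "provenance") <- fmap
  attr(scores, "normalization") <- normalization
  class(scores) <- c("collaboration_profile", class(scores))
  scores
}

#' Aggregate dyad-level profile from player profiles
#'
#' Sums feature counts over the two players of a dyad before scoring,
#' for analyses where the dyad is the unit.
#'
#' @param features Feature data frame for both players of one dyad.
#' @param normalization Passed to [score_dimensions()].
#' @return One-row `collaboration_profile` labeled `"dyad"`.
#' @export
score_dimensions_dyad <- function(features, normalization = "rate_per_minute") {
  num <- vapply(features, is.numeric, logical(1))
  pooled <- as.data.frame(lapply(features[num], sum))
  pooled$game_duration <- max(features$game_duration)
  pooled$task_score <- max(features$task_score)
  pooled$player <- "dyad"
  score_dimensions(pooled, normalization)
}

#' Aggregate per-feature effect sizes to dimension level
#'
#' A dimension's mean effect size is the arithmetic mean of the
#' *absolute* Cohen's d values of its constituent features.
#'
#' @param d_values Named numeric vector of per-feature Cohen's d values,
#'   or a list grouping d values by dimension.
#' @param fmap Feature-to-dimension map (default
#'   [dimension_feature_map()]); ignored when `d_values` is already a
#'   grouped list.
#' @return Named numeric vector: mean |d| per dimension.
#' @export
aggregate_dimension_effects <- function(d_values, fmap = dimension_feature_map()) {
  if (is.list(d_values) && !is.data.frame(d_values)) {
    groups <- d_values
  } else {
    if (is.null(names(d_values))) {
      stop("d_values must be named by feature", call. = FALSE)
    }
    groups <- lapply(fmap, function(cols) {
      d_values[intersect(cols, names(d_values))]
    })
  }
  vapply(groups, function(ds) {
    ds <- unlist(ds)
    if (!length(ds)) stop("a dimension has no constituent effect sizes", call. = FALSE)
    mean(abs(ds))
  }, numeric(1))
}
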