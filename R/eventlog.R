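# Canonical 15-column record schema. Column order is the on-disk order.
.record_schema <- function() {
  c(timestamp        = "numeric",
    player           = "character",
    transcribed_text = "character",
    gaze_x           = "numeric",
    gaze_y           = "numeric",
    focused_object   = "character",
    total_score      = "numeric",
    individual_score = "numeric",
    piece_at_target  = "character",
    piece_shared     = "character",
    shared_count     = "numeric",
    piece_selected   = "character",
    active_effort    = "numeric",
    game_duration    = "numeric",
    object_distance  = "numeric")
}

# Accepted header aliases (lower-cased, punctuation collapsed to "_").
.column_aliases <- function() {
  list(timestamp        = c("timestamp", "time"),
       player           = c("player", "player_label", "player_id"),
       transcribed_text = c("transcribed_text", "text", "transcript", "speech"),
       gaze_x           = c("gaze_x", "x_gaze_point", "x_gaze", "gazex"),
       gaze_y           = c("gaze_y", "y_gaze_point", "y_gaze", "gazey"),
       focused_object   = c("focused_object", "focus_object", "roi"),
       total_score      = c("total_score", "totalscore"),
       individual_score = c("individual_score", "indiv_score"),
       piece_at_target  = c("piece_at_target", "piece_on_target"),
       piece_shared     = c("piece_shared", "shared_piece"),
       shared_count     = c("shared_count", "share_count", "pieces_shared"),
       piece_selected   = c("piece_selected", "selected_piece"),
       active_effort    = c("active_effort", "effort", "active"),
       game_duration    = c("game_duration", "duration"),
       object_distance  = c("object_distance", "distance", "object_dist"))
}

#' Parse a session clock string to elapsed seconds
#'
#' Timestamps are logged as `HH:MM:SS` with optional fractional seconds
#' (`HH:MM:SS.mmm`). Whole-second stamps are valid but limit downstream
#' fixation-duration resolution, so loggers are encouraged to include
#' milliseconds.
#'
#' @param text Character vector of clock strings.
#' @return Numeric vector of elapsed seconds.
#' @seealso [format_timestamp()] for the inverse.
#' @examples
#' parse_timestamp("00:01:30")       # 90
#' parse_timestamp("01:00:00.250")   # 3600.25
#' @export
parse_timestamp <- function(text) {
  text <- trimws(as.character(text))
  ok <- grepl("^\\d{1,2}:\\d{2}:\\d{2}(\\.\\d{1,3})?$", text)
  if (any(!ok)) {
    bad <- which(!ok)
    stop(sprintf("malformed timestamp at record %d: '%s' (expected HH:MM:SS or HH:MM:SS.mmm)",
                 bad[1], text[bad[1]]), call. = FALSE)
  }
  parts <- strsplit(text, ":", fixed = TRUE)
  vapply(parts, function(p) {
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60 + as.numeric(p[3])
  }, numeric(1))
}

#' Format elapsed seconds as a session clock string
#'
#' @param seconds Numeric vector of non-negative elapsed seconds.
#' @param digits Fractional-second digits to print (default 3).
#' @return Character vector in `HH:MM:SS.mmm` form (fraction omitted when
#'   `digits = 0`).
#' @export
format_timestamp <- function(seconds, digits = 3) {
  stopifnot(is.numeric(seconds), all(seconds >= 0))
  h <- floor(seconds / 3600)
  m <- floor((seconds - h * 3600) / 60)
  s <- seconds - h * 3600 - m * 60
  if (digits > 0) {
    ss <- formatC(round(s, digits), format = "f", digits = digits, width = digits + 3, flag = "0")
    # rounding may carry 59.9995 -> "60.000"
    carry <- as.numeric(ss) >= 60
    if (any(carry)) {
      s[carry] <- 0
      m[carry] <- m[carry] + 1
      over <- m >= 60
      m[over] <- m[over] - 60
      h[over] <- h[over] + 1
      ss <- formatC(round(s, digits), format = "f", digits = digits, width = digits + 3, flag = "0")
    }
    sprintf("%02d:%02d:%s", h, m, ss)
  } else {
    sprintf("%02d:%02d:%02d", h, m, round(s))
  }
}

#' Construct a session log
#'
#' A `session_log` bundles the time-ordered multimodal record stream for
#' one dyad with its metadata: dyad identifier, study arm, the mapping
#' from on-screen object names to gaze categories, and the session
#' length. Records are sorted by timestamp with ties broken by player
#' (P1 before P2) then original order, so identical inputs always yield
#' identical logs.
#'
#' @param records Data frame with the 15-column record schema (see
#'   [read_session()] for column names). `timestamp` is numeric seconds.
#' @param dyad_id Dyad identifier string.
#' @param group Study arm, `"training"` or `"control"`.
#' @param roi_map Named character vector mapping object names to gaze
#'   categories `"task"`, `"social"` or `"time"`. Unmapped objects
#'   default to `"task"`.
#' @param session_length Session length in seconds; defaults to the
#'   latest record timestamp rounded up to a whole second.
#' @return An object of class `session_log`.
#' @export
session_log <- function(records, dyad_id = "dyad", group = c("training", "control"),
                        roi_map = default_roi_map(), session_length = NULL) {
  group <- match.arg(group)
  records <- validate_records(records)
  ord <- order(records$timestamp, match(records$player, c("P1", "P2")))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(session_length)) {
    session_length <- if (nrow(records)) ceiling(max(records$timestamp)) else 0
  }
  if (length(roi_map) && (is.null(names(roi_map)) ||
      !all(roi_map %in% c("task", "social", "time")))) {
    stop("roi_map must be a named vector with values in {task, social, time}", call. = FALSE)
  }
  structure(list(dyad_id = dyad_id, group = group, records = records,
                 roi_map = roi_map, session_length = session_length),
            class = "session_log")
}

#' Default region-of-interest categorization
#'
#' Maps the partner video window to social gaze and the timer bar to
#' time gaze; any other focused object is task gaze by default.
#'
#' @return Named character vector of gaze categories.
#' @export
default_roi_map <- function() {
  c(video_window = "social", partner_video = "social",
    timer_bar = "time", time_bar = "time")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> dyad %s (%s): %d records, %d players, %.1f s\n",
              x$dyad_id, x$group, nrow(x$records),
              length(unique(x$records$player)), x$session_length))
  invisible(x)
}

# Coerce and validate a record data frame against the schema; bad rows are
# an error here (reader-level dropping happens in read_session).
validate_records <- function(records) {
  schema <- .record_schema()
  missing <- setdiff(names(schema), names(records))
  for (col in missing) {
    records[[col]] <- if (schema[[col]] == "numeric") NA_real_ else NA_character_
  }
  records <- records[names(schema)]
  for (col in names(schema)) {
    records[[col]] <- if (schema[[col]] == "numeric") as.numeric(records[[col]])
                      else as.character(records[[col]])
  }
  bad <- .invalid_record_rows(records)
  if (any(bad)) {
    stop(sprintf("invalid record at row %d (bad timestamp, player, flag or score)",
                 which(bad)[1]), call. = FALSE)
  }
  records
}

# Row-level validity per the conservative missing-data policy: structural
# fields must parse; optional payloads may be NA.
.invalid_record_rows <- function(records) {
  bad <- is.na(records$timestamp) | records$timestamp < 0
  bad <- bad | is.na(records$player) | !(records$player %in% c("P1", "P2"))
  bad <- bad | (!is.na(records$active_effort) & !(records$active_effort %in% c(0, 1)))
  for (col in c("total_score", "individual_score")) {
    v <- records[[col]]
    bad <- bad | (!is.na(v) & (v < 0 | v > 100))
  }
  bad <- bad | (!is.na(records$shared_count) & records$shared_count < 0)
  bad <- bad | (!is.na(records$object_distance) & records$object_distance < 0)
  bad
}

#' Read a session log from CSV or JSON-lines
#'
#' Parses the 15-parameter multimodal schema (header names matched
#' case-insensitively against documented aliases), converts clock-string
#' timestamps to seconds, validates each row, and drops invalid or
#' corrupted rows rather than imputing them. The number of dropped rows
#' is reported in the `dropped` attribute; more than 50% dropped rows is
#' treated as a wrong-file error.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension when
#'   omitted.
#' @param dyad_id,group,roi_map,session_length Passed to [session_log()].
#' @return A `session_log`; `attr(x, "dropped")` gives the dropped-row
#'   count.
#' @export
read_session <- function(path, format = c("auto", "csv", "jsonl"),
                         dyad_id = "dyad", group = "training",
                         roi_map = default_roi_map(), session_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read session file '%s'", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") .read_csv_records(path) else .read_jsonl_records(path)
  if (nrow(raw) == 0) stop(sprintf("no parseable records in '%s'", path), call. = FALSE)

  # timestamps: clock strings or bare seconds
  ts <- raw$timestamp
  parsed <- suppressWarnings(as.numeric(ts))
  clockish <- is.na(parsed) & grepl(":", ts %||% "")
  parsed[clockish] <- vapply(ts[clockish], function(t) {
    tryCatch(parse_timestamp(t), error = function(e) NA_real_)
  }, numeric(1))
  raw$timestamp <- parsed

  schema <- .record_schema()
  for (col in names(schema)) {
    if (!col %in% names(raw)) {
      raw[[col]] <- if (schema[[col]] == "numeric") NA_real_ else NA_character_
    }
    raw[[col]] <- if (schema[[col]] == "numeric") suppressWarnings(as.numeric(raw[[col]]))
                  else { v <- as.character(raw[[col]]); v[!is.na(v) & v == ""] <- NA_character_; v }
  }
  raw <- raw[names(schema)]
  bad <- .invalid_record_rows(raw)
  dropped <- sum(bad)
  if (dropped > nrow(raw) / 2) {
    stop(sprintf("more than half of the rows in '%s' are invalid (%d of %d); wrong file or schema?",
                 path, dropped, nrow(raw)), call. = FALSE)
  }
  log <- session_log(raw[!bad, , drop = FALSE], dyad_id = dyad_id, group = group,
                     roi_map = roi_map, session_length = session_length)
  attr(log, "dropped") <- dropped
  log
}

.normalize_header <- function(h) gsub("[^a-z0-9]+", "_", tolower(trimws(h)))

.map_columns <- function(df) {
  aliases <- .column_aliases()
  names(df) <- .normalize_header(names(df))
  for (canon in names(aliases)) {
    hit <- intersect(aliases[[canon]], names(df))
    if (length(hit) && !canon %in% names(df)) {
      names(df)[match(hit[1], names(df))] <- canon
    }
  }
  df
}

.read_csv_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  .map_columns(df)
}

.read_jsonl_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(data.frame())
  keys <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(keys, function(k) {
    vapply(rows, function(r) {
      v <- r[[k]]
      if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))) NA_character_
      else as.character(v[1])
    }, character(1))
  }), stringsAsFactors = FALSE)
  names(df) <- keys
  .map_columns(df)
}

#' Write a session log to CSV or JSON-lines
#'
#' The inverse of [read_session()]: timestamps are serialized as
#' `HH:MM:SS.mmm` clock strings and all 15 canonical columns are
#' written. `write_session()` then `read_session()` round-trips the
#' record content exactly.
#'
#' @param log A `session_log`.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path, format = c("auto", "csv", "jsonl")) {
  stopifnot(inherits(log, "session_log"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  out <- log$records
  out$timestamp <- format_timestamp(out$timestamp)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      row <- as.list(out[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Merge two single-player record streams into one session log
#'
#' Produces the time-sorted union of both streams. No records are lost;
#' the relative order within each player's stream is preserved, and at
#' equal timestamps P1 sorts before P2 (then original order) so merging
#' is deterministic regardless of input interleaving.
#'
#' @param a,b Record data frames, each for a single distinct player.
#' @param ... Passed to [session_log()].
#' @return A `session_log`.
#' @export
merge_player_streams <- function(a, b, ...) {
  pa <- unique(a$player)
  pb <- unique(b$player)
  if (length(pa) > 1 || length(pb) > 1) {
    stop("each input stream must belong to a single player", call. = FALSE)
  }
  if (length(intersect(pa, pb))) {
    stop(sprintf("overlapping player identifier '%s' in both streams", pa), call. = FALSE)
  }
  session_log(rbind(a, b), ...)
}

#' Discretize a session into per-player analysis windows
#'
#' Splits the session into half-open windows `[k*tick, (k+1)*tick)` and
#' projects each player's records onto boolean channels per window:
#' speech present, controller active (any `active_effort == 1`), gaze
#' present (any valid gaze sample), plus the signed object-distance
#' change across the window (last known distance at window end minus
#' last known distance before window start; `NA` until the first
#' distance observation). A record falling exactly on a boundary belongs
#' to the later window.
#'
#' @param log A `session_log`.
#' @param tick Window length in seconds (default 1).
#' @return Data frame with columns `player`, `window` (0-based index),
#'   `start`, `speech_present`, `controller_active`, `gaze_present`,
#'   `dist_delta`, `n_records`.
#' @export
window_session <- function(log, tick = 1) {
  stopifnot(inherits(log, "session_log"), tick > 0)
  rec <- log$records
  players <- sort(unique(rec$player))
  if (!length(players)) players <- c("P1", "P2")
  max_t <- if (nrow(rec)) max(rec$timestamp) else 0
  n_win <- max(ceiling(log$session_length / tick), floor(max_t / tick) + 1, 1)
  out <- do.call(rbind, lapply(players, function(p) {
    r <- rec[rec$player == p, , drop = FALSE]
    idx <- floor(r$timestamp / tick)
    speech <- !is.na(r$transcribed_text) & nzchar(trimws(r$transcribed_text))
    ctrl <- !is.na(r$active_effort) & r$active_effort == 1
    gaze <- !is.na(r$gaze_x) & !is.na(r$gaze_y)
    win <- data.frame(player = p, window = seq_len(n_win) - 1L,
                      start = (seq_len(n_win) - 1L) * tick,
                      speech_present = FALSE, controller_active = FALSE,
                      gaze_present = FALSE, dist_delta = NA_real_,
                      n_records = 0L, stringsAsFactors = FALSE)
    if (nrow(r)) {
      tab <- tabulate(idx + 1L, nbins = n_win)
      win$n_records <- tab
      win$speech_present <- tabulate((idx + 1L)[speech], nbins = n_win) > 0
      win$controller_active <- tabulate((idx + 1L)[ctrl], nbins = n_win) > 0
      win$gaze_present <- tabulate((idx + 1L)[gaze], nbins = n_win) > 0
      # carry-forward distance: delta across each window
      has_d <- !is.na(r$object_distance)
      if (any(has_d)) {
        dt <- r$timestamp[has_d]
        dv <- r$object_distance[has_d]
        # last observed distance at or before each window end / start
        ends <- win$start + tick
        last_at <- function(times) {
          pos <- findInterval(times - 1e-9, dt)
          ifelse(pos >= 1, dv[pmax(pos, 1)], NA_real_)
        }
        d_end <- last_at(ends)
        d_start <- last_at(win$start)
        win$dist_delta <- d_end - d_start
        # windows wholly before the first observation stay NA; the window
        # containing the first observation uses it as its own baseline
        first_seen <- !is.na(d_end) & is.na(d_start)
        win$dist_delta[first_seen] <- d_end[first_seen] - dv[1]
      }
    }
    win
  }))
  rownames(out) <- NULL
  attr(out, "tick") <- tick
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
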