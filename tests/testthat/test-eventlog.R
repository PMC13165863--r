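test_that("clock strings parse to elapsed seconds and round-trip", {
  expect_equal(parse_timestamp("00:01:30"), 90)
  expect_equal(parse_timestamp("00:00:00"), 0)
  expect_equal(parse_timestamp("01:00:00.250"), 3600.25)
  expect_error(parse_timestamp("1:2:3:4"), "malformed")
  expect_error(parse_timestamp("not a time"), "malformed")
  ts <- c(0, 0.2, 59.999, 90, 3600.25, 86399)
  expect_equal(parse_timestamp(format_timestamp(ts)), ts)
})

test_that("session files round-trip through CSV and JSON-lines", {
  rec <- rbind(
    make_records(c(0, 1.5, 3), "P1", active_effort = 1, object_distance = 2.5,
                 total_score = 50, shared_count = 1),
    make_records(c(0.5, 2), "P2", transcribed_text = "okay then",
                 gaze_x = 100, gaze_y = 200, focused_object = "CPU"))
  log <- session_log(rec, dyad_id = "d1", group = "control")
  for (fmt in c("csv", "jsonl")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_session(log, path)
    back <- read_session(path, dyad_id = "d1", group = "control")
    expect_equal(back$records, log$records, tolerance = 1e-9)
    expect_equal(attr(back, "dropped"), 0)
  }
})

test_that("invalid rows are dropped and counted; mostly-bad files are an error", {
  good <- make_records(seq(0, 9), "P1", active_effort = 1)
  path <- tempfile(fileext = ".csv")
  log <- session_log(good)
  write_session(log, path)
  lines <- readLines(path)
  lines[5] <- gsub("^\"?00[^,]*", "garbage", lines[5])  # corrupt one timestamp
  writeLines(lines, path)
  back <- read_session(path)
  expect_equal(nrow(back$records), 9)
  expect_equal(attr(back, "dropped"), 1)

  bad <- lines
  bad[2:10] <- vapply(bad[2:10], function(l) gsub("^\"?00[^,]*", "x", l), "")
  writeLines(bad, path)
  expect_error(read_session(path), "half")
  expect_error(read_session(tempfile()), "cannot read")
})

test_that("header aliases and bare-second timestamps are accepted", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Timestamp,Player Label,Transcribed Text,Active Effort",
               "00:00:01,P1,hello there,1",
               "2.5,P2,,0"), path)
  log <- read_session(path)
  expect_equal(log$records$timestamp, c(1, 2.5))
  expect_equal(log$records$player, c("P1", "P2"))
  expect_equal(log$records$transcribed_text[1], "hello there")
})

test_that("merging player streams is order-preserving, tie-broken, and permutation-safe", {
  a <- make_records(c(0, 2), "P1")
  b <- make_records(c(1, 3), "P2")
  m <- merge_player_streams(a, b)
  expect_equal(m$records$player, c("P1", "P2", "P1", "P2"))
  expect_equal(m$records$timestamp, c(0, 1, 2, 3))

  expect_equal(merge_player_streams(a, b[0, ])$records$timestamp, c(0, 2))

  tie <- merge_player_streams(make_records(5, "P2"), make_records(5, "P1"))
  expect_equal(tie$records$player, c("P1", "P2"))

  expect_error(merge_player_streams(a, make_records(1, "P1")), "overlapping")

  # permutation safety: shuffled single log reconstructs identically
  set.seed(42)
  big_a <- make_records(sort(runif(20, 0, 10)), "P1", active_effort = 1)
  big_b <- make_records(sort(runif(20, 0, 10)), "P2")
  ref <- merge_player_streams(big_a, big_b)
  for (k in 1:5) {
    alt <- merge_player_streams(big_b, big_a)
    expect_equal(alt$records, ref$records)
  }
})

test_that("windowing uses half-open windows and projects channels", {
  rec <- rbind(make_records(seq(0, 9.5, by = 0.5), "P1", active_effort = 0),
               make_records(seq(0, 9.5, by = 0.5), "P2", active_effort = 0))
  log <- session_log(rec, session_length = 10)
  w <- window_session(log, tick = 1)
  expect_equal(sum(w$player == "P1"), 10)
  expect_equal(sum(w$player == "P2"), 10)

  # record exactly at a boundary belongs to the later window
  log2 <- session_log(rbind(make_record(1.0, "P1", transcribed_text = "hi"),
                            make_record(0.5, "P2")), session_length = 2)
  w2 <- window_session(log2, tick = 1)
  expect_false(w2$speech_present[w2$player == "P1" & w2$window == 0])
  expect_true(w2$speech_present[w2$player == "P1" & w2$window == 1])

  # channel projections
  log3 <- session_log(rbind(
    make_record(0.2, "P1", active_effort = 1),
    make_record(1.2, "P1", gaze_x = 5, gaze_y = 5),
    make_record(2.2, "P1", transcribed_text = "ok")), session_length = 3)
  w3 <- window_session(log3, tick = 1)
  expect_equal(w3$controller_active, c(TRUE, FALSE, FALSE))
  expect_equal(w3$gaze_present, c(FALSE, TRUE, FALSE))
  expect_equal(w3$speech_present, c(FALSE, FALSE, TRUE))
})

test_that("adding records to a window only turns channels on, never off", {
  set.seed(7)
  base <- make_records(sort(runif(30, 0, 10)), "P1")
  log <- session_log(base, session_length = 10)
  w0 <- window_session(log)
  extra <- make_record(4.5, "P1", transcribed_text = "new words")
  w1 <- window_session(session_log(rbind(base, extra), session_length = 10))
  expect_true(all(w1$speech_present >= w0$speech_present))
  expect_true(all(w1$controller_active >= w0$controller_active))
  expect_true(all(w1$gaze_present >= w0$gaze_present))
  expect_true(w1$speech_present[w1$window == 4])
})

test_that("distance deltas carry the last known distance across windows", {
  rec <- rbind(make_record(0.0, "P1", object_distance = 10),
               make_record(1.5, "P1", object_distance = 8),
               make_record(3.5, "P1", object_distance = 8))
  log <- session_log(rec, session_length = 4)
  w <- window_session(log, tick = 1)
  expect_equal(w$dist_delta, c(0, -2, 0, 0))
})
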