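test_that("the feature-to-dimension incidence map is frozen", {
  fmap <- dimension_feature_map()
  expect_equal(names(fmap), collaboration_dimensions())
  expect_equal(fmap$DialogueManagement,
               c("initiation_count", "da_Acks", "da_Neg", "da_Conv"))
  expect_equal(fmap$InformationPooling,
               c("piece_shared_count", "da_Ques", "da_Read", "da_Inform"))
  expect_equal(fmap$ReciprocalInteraction,
               c("active_effort_total", "da_Pos", "da_Acks"))
  expect_equal(fmap$TaskDivisionCoordination,
               c("gaze_at_object", "piece_shared_count",
                 "active_effort_total", "da_Inform"))
  expect_equal(fmap$TimeManagement, "gaze_at_timebar")
  # the Out class feeds no dimension
  expect_false(any(grepl("da_Out", unlist(fmap))))
})

feat_row <- function(player = "P1", ...) {
  base <- data.frame(player = player, initiation_count = 0,
                     da_Acks = 0, da_Neg = 0, da_Pos = 0, da_Ques = 0,
                     da_Read = 0, da_Inform = 0, da_Conv = 0, da_Out = 0,
                     piece_shared_count = 0, active_effort_total = 0,
                     gaze_at_object = 0, gaze_at_partner = 0,
                     gaze_at_timebar = 0, task_score = 0,
                     individual_score = 0, game_duration = 480,
                     stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

test_that("all-zero features give an all-zero profile under rate normalization", {
  prof <- score_dimensions(feat_row())
  expect_equal(unlist(prof[collaboration_dimensions()]), rep(0, 5),
               ignore_attr = TRUE)
  expect_equal(attr(prof, "provenance"), dimension_feature_map())
})

test_that("time management depends only on timer-bar fixations", {
  f1 <- feat_row(gaze_at_timebar = 6, da_Inform = 5, piece_shared_count = 3)
  f2 <- feat_row(gaze_at_timebar = 6, da_Inform = 10, piece_shared_count = 6,
                 active_effort_total = 100, initiation_count = 4)
  p1 <- score_dimensions(f1); p2 <- score_dimensions(f2)
  expect_equal(p1$TimeManagement, p2$TimeManagement)
  expect_true(p2$InformationPooling > p1$InformationPooling)
})

test_that("a shared feature moves every dimension it belongs to", {
  base <- feat_row()
  more <- feat_row(piece_shared_count = 8)
  pb <- score_dimensions(base); pm <- score_dimensions(more)
  expect_gt(pm$InformationPooling, pb$InformationPooling)
  expect_gt(pm$TaskDivisionCoordination, pb$TaskDivisionCoordination)
  expect_equal(pm$DialogueManagement, pb$DialogueManagement)
  expect_equal(pm$TimeManagement, pb$TimeManagement)
})

test_that("rates are invariant to proportional scaling of session length", {
  f <- feat_row(initiation_count = 4, da_Acks = 6, piece_shared_count = 3,
                active_effort_total = 120, gaze_at_object = 50,
                gaze_at_timebar = 5)
  doubled <- f
  for (col in unique(unlist(dimension_feature_map()))) doubled[[col]] <- f[[col]] * 2
  doubled$game_duration <- f$game_duration * 2
  expect_equal(unlist(score_dimensions(f)[collaboration_dimensions()]),
               unlist(score_dimensions(doubled)[collaboration_dimensions()]))
})

test_that("z-score normalization centers the cohort", {
  cohort <- rbind(feat_row("P1", da_Acks = 2), feat_row("P2", da_Acks = 8))
  prof <- score_dimensions(cohort, "zscore")
  for (dim in collaboration_dimensions()) {
    expect_equal(mean(prof[[dim]]), 0, tolerance = 1e-12)
  }
  expect_error(score_dimensions(cohort, "rank"), "arg")
})

test_that("dimension effects aggregate as the mean absolute d", {
  expect_equal(unname(aggregate_dimension_effects(list(A = c(0.5, -0.9)))), 0.7)
  expect_equal(unname(aggregate_dimension_effects(list(A = -0.3))), 0.3)
  expect_equal(unname(aggregate_dimension_effects(list(A = c(0, 0, 0)))), 0)
  expect_error(aggregate_dimension_effects(list(A = numeric(0))), "no constituent")
  # named per-feature vector routed through the frozen map
  d <- c(initiation_count = 0.4, da_Acks = -0.6, da_Neg = 0.2, da_Conv = 0,
         gaze_at_timebar = -1.1)
  agg <- aggregate_dimension_effects(d[c("initiation_count", "da_Acks",
                                         "da_Neg", "da_Conv", "gaze_at_timebar")],
                                     dimension_feature_map()[c("DialogueManagement",
                                                               "TimeManagement")])
  expect_equal(unname(agg["DialogueManagement"]), mean(abs(d[1:4])))
  expect_equal(unname(agg["TimeManagement"]), 1.1)
})

test_that("feature extraction counts events and excludes Out downstream", {
  rec <- rbind(
    make_records(c(10, 20, 30, 40), "P1", piece_shared = paste0("p", 1:4),
                 shared_count = 1:4),
    make_records(seq(1, 55, by = 1), "P2"))
  rec$active_effort[rec$player == "P2"][1:10] <- 1
  log <- session_log(rec, session_length = 60)
  feats <- extract_features(log)
  expect_equal(feats$piece_shared_count[feats$player == "P1"], 4)
  expect_equal(feats$active_effort_total[feats$player == "P2"], 10)
  # empty session yields all-zero counts
  empty <- session_log(make_records(0, "P1"), session_length = 10)
  f0 <- extract_features(empty)
  expect_true(all(f0[grep("^da_", names(f0))] == 0))
  expect_equal(f0$initiation_count, c(0, 0))
})

test_that("profiles are invariant to record ordering within a session", {
  sim <- simulate_session(preset_scenarios(seed = 4)$observe_baseline)
  rec <- sim$log$records
  set.seed(8)
  shuffled <- rec[sample(nrow(rec)), ]
  log2 <- session_log(shuffled, group = sim$log$group,
                      session_length = sim$log$session_length)
  f1 <- extract_features(sim$log)
  f2 <- extract_features(log2)
  expect_equal(f1, f2)
})
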