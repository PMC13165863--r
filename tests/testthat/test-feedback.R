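test_that("an all-Engaged dyad stays in Observe with no prompts", {
  n <- 80
  tr <- run_fsm(make_timeline(rep("Engaged", n)),
                make_timeline(rep("Engaged", n), "P2"))
  expect_equal(tr$states$state, "Observe")
  expect_equal(nrow(tr$prompts), 0)
  expect_length(tr$auto_completions, 0)
})

test_that("sustained Waiting prompts at +30 s and escalates at +60 s", {
  tr <- run_fsm(make_timeline(rep("Waiting", 70)),
                make_timeline(rep("Engaged", 70), "P2"))
  expect_equal(tr$prompts$time, c(30, 30, 60))
  expect_equal(tr$prompts$template_id,
               c("redirect_waiting", "redirect_partner", "redirect_escalate"))
  expect_equal(tr$prompts$recipient, c("P1", "P2", "both"))
  expect_equal(tr$prompts$text[1], "Please wait for your partner to finish")
})

test_that("sustained Struggling prompts at +30 s and auto-completes at +60 s", {
  tr <- run_fsm(make_timeline(rep("Struggling", 90)),
                make_timeline(rep("Engaged", 90), "P2"))
  p <- tr$prompts
  expect_equal(p$time[p$template_id == "assist_struggling"], 30)
  expect_equal(p$recipient[p$template_id == "assist_struggling"], "P1")
  expect_equal(p$time[p$template_id == "assist_partner"], 30)
  expect_equal(tr$auto_completions, 60)
  # after auto-completion the machine passes through Observe with timers
  # cleared (the still-Struggling dyad then re-enters Assist afresh)
  st <- tr$states
  expect_true("Observe" %in% st$state[st$time > 60])
  expect_false(any(p$time > 60 & p$time < 90))
})

test_that("a dyad Struggling together enters Intervene and auto-completes", {
  tr <- run_fsm(make_timeline(rep("Struggling", 90)),
                make_timeline(rep("Struggling", 90), "P2"))
  expect_true("Intervene" %in% tr$states$state)
  p <- tr$prompts
  expect_equal(p$time[p$template_id == "intervene_help"], 30)
  expect_equal(p$recipient[p$template_id == "intervene_help"], "both")
  expect_equal(tr$auto_completions, 60)
})

test_that("task completion fires positive feedback for one tick then returns to Observe", {
  tr <- run_fsm(make_timeline(rep("Engaged", 50)),
                make_timeline(rep("Engaged", 50), "P2"),
                task_events = data.frame(time = 20, kind = "step"))
  st <- tr$states
  expect_equal(st$state, c("Observe", "PositiveFeedback", "Observe"))
  expect_equal(st$time, c(0, 20, 21))
  expect_equal(tr$prompts$template_id, "positive_step")
  expect_equal(tr$prompts$text, "Good job!")

  tr2 <- run_fsm(make_timeline(rep("Engaged", 50)),
                 make_timeline(rep("Engaged", 50), "P2"),
                 task_events = data.frame(time = 10, kind = "task"))
  expect_equal(tr2$prompts$template_id, "positive_task")
})

test_that("no prompt ever fires before 30 s of continuous condition", {
  set.seed(23)
  for (rep in 1:20) {
    # random bursts of breakdown states, each at most 29 windows long
    s1 <- character(0)
    while (length(s1) < 120) {
      s1 <- c(s1, rep("Engaged", sample(1:10, 1)),
              rep(sample(c("Waiting", "Struggling"), 1), sample(1:29, 1)))
    }
    s1 <- s1[1:120]
    tr <- run_fsm(make_timeline(s1), make_timeline(rep("Engaged", 120), "P2"))
    expect_equal(nrow(tr$prompts), 0, info = paste("rep", rep))
  }
})

test_that("a 29 s burst resets the timer; prompts need fresh persistence", {
  s1 <- c(rep("Waiting", 29), "Engaged", rep("Waiting", 29), rep("Engaged", 21))
  tr <- run_fsm(make_timeline(s1), make_timeline(rep("Engaged", 80), "P2"))
  expect_equal(nrow(tr$prompts), 0)
})

test_that("the dyad-state priority table matches the hand oracle exactly", {
  states <- behavior_states()
  for (s1 in states) for (s2 in states) {
    got <- dyadsense:::.fsm_target(s1, s2)
    expect_equal(got, oracle_fsm_state(s1, s2), info = paste(s1, s2))
  }
})

test_that("traces are deterministic and mismatched timelines are rejected", {
  s1 <- make_timeline(rep(c("Waiting", "Engaged"), each = 40))
  s2 <- make_timeline(rep("Engaged", 80), "P2")
  a <- run_fsm(s1, s2)
  b <- run_fsm(s1, s2)
  expect_identical(a, b)
  expect_error(run_fsm(make_timeline(rep("Engaged", 5)),
                       make_timeline(rep("Engaged", 6), "P2")), "length")
  # empty timelines yield the initial Observe only
  tr0 <- run_fsm(make_timeline(character(0)), make_timeline(character(0), "P2"))
  expect_equal(tr0$states$state, "Observe")
})

test_that("swapping which player waits resets the persistence timer", {
  s1 <- c(rep("Waiting", 20), rep("Engaged", 40))
  s2 <- c(rep("Engaged", 20), rep("Waiting", 40))
  tr <- run_fsm(make_timeline(s1), make_timeline(s2, "P2"))
  # P2's waiting run starts at t=20; its prompt must be at 50, not 30
  expect_equal(min(tr$prompts$time), 50)
  expect_equal(tr$prompts$recipient[tr$prompts$template_id == "redirect_waiting"], "P2")
})

test_that("prompt catalogues round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_prompt_catalogue(default_prompt_catalogue(), path)
  back <- read_prompt_catalogue(path)
  expect_equal(back, default_prompt_catalogue())
})
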