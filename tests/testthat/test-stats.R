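test_that("Cohen's d follows its definition and bands", {
  expect_error(cohens_d(c(1, 1, 1), c(1, 1, 1)), "zero")
  # means one pooled SD apart give d = 1, large
  a <- c(1, 2, 3, 4, 5)
  b <- a + sd(a)
  es <- cohens_d(b, a)
  expect_equal(es$d, 1)
  expect_equal(es$band, "large")
  # paired definition: mean(diff)/sd(diff)
  x <- c(1, 2, 3, 4); y <- c(2, 2, 5, 5)
  es2 <- cohens_d(x, y, "paired")
  expect_equal(es2$d, mean(x - y) / sd(x - y))
  # band thresholds
  expect_equal(effect_band(c(0.1, 0.2, 0.5, 0.79, 0.85)),
               c("negligible", "small", "medium", "medium", "large"))
  # sign anti-symmetry
  set.seed(9)
  for (rep in 1:10) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(cohens_d(u, v)$d, -cohens_d(v, u)$d)
    expect_equal(cohens_d(u, v, "paired")$d, -cohens_d(v, u, "paired")$d)
  }
  # Hedges correction shrinks toward zero
  expect_lt(abs(cohens_d(b, a, hedges = TRUE)$d), 1)
})

test_that("t-tests agree with the reference implementation", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 5, 4)
  got <- t_test(a, b, "paired")
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$ci95, as.numeric(ref$conf.int))

  set.seed(17)
  for (rep in 1:10) {
    u <- rnorm(7, 1); v <- rnorm(9)
    got <- t_test(u, v, "independent")
    ref <- t.test(u, v, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
    expect_equal(got$ci95, as.numeric(ref$conf.int))
  }
  # degenerate cases
  expect_equal(t_test(c(1, 5, 3), c(1, 5, 3), "independent")$statistic, 0)
  expect_error(t_test(c(0, 0, 0), c(0, 0, 0), "paired"), "zero")
  # one-sided p-values split the two-sided mass
  g <- t_test(a, b, "paired", "less")
  expect_lt(g$p_value, 0.5)
})

test_that("paired all-zero differences give t = 0 via constant shift", {
  # all differences equal but nonzero SD is impossible; use symmetric case
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  got <- t_test(a, b, "paired")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("BH adjustment matches hand computations and the brute-force oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(0.5, 6)), rep(0.5, 6))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # order preserving: adjustment never reorders the evidence
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("power equals alpha at d = 0 and is monotone in n, |d| and alpha", {
  expect_equal(posthoc_power(0, 6, design = "paired")$power, 0.05)
  expect_equal(posthoc_power(0, 10, design = "independent", alpha = 0.1)$power, 0.1)
  expect_gt(posthoc_power(1, 12, design = "independent")$power,
            posthoc_power(1, 6, design = "independent")$power)
  expect_gt(posthoc_power(1.5, 8, design = "paired")$power,
            posthoc_power(0.8, 8, design = "paired")$power)
  expect_gt(posthoc_power(1, 8, alpha = 0.1, design = "paired")$power,
            posthoc_power(1, 8, alpha = 0.01, design = "paired")$power)
  # converges to 1 with n
  expect_gt(posthoc_power(0.5, 400, design = "independent")$power, 0.999)
})

test_that("power agrees with the reference noncentral-t routine", {
  for (d in c(0.3, 0.8, 1.5)) for (n in c(6, 12, 30)) {
    ref <- power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05,
                        type = "two.sample", strict = TRUE)$power
    got <- posthoc_power(d, n, design = "independent")$power
    expect_equal(got, ref, tolerance = 1e-6, info = paste(d, n))
    ref_p <- power.t.test(n = n, delta = d, sd = 1, type = "paired",
                          strict = TRUE)$power
    got_p <- posthoc_power(d, n, design = "paired")$power
    expect_equal(got_p, ref_p, tolerance = 1e-6)
  }
})

test_that("t-test p-values are uniform under the null", {
  set.seed(77)
  reps <- 10000; n <- 10
  x <- matrix(rnorm(reps * n), nrow = n)
  # vectorized one-sample t on the columns (paired with a zero partner)
  tstat <- colMeans(x) / (apply(x, 2, sd) / sqrt(n))
  p <- 2 * pt(-abs(tstat), n - 1)
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
  # spot-check the vectorized statistic against the package implementation
  i <- c(1, 500, 9999)
  for (k in i) {
    expect_equal(t_test(x[, k], rep(0, n), "paired")$statistic, tstat[k])
  }
})

test_that("the battery table assembles all layers consistently", {
  set.seed(41)
  df <- data.frame(id = rep(1:8, 2),
                   phase = rep(c("pre", "post"), each = 8),
                   score = c(rnorm(8, 50, 10), rnorm(8, 60, 10)),
                   effort = c(rnorm(8, 250, 40), rnorm(8, 210, 40)))
  out <- stat_battery(df, c("score", "effort"), "phase", "paired", id = "id")
  expect_equal(nrow(out), 2)
  expect_true(all(out$p_adj >= out$p_raw))
  expect_true(all(out$ci_low <= out$ci_high))
  expect_true(all(out$band %in% c("negligible", "small", "medium", "large")))
  expect_true(all(out$power >= 0 & out$power <= 1))
  expect_equal(out$p_adj, benjamini_hochberg(out$p_raw))
})
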