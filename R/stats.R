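#' Cohen's d standardized mean difference
#'
#' For independent samples, the mean difference divided by the pooled
#' standard deviation (variances pooled with `n - 1` weights); for
#' paired samples, the mean of the differences divided by their
#' standard deviation. The magnitude is banded with the conventional
#' thresholds: |d| < 0.2 negligible, 0.2–0.5 small, 0.5–0.8 medium,
#' >= 0.8 large. An optional small-sample (Hedges) correction
#' multiplies d by `1 - 3/(4*df - 1)`; it is off by default.
#'
#' @param a,b Numeric samples (equal length when paired).
#' @param design `"independent"` or `"paired"`.
#' @param hedges Apply the small-sample correction (default `FALSE`).
#' @return List of class `effect_size`: `d`, `design`, `band`.
#' @export
cohens_d <- function(a, b, design = c("independent", "paired"), hedges = FALSE) {
  design <- match.arg(design)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 observations per sample", call. = FALSE)
  if (design == "paired") {
    if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
    diffs <- a - b
    s <- stats::sd(diffs)
    if (s == 0) stop("zero variance of differences: Cohen's d undefined", call. = FALSE)
    d <- mean(diffs) / s
    df <- length(a) - 1
  } else {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    if (sp2 == 0) stop("zero pooled variance: Cohen's d undefined", call. = FALSE)
    d <- (mean(a) - mean(b)) / sqrt(sp2)
    df <- na + nb - 2
  }
  if (hedges) d <- d * (1 - 3 / (4 * df - 1))
  structure(list(d = d, design = design, band = effect_band(d)), class = "effect_size")
}

#' Interpretation band for an effect size
#'
#' @param d Numeric Cohen's d (vectorized).
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`, using the
#'   0.2 / 0.5 / 0.8 thresholds on |d|.
#' @export
effect_band <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "negligible",
         ifelse(a < 0.5, "small",
                ifelse(a < 0.8, "medium", "large")))
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s, %s)\n", x$d, x$design, x$band))
  invisible(x)
}

#' Paired or independent t-test with a 95% CI on the mean difference
#'
#' Classical Student t-test computed from closed forms: paired uses the
#' differences; independent uses the pooled-variance two-sample
#' statistic (consistent with the pooled-SD convention in
#' [cohens_d()]).
#'
#' @param a,b Numeric samples.
#' @param design `"independent"` or `"paired"`.
#' @param sidedness `"two.sided"`, `"greater"` or `"less"`.
#' @param conf.level CI coverage (default 0.95).
#' @return List of class `dyad_test`: `statistic`, `df`, `p_value`,
#'   `ci95`, `estimate` (mean difference), `design`, `sidedness`.
#' @export
t_test <- function(a, b, design = c("independent", "paired"),
                   sidedness = c("two.sided", "greater", "less"),
                   conf.level = 0.95) {
  design <- match.arg(design)
  sidedness <- match.arg(sidedness)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 observations per sample", call. = FALSE)
  if (design == "paired") {
    if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
    diffs <- a - b
    n <- length(diffs)
    se <- stats::sd(diffs) / sqrt(n)
    est <- mean(diffs)
    df <- n - 1
  } else {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    est <- mean(a) - mean(b)
    df <- na + nb - 2
  }
  if (se == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  tstat <- est / se
  p <- switch(sidedness,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  alpha <- 1 - conf.level
  crit <- stats::qt(1 - alpha / 2, df)
  structure(list(statistic = tstat, df = df, p_value = p,
                 ci95 = c(est - crit * se, est + crit * se),
                 estimate = est, design = design, sidedness = sidedness),
            class = "dyad_test")
}

#' @export
print.dyad_test <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, diff = %.3f, 95%% CI [%.3f, %.3f] (%s)\n",
              x$df, x$statistic, x$p_value, x$estimate, x$ci95[1], x$ci95[2], x$design))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: sort ascending, scale the i-th by `m/i`,
#' enforce monotonicity from the largest rank down, cap at 1, and
#' return in the original order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Post hoc power from the noncentral t distribution
#'
#' Exact power of a t-test at an observed standardized effect size.
#' For a paired (or one-sample) design with `n` pairs, the
#' noncentrality parameter is `d * sqrt(n)` on `n - 1` degrees of
#' freedom; for a two-sample design with `n` per group it is
#' `d * sqrt(n/2)` on `2n - 2`. Two-sided power is
#' `P(T_ncp > t_crit) + P(T_ncp < -t_crit)` at the `1 - alpha/2`
#' critical value; one-sided power uses the `1 - alpha` value. At
#' `d = 0`, power equals `alpha` by construction.
#'
#' @param d Observed Cohen's d.
#' @param n Pairs (paired) or per-group size (independent); `n >= 2`.
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param design `"paired"` or `"independent"`.
#' @param sidedness `"two.sided"` or `"one.sided"`.
#' @return List of class `power_result`: `power`, `d`, `n`, `alpha`,
#'   `design`, `sidedness`, `df`, `ncp`.
#' @export
posthoc_power <- function(d, n, alpha = 0.05,
                          design = c("paired", "independent"),
                          sidedness = c("two.sided", "one.sided")) {
  design <- match.arg(design)
  sidedness <- match.arg(sidedness)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  if (design == "paired") {
    df <- n - 1
    ncp <- d * sqrt(n)
  } else {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
  }
  if (sidedness == "two.sided") {
    crit <- stats::qt(1 - alpha / 2, df)
    power <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
             stats::pt(-crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    power <- stats::pt(crit, df, ncp = abs(ncp), lower.tail = FALSE)
  }
  structure(list(power = power, d = d, n = n, alpha = alpha,
                 design = design, sidedness = sidedness, df = df, ncp = ncp),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("post hoc power = %.3f (d = %.2f, n = %d, alpha = %.3f, %s %s)\n",
              x$power, x$d, x$n, x$alpha, x$design, x$sidedness))
  invisible(x)
}

#' Run the full effect-size battery over a tidy feature table
#'
#' For each measure column, compares the two conditions with the chosen
#' design, reporting the mean difference with 95% CI, raw and
#' BH-adjusted p-values, Cohen's d with its interpretation band, and
#' post hoc power. A thin convenience wrapper over [t_test()],
#' [cohens_d()], [benjamini_hochberg()] and [posthoc_power()]; nested
#' model fitting (mixed models, MANOVA, regression) is delegated to
#' standard modeling tools and is outside this battery.
#'
#' @param data Data frame in long-by-observation form.
#' @param measures Character vector of measure column names.
#' @param condition Name of the two-level condition column.
#' @param design `"paired"` (rows matched by `id` within condition,
#'   sorted) or `"independent"`.
#' @param id Optional unit-id column used to order paired observations.
#' @param alpha Alpha for the power computation.
#' @return Data frame: one row per measure with `estimate`, `ci_low`,
#'   `ci_high`, `t`, `df`, `p_raw`, `p_adj`, `d`, `band`, `power`.
#' @export
stat_battery <- function(data, measures, condition, design = c("independent", "paired"),
                         id = NULL, alpha = 0.05) {
  design <- match.arg(design)
  lev <- unique(as.character(data[[condition]]))
  if (length(lev) != 2) stop("condition column must have exactly two levels", call. = FALSE)
  rows <- lapply(measures, function(m) {
    da <- data[data[[condition]] == lev[1], , drop = FALSE]
    db <- data[data[[condition]] == lev[2], , drop = FALSE]
    if (!is.null(id)) {
      da <- da[order(da[[id]]), , drop = FALSE]
      db <- db[order(db[[id]]), , drop = FALSE]
    }
    a <- da[[m]]; b <- db[[m]]
    tt <- t_test(a, b, design)
    es <- cohens_d(a, b, design)
    n_pow <- if (design == "paired") length(a) else min(length(a), length(b))
    pw <- posthoc_power(es$d, n_pow, alpha, design = design)
    data.frame(measure = m, estimate = tt$estimate,
               ci_low = tt$ci95[1], ci_high = tt$ci95[2],
               t = tt$statistic, df = tt$df, p_raw = tt$p_value,
               d = es$d, band = es$band, power = pw$power,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p_raw)
  out <- out[c("measure", "estimate", "ci_low", "ci_high", "t", "df",
               "p_raw", "p_adj", "d", "band", "power")]
  rownames(out) <- NULL
  out
}
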