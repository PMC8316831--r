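## Cross-proficiency and cross-modality statistics over a per-corpus
## metrics table: simple OLS trend regressions (proficiency coded 1..4 for
## learner levels, 5 for the native reference), pooled and Welch
## two-sample t-tests on learner levels, and Pearson correlations.  The
## closed-form implementations are deliberately explicit; the test suite
## cross-checks them against stats::lm / stats::t.test.

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with intercept.  The slope p-value
#' is the two-sided t-test on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @return List with `slope`, `intercept`, `R2`, `p_slope`, `se_slope`,
#'   `n`, `df`.
#' @export
ols_simple <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop_validation("need n >= 3 paired observations")
  if (var(x) == 0) stop_validation("x is constant")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  df <- n - 2
  se <- sqrt(ss_res / df / sxx)
  tval <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (is.finite(tval)) 2 * pt(-abs(tval), df) else 0
  list(slope = slope, intercept = intercept, R2 = r2, p_slope = p,
       se_slope = se, t = tval, n = n, df = df)
}

#' Two-sample t-test (pooled or Welch)
#'
#' `variant = "pooled"` assumes a common variance (`df = n_a + n_b - 2`);
#' `variant = "welch"` uses unpooled standard errors with the
#' Welch-Satterthwaite degrees of freedom.  The p-value is two-sided.
#' The statistic is for `mean(a) - mean(b)`.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `variant`, `t`, `df`, `p`, `mean_a`, `mean_b`, `diff`.
#' @export
t_test2 <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_validation("each sample needs >= 2 observations")
  va <- var(a); vb <- var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0 && ma == mb)
    stop_validation("zero variance in both samples with equal means: t undefined")
  if (variant == "pooled") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tval <- (ma - mb) / se
  p <- 2 * pt(-abs(tval), df)
  list(variant = variant, t = tval, df = df, p = p,
       mean_a = ma, mean_b = mb, diff = ma - mb)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return List with `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop_validation("need n >= 3 paired observations")
  if (var(x) == 0 || var(y) == 0) stop_validation("constant input")
  r <- sum(scale(x) * scale(y)) / (n - 1)
  df <- n - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)
  list(r = r, t = tval, df = df, p = p, n = n)
}

#' Default battery plan
#'
#' Which t-test variant each panel metric uses in [run_battery()], and
#' whether the native reference enters the trend regressions (it does, at
#' proficiency code 5).  The variant mapping follows the degrees of
#' freedom of the published comparisons this battery reproduces: Welch for
#' `<k>` and `NC`, pooled for `L`, `C`, `ND`; `gamma_prime` has no
#' documented variant and defaults to Welch.
#'
#' @return A list with `t_variant` (named character) and
#'   `native_in_regression` (logical).
#' @export
default_battery_plan <- function() {
  list(
    t_variant = c(k_mean = "welch", NC = "welch",
                  L = "pooled", C = "pooled", ND = "pooled",
                  gamma_prime = "welch"),
    native_in_regression = TRUE)
}

## proficiency code: learner levels 1..4, native = 5
level_code <- function(level) {
  ifelse(level == "native", 5, suppressWarnings(as.numeric(level)))
}

#' Run the cross-level / cross-modality statistical battery
#'
#' For each panel metric (`k_mean`, `gamma_prime`, `C`, `L`, `ND`, `NC`)
#' and each modality, fits the proficiency-trend regression (levels coded
#' 1..4 plus native = 5 when `native_in_regression`); and runs the
#' cross-modality two-sample t-test on the learner levels only (native
#' rows excluded), with the per-metric variant from the plan.  No
#' multiple-testing correction is applied.
#'
#' @param metrics_table Data.frame in the panel schema
#'   ([read_metrics_table()]) containing both modalities, learner levels
#'   1..4 and the native rows.
#' @param plan A plan list, see [default_battery_plan()].
#' @return A `battery_report` list: per metric, `regression$written`,
#'   `regression$oral` and `t_test`.
#' @export
run_battery <- function(metrics_table, plan = default_battery_plan()) {
  tab <- metrics_table
  tab$code <- level_code(tab$level)
  need_levels <- c(as.character(1:4), "native")
  for (mod in c("written", "oral")) {
    have <- tab$level[tab$modality == mod]
    absent <- setdiff(need_levels, have)
    if (length(absent))
      stop_validation("missing rows: modality '%s' lacks level(s) %s",
                      mod, paste(absent, collapse = ", "))
  }
  metrics <- c("k_mean", "gamma_prime", "C", "L", "ND", "NC")
  out <- lapply(metrics, function(m) {
    reg <- lapply(c(written = "written", oral = "oral"), function(mod) {
      rows <- tab[tab$modality == mod &
                    (plan$native_in_regression | tab$level != "native"), ]
      rows <- rows[order(rows$code), ]
      ols_simple(rows$code, rows[[m]])
    })
    a <- tab[tab$modality == "written" & tab$level != "native", ]
    b <- tab[tab$modality == "oral" & tab$level != "native", ]
    a <- a[order(a$code), ]; b <- b[order(b$code), ]
    tt <- t_test2(a[[m]], b[[m]],
                  variant = plan$t_variant[[m]] %||% "pooled")
    list(metric = m, regression = reg, t_test = tt)
  })
  names(out) <- metrics
  structure(list(metrics = out, plan = plan), class = "battery_report")
}

#' Flatten a battery report to a data.frame
#'
#' One row per metric: regression slope/intercept/R2/p per modality and
#' the cross-modality t statistic, df and p.
#'
#' @param report A `battery_report`.
#' @return A data.frame.
#' @export
battery_as_table <- function(report) {
  do.call(rbind, lapply(report$metrics, function(e) {
    data.frame(
      metric = e$metric,
      slope_written = e$regression$written$slope,
      intercept_written = e$regression$written$intercept,
      R2_written = e$regression$written$R2,
      p_written = e$regression$written$p_slope,
      slope_oral = e$regression$oral$slope,
      intercept_oral = e$regression$oral$intercept,
      R2_oral = e$regression$oral$R2,
      p_oral = e$regression$oral$p_slope,
      t = e$t_test$t, t_df = e$t_test$df, t_p = e$t_test$p,
      t_variant = e$t_test$variant,
      stringsAsFactors = FALSE)
  }))
}
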