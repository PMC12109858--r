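#' Per-skill dispersion of speed and accuracy
#'
#' Sample variance (divisor `n - 1`) and standard deviation of the speed
#' and accuracy channels, per skill. Skills with fewer than two records are
#' omitted with a warning (their variance is undefined).
#'
#' @param records A data.frame with columns `skill`, `speed`, `accuracy`
#'   (raw measurements, any units).
#' @return A data.frame with columns `skill`, `speed_variance`,
#'   `speed_sd`, `accuracy_variance`, `accuracy_sd`, `n`.
#' @export
per_skill_stats <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("skill", "speed", "accuracy") %in% names(records)))
  out <- lapply(split(records, records$skill), function(g) {
    if (nrow(g) < 2L) return(NULL)
    data.frame(skill = g$skill[1L],
               speed_variance = stats::var(g$speed),
               speed_sd = stats::sd(g$speed),
               accuracy_variance = stats::var(g$accuracy),
               accuracy_sd = stats::sd(g$accuracy),
               n = nrow(g), stringsAsFactors = FALSE)
  })
  dropped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(dropped) > 0L)
    warning("skills omitted (fewer than 2 records): ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation with a regression-error slot
#'
#' Standard product-moment correlation of two equal-length series, as used
#' for the speed-accuracy trade-off analysis. The `se_estimate` slot is
#' the standard error of the estimate of the regression of `y` on `x`
#' (the residual standard deviation, `sqrt(SSE / (n - 2))`) — a
#' precision-of-prediction figure, not the sampling standard error of `r`.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A list of class `correlation_result` with `r`, `n`,
#'   `se_estimate`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  se <- sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2L))
  structure(list(r = r, n = length(x), se_estimate = se),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f (n = %d, SE of estimate = %.4f)\n",
              x$r, x$n, x$se_estimate))
  invisible(x)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances
#' (Welch 1951). With groups of size `n_i`, mean `m_i` and variance
#' `s_i^2`, the precision weights are `w_i = n_i / s_i^2`, the weighted
#' grand mean is `sum(w_i m_i) / sum(w_i)`, and
#' \deqn{F^* = \frac{\sum_i w_i (m_i - \bar{m}_w)^2 / (k - 1)}
#'            {1 + \frac{2(k-2)}{k^2-1} \sum_i \frac{(1 - w_i/\sum w)^2}{n_i - 1}}}
#' with numerator degrees of freedom `k - 1` and Satterthwaite-type
#' denominator degrees of freedom
#' `df2 = (k^2 - 1) / (3 sum_i (1 - w_i/sum w)^2 / (n_i - 1))`. The
#' p-value comes from the F distribution.
#'
#' @param groups A list of >= 2 numeric vectors, each with >= 2 values and
#'   positive variance.
#' @return A list of class `welch_anova` with `F`, `df1`, `df2`,
#'   `p_value`, `k`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2L)) stop("every group needs at least 2 values")
  s2 <- vapply(groups, stats::var, numeric(1))
  if (any(s2 <= 0)) stop("zero-variance group: Welch weights undefined")
  m <- vapply(groups, mean, numeric(1))
  k <- length(groups)
  w <- n / s2
  mw <- sum(w * m) / sum(w)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  f <- a / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2 <- (k^2 - 1) / (3 * lam)
  structure(list(F = f, df1 = k - 1, df2 = df2,
                 p_value = stats::pf(f, k - 1, df2, lower.tail = FALSE),
                 k = k),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F(%d, %.2f) = %.4f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' A-priori power analysis for a paired (one-sample) t test
#'
#' Finds the smallest sample size `N >= 2` such that a two-tailed paired
#' t test with `df = N - 1`, significance level `alpha` and effect size
#' `dz` (the mean of the paired differences in units of their standard
#' deviation) reaches the target power. At each candidate `N` the
#' noncentrality parameter is `delta = dz * sqrt(N)`, the critical value
#' is `t_crit = qt(1 - alpha/2, N - 1)`, and the rejection probability is
#' computed from the noncentral t distribution,
#' `P(|T| > t_crit) = 1 - pt(t_crit, df, delta) + pt(-t_crit, df, delta)`.
#'
#' @param dz Effect size (> 0).
#' @param alpha Two-tailed significance level in `(0, 1)` (default 0.05).
#' @param target_power Desired power in `(0, 1)` (default 0.95).
#' @param n_max Search bound (an error is thrown if the target is not
#'   reached by then).
#' @return A list of class `power_result` with `N`, `delta`, `t_crit`,
#'   `achieved_power`, `dz`, `alpha`, `target_power`.
#' @examples
#' power_paired_t(0.56, 0.05, 0.95)  # N = 44
#' @export
power_paired_t <- function(dz, alpha = 0.05, target_power = 0.95,
                           n_max = 1e6) {
  stopifnot(dz > 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  for (n in 2:n_max) {
    df <- n - 1
    delta <- dz * sqrt(n)
    t_crit <- stats::qt(1 - alpha / 2, df)
    pw <- 1 - stats::pt(t_crit, df, ncp = delta) +
      stats::pt(-t_crit, df, ncp = delta)
    if (pw >= target_power) {
      return(structure(list(N = n, delta = delta, t_crit = t_crit,
                            achieved_power = pw, dz = dz, alpha = alpha,
                            target_power = target_power),
                       class = "power_result"))
    }
  }
  stop("target power not attainable with N <= ", n_max)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("Paired t power analysis: dz = %.2f, alpha = %.3f, ",
                     "target power = %.2f\n  N = %d, delta = %.4f, ",
                     "t_crit = %.4f (df = %d), achieved power = %.4f\n"),
              x$dz, x$alpha, x$target_power, x$N, x$delta, x$t_crit,
              x$N - 1L, x$achieved_power))
  invisible(x)
}

#' Summarize session logs into a metric table
#'
#' Aggregates a cohort of session logs into per-metric mean/min/max/count
#' rows. "Level" is the 1-based difficulty level of a skill
#' (`difficulty_rank + 1`). Metrics:
#'
#' * `correct_answers_level`, `wrong_answers_level`,
#'   `specific_wrong_level` — per session, the mean level of the tasks
#'   answered correctly / wrongly / with a specific (case-matching) wrong
#'   answer;
#' * `correct_answers_questions`, `wrong_answers_questions`,
#'   `specific_wrong_questions` — per session and skill, the count of such
#'   answers;
#' * `special_case` — per session with at least one specific wrong answer,
#'   the count of distinct error cases observed.
#'
#' Level metrics are summarized over the sessions in which they are
#' defined, question metrics over the (session, skill) groups in which at
#' least one answer of the kind occurred (for the specific-wrong and
#' special-case rows) or over all groups (correct/wrong rows). An empty
#' metric yields `n = 0` with `NA` summaries.
#'
#' @param logs A list of `session_log`s (or a single one).
#' @param graph The [skill_graph()] the sessions ran on (for difficulty
#'   levels).
#' @return A data.frame with columns `metric`, `mean`, `min`, `max`, `n`.
#' @export
summarize_sessions <- function(logs, graph) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  stopifnot(length(logs) >= 1L, inherits(graph, "skill_graph"))
  level_of <- stats::setNames(graph$skills$difficulty_rank + 1,
                              graph$skills$id)
  per_session <- list(correct_answers_level = numeric(),
                      wrong_answers_level = numeric(),
                      specific_wrong_level = numeric(),
                      special_case = numeric())
  per_group <- list(correct_answers_questions = numeric(),
                    wrong_answers_questions = numeric(),
                    specific_wrong_questions = numeric())
  for (log in logs) {
    if (nrow(log) == 0L) next
    lev <- level_of[log$skill_id]
    specific <- log$error_case %in% error_cases
    if (any(log$correct))
      per_session$correct_answers_level <-
        c(per_session$correct_answers_level, mean(lev[log$correct]))
    if (any(!log$correct))
      per_session$wrong_answers_level <-
        c(per_session$wrong_answers_level, mean(lev[!log$correct]))
    if (any(specific)) {
      per_session$specific_wrong_level <-
        c(per_session$specific_wrong_level, mean(lev[specific]))
      per_session$special_case <-
        c(per_session$special_case, length(unique(log$error_case[specific])))
    }
    for (g in split(seq_len(nrow(log)), log$skill_id)) {
      per_group$correct_answers_questions <-
        c(per_group$correct_answers_questions, sum(log$correct[g]))
      per_group$wrong_answers_questions <-
        c(per_group$wrong_answers_questions, sum(!log$correct[g]))
      if (any(specific[g]))
        per_group$specific_wrong_questions <-
          c(per_group$specific_wrong_questions, sum(specific[g]))
    }
  }
  all_metrics <- c(per_session[c("correct_answers_level",
                                 "wrong_answers_level",
                                 "specific_wrong_level")],
                   per_group,
                   per_session["special_case"])
  rows <- lapply(names(all_metrics), function(nm) {
    v <- all_metrics[[nm]]
    if (length(v) == 0L)
      data.frame(metric = nm, mean = NA_real_, min = NA_real_,
                 max = NA_real_, n = 0L, stringsAsFactors = FALSE)
    else
      data.frame(metric = nm, mean = mean(v), min = min(v), max = max(v),
                 n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load the packaged per-skill speed/accuracy statistics
#'
#' Reads the packaged fixture of pre-assessment dispersion statistics
#' (11 skills; columns `skill`, `speed_variance`, `speed_sd`,
#' `accuracy_variance`, `accuracy_sd`), or any CSV with that layout.
#'
#' @param path Path to a CSV in the fixture layout; defaults to the
#'   packaged table.
#' @return A data.frame.
#' @export
read_skill_stats <- function(path = system.file("extdata",
                                                "preassessment_stats.csv",
                                                package = "knowtrace")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("skill", "speed_variance", "speed_sd", "accuracy_variance",
              "accuracy_sd")
  if (!all(needed %in% names(df)))
    stop("expected columns: ", paste(needed, collapse = ", "))
  df
}

#' Speed-accuracy correlation of a per-skill statistics table
#'
#' Correlates the speed and accuracy dispersion columns across skills, the
#' trade-off analysis of the pre-assessment: a negative `r` means skills
#' on which response speed varied more showed less accuracy variation (and
#' vice versa).
#'
#' @param stats A data.frame in the [read_skill_stats()] layout.
#' @param channel `"variance"` or `"sd"`: which pair of columns to
#'   correlate.
#' @return A [pearson_cor()] `correlation_result`.
#' @export
speed_accuracy_correlation <- function(stats,
                                       channel = c("variance", "sd")) {
  channel <- match.arg(channel)
  if (channel == "variance")
    pearson_cor(stats$speed_variance, stats$accuracy_variance)
  else
    pearson_cor(stats$speed_sd, stats$accuracy_sd)
}
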