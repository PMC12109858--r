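test_that("per-skill dispersion uses the n-1 divisor and sd^2 = variance", {
  rec <- data.frame(skill = rep(c("a", "b"), each = 4),
                    speed = c(1, 1, 1, 1, 2, 4, 6, 9),
                    accuracy = c(10, 12, 9, 11, 50, 50, 50, 50))
  st <- per_skill_stats(rec)
  expect_equal(st$speed_variance[st$skill == "a"], 0)
  expect_equal(st$accuracy_variance[st$skill == "b"], 0)
  expect_equal(st$speed_sd^2, st$speed_variance, tolerance = 1e-12)
  expect_equal(st$accuracy_sd^2, st$accuracy_variance, tolerance = 1e-12)

  # independent two-pass computation
  set.seed(181)
  x <- rnorm(37, 5, 2)
  rec <- data.frame(skill = "z", speed = x, accuracy = rev(x))
  st <- per_skill_stats(rec)
  two_pass <- sum((x - sum(x) / length(x))^2) / (length(x) - 1)
  expect_equal(st$speed_variance, two_pass, tolerance = 1e-9)

  expect_warning(
    per_skill_stats(data.frame(skill = c("a", "a", "lone"),
                               speed = 1:3, accuracy = 1:3)),
    "lone")
})

test_that("pearson_cor reproduces exact and affine-invariant cases", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -3 * x + 7)$r, -1)
  set.seed(191)
  y <- rnorm(20); z <- rnorm(20)
  r0 <- pearson_cor(y, z)$r
  expect_equal(pearson_cor(5 * y - 2, z)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(y, -2 * z + 4)$r, -r0, tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")
  expect_error(pearson_cor(1:4, 1:5), "equal length")
})

test_that("the packaged pre-assessment table gives the published trade-off correlations", {
  st <- read_skill_stats()
  expect_equal(nrow(st), 11L)
  rv <- speed_accuracy_correlation(st, "variance")
  rs <- speed_accuracy_correlation(st, "sd")
  expect_equal(rv$r, -0.5176, tolerance = 0.002 / 0.5176)
  expect_equal(rs$r, -0.5034, tolerance = 0.002 / 0.5034)
  expect_equal(rv$n, 11L)
})

test_that("welch_anova agrees with stats::oneway.test and an independent formula", {
  set.seed(201)
  for (rep in 1:40) {
    k <- sample(2:5, 1L)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(4:30, 1L), mean = runif(1, -2, 2),
            sd = runif(1, 0.3, 3)))
    got <- welch_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k),
                                    vapply(groups, length, integer(1)))))
    ref <- stats::oneway.test(y ~ g, data = df, var.equal = FALSE)
    expect_equal(got$F, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$df1, unname(ref$parameter[1]), tolerance = 1e-8)
    expect_equal(got$df2, unname(ref$parameter[2]), tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
    ora <- oracle_welch(groups)
    expect_equal(got$F, ora$F, tolerance = 1e-12)
    expect_equal(got$p_value, ora$p, tolerance = 1e-12)
  }
})

test_that("welch_anova approaches the classic F when variances and sizes are equal", {
  # equalize the sample variances so the premise holds exactly: the Welch
  # weights then coincide and F* differs from the classic F only by the
  # small denominator correction
  set.seed(211)
  for (rep in 1:10) {
    groups <- lapply(1:3, function(i)
      scale(rnorm(25))[, 1] * 1.3 + i * 0.5)
    got <- welch_anova(groups)
    df <- data.frame(y = unlist(groups), g = factor(rep(1:3, each = 25)))
    classic <- summary(stats::aov(y ~ g, data = df))[[1]]$`F value`[1]
    expect_lt(abs(got$F - classic) / classic, 0.05)
  }
})

test_that("welch_anova is well-calibrated under the null and rejects degenerate input", {
  expect_error(welch_anova(list(rep(1, 5), rnorm(5))), "zero-variance")
  expect_error(welch_anova(list(rnorm(5))), ".")
  set.seed(221)
  p <- vapply(1:200, function(i)
    welch_anova(lapply(1:3, function(j)
      rnorm(12, mean = 0, sd = j)))$p_value, numeric(1))
  expect_gt(mean(p), 0.4)   # uniform null p-values average 0.5
  expect_lt(mean(p), 0.6)
  expect_lt(mean(p < 0.05), 0.10)  # type-I error near nominal
})

test_that("paired-t power analysis reproduces the published planning numbers", {
  res <- power_paired_t(0.56, 0.05, 0.95)
  expect_equal(res$N, 44L)
  expect_equal(res$delta, 3.7146, tolerance = 1e-4 / 3.7146)
  expect_equal(res$t_crit, 2.0167, tolerance = 1e-4 / 2.0167)
  expect_equal(res$achieved_power, 0.9526, tolerance = 5e-4 / 0.9526)
  # one participant fewer is underpowered
  expect_lt(1 - stats::pt(stats::qt(0.975, 42), 42, ncp = 0.56 * sqrt(43)) +
              stats::pt(-stats::qt(0.975, 42), 42, ncp = 0.56 * sqrt(43)),
            0.95)
})

test_that("power search hits the minimum N and is monotone in its arguments", {
  expect_equal(power_paired_t(50, 0.05, 0.8)$N, 2L)
  n_by_dz <- vapply(c(0.3, 0.5, 0.8), function(d)
    power_paired_t(d, 0.05, 0.9)$N, numeric(1))
  expect_true(all(diff(n_by_dz) <= 0))
  n_by_alpha <- vapply(c(0.01, 0.05, 0.1), function(a)
    power_paired_t(0.5, a, 0.9)$N, numeric(1))
  expect_true(all(diff(n_by_alpha) <= 0))
  n_by_power <- vapply(c(0.8, 0.9, 0.99), function(pw)
    power_paired_t(0.5, 0.05, pw)$N, numeric(1))
  expect_true(all(diff(n_by_power) >= 0))
})

test_that("achieved power matches a Monte-Carlo paired t test and power.t.test", {
  res <- power_paired_t(0.56, 0.05, 0.95)
  ref <- stats::power.t.test(n = res$N, delta = 0.56, sd = 1,
                             sig.level = 0.05, type = "one.sample")
  expect_equal(res$achieved_power, ref$power, tolerance = 1e-6)

  set.seed(231)
  reps <- 100000
  draws <- matrix(rnorm(reps * res$N, mean = 0.56, sd = 1), nrow = res$N)
  m <- colMeans(draws)
  s <- sqrt((colSums(draws^2) - res$N * m^2) / (res$N - 1))
  tstat <- m / (s / sqrt(res$N))
  expect_equal(mean(abs(tstat) > res$t_crit), res$achieved_power,
               tolerance = 0.01 / res$achieved_power)
})

test_that("session summaries mirror the metric-table layout and recount exactly", {
  g <- default_skill_graph()
  logs <- simulate_cohort(g, cohort_config(n_learners = 4L, seed = 17L))
  tab <- summarize_sessions(logs, g)
  expect_setequal(tab$metric,
                  c("correct_answers_level", "wrong_answers_level",
                    "specific_wrong_level", "correct_answers_questions",
                    "wrong_answers_questions", "specific_wrong_questions",
                    "special_case"))
  # recount oracle: total correct answers across all (session, skill) groups
  all_logs <- do.call(rbind, lapply(logs, as.data.frame))
  got <- tab[tab$metric == "correct_answers_questions", ]
  expect_equal(got$mean * got$n, sum(all_logs$correct))
  gotw <- tab[tab$metric == "wrong_answers_questions", ]
  expect_equal(gotw$mean * gotw$n, sum(!all_logs$correct))
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max, na.rm = TRUE))

  # single-record log: mean = min = max
  one <- logs[[1]][1, ]
  attr(one, "class") <- c("session_log", "data.frame")
  t1 <- summarize_sessions(list(one), g)
  lvl <- t1[t1$metric == paste0(if (one$correct) "correct" else "wrong",
                                "_answers_level"), ]
  expect_equal(lvl$mean, lvl$min)
  expect_equal(lvl$mean, lvl$max)

  # empty metric reports n = 0
  empty <- logs[[1]][0, ]
  attr(empty, "class") <- c("session_log", "data.frame")
  t0 <- summarize_sessions(list(empty), g)
  expect_true(all(t0$n == 0L))
})
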