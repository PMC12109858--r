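#' A simulated learner
#'
#' Synthetic learners make the engine testable end-to-end without any real
#' student data. A learner has a latent binary mastery state per skill,
#' slip/guess response noise, a practice-driven learning rate, an error
#' profile governing which buggy rule produces wrong answers, and a
#' lognormal response-time model whose location grows with task difficulty.
#'
#' @param true_mastery Named logical vector over skill ids: `TRUE` =
#'   learned.
#' @param learn_rate Probability an unlearned skill becomes learned after
#'   one practice step on it.
#' @param slip Probability a learned skill still yields a wrong answer.
#' @param guess Probability an unlearned skill yields a correct answer.
#' @param error_profile Named non-negative weights over
#'   `c(error_cases, "GENERIC")`, normalized to sum to 1; drawn from when a
#'   wrong answer is produced (see [memory_subtype_weights()] for presets).
#' @param rt_mu0 Median response time in seconds at difficulty rank 0.
#' @param rt_dmu Log-scale increment per difficulty rank (> 0 makes
#'   harder tasks slower).
#' @param rt_sigma Log-scale standard deviation.
#' @param hint_rate,extra_attempt_rate Means of the geometric hint and
#'   repeat-attempt counts (defaults 0: one attempt, no hints).
#' @return A list of class `learner_profile`.
#' @export
learner_profile <- function(true_mastery, learn_rate = 0.2, slip = 0.10,
                            guess = 0.20,
                            error_profile = memory_subtype_weights("mixed"),
                            rt_mu0 = 8, rt_dmu = 0.15, rt_sigma = 0.4,
                            hint_rate = 0, extra_attempt_rate = 0) {
  stopifnot(is.logical(true_mastery), !is.null(names(true_mastery)),
            learn_rate >= 0, learn_rate <= 1, slip >= 0, slip <= 1,
            guess >= 0, guess <= 1, all(error_profile >= 0),
            rt_mu0 > 0, rt_sigma >= 0, hint_rate >= 0,
            extra_attempt_rate >= 0)
  full <- stats::setNames(numeric(length(error_cases) + 1L),
                          c(error_cases, "GENERIC"))
  full[names(error_profile)] <- error_profile
  if (sum(full) <= 0) stop("error_profile must have positive total weight")
  full <- full / sum(full)
  structure(list(true_mastery = true_mastery, learn_rate = learn_rate,
                 slip = slip, guess = guess, error_profile = full,
                 rt_mu0 = rt_mu0, rt_dmu = rt_dmu, rt_sigma = rt_sigma,
                 hint_rate = hint_rate,
                 extra_attempt_rate = extra_attempt_rate),
            class = "learner_profile")
}

#' Error-profile presets by memory subtype
#'
#' Maps the memory subtypes implicated in the five error cases to weight
#' presets: `"semantic"` weights operation misattribution and the
#' zero-effect misconception (Cases 1 and 5), `"visuospatial"` weights the
#' no-carry concatenation error (Case 2), `"procedural"` weights digit
#' collapse and carry omission (Cases 3 and 4). `"mixed"` spreads weight
#' evenly. Every preset keeps some mass on `GENERIC` (an unpatterned wrong
#' answer). The weights are package defaults, not empirical prevalences.
#'
#' @param subtype One of `"semantic"`, `"visuospatial"`, `"procedural"`,
#'   `"mixed"`.
#' @return Named numeric weights over `c(error_cases, "GENERIC")`, summing
#'   to 1.
#' @export
memory_subtype_weights <- function(subtype = c("mixed", "semantic",
                                               "visuospatial", "procedural")) {
  subtype <- match.arg(subtype)
  w <- switch(subtype,
    semantic     = c(0.35, 0.05, 0.05, 0.05, 0.35, 0.15),
    visuospatial = c(0.05, 0.60, 0.05, 0.10, 0.05, 0.15),
    procedural   = c(0.05, 0.05, 0.35, 0.35, 0.05, 0.15),
    mixed        = c(0.16, 0.16, 0.16, 0.16, 0.16, 0.20))
  stats::setNames(w / sum(w), c(error_cases, "GENERIC"))
}

#' Simulate one response to a task
#'
#' A learner answers correctly with probability `1 - slip` when the task's
#' skill is learned and `guess` otherwise. Wrong answers are produced by a
#' buggy rule drawn from the learner's error profile ([buggy_answer()]);
#' `GENERIC` wrong answers are the correct result shifted by a uniform
#' nonzero offset in -9..9. When the drawn buggy rule happens to coincide
#' with the correct result (common on carry-free tasks) the generic wrong
#' answer is used instead, so the empirical correct rate equals
#' `p (1 - slip) + (1 - p) guess` exactly. Response time is lognormal with
#' median
#' `rt_mu0 * exp(rt_dmu * rank)` seconds. Deterministic under a fixed R
#' random seed.
#'
#' @param learner A [learner_profile()].
#' @param task An [arith_task()] whose `skill_id` is in the profile.
#' @param rank Difficulty rank of the task's skill (drives response time).
#' @return A list with `answer`, `rt_seconds`, `hints`, `attempts`.
#' @export
simulate_response <- function(learner, task, rank = 0) {
  stopifnot(inherits(learner, "learner_profile"), inherits(task, "arith_task"))
  if (!task$skill_id %in% names(learner$true_mastery))
    stop("task skill '", task$skill_id, "' not in learner profile")
  learned <- learner$true_mastery[[task$skill_id]]
  p_correct <- if (learned) 1 - learner$slip else learner$guess
  truth <- correct_answer(task)

  answer <- if (stats::runif(1) < p_correct) {
    truth
  } else if (task$operation == "multiplication") {
    generic_wrong(truth)
  } else {
    case <- sample(names(learner$error_profile), 1L,
                   prob = learner$error_profile)
    wrong <- if (case == "GENERIC") generic_wrong(truth)
             else buggy_answer(task, case)
    # a failed attempt must yield a wrong answer: when the drawn buggy rule
    # coincides with the truth (e.g. no-carry rules on a carry-free sum),
    # fall back to an unpatterned wrong answer
    if (wrong == truth) generic_wrong(truth) else wrong
  }
  rt <- stats::rlnorm(1, meanlog = log(learner$rt_mu0) +
                        learner$rt_dmu * rank, sdlog = learner$rt_sigma)
  hints <- if (learner$hint_rate > 0)
    stats::rgeom(1, 1 / (1 + learner$hint_rate)) else 0L
  attempts <- 1L + if (learner$extra_attempt_rate > 0)
    stats::rgeom(1, 1 / (1 + learner$extra_attempt_rate)) else 0L
  list(answer = as.integer(answer), rt_seconds = rt,
       hints = as.integer(hints), attempts = as.integer(attempts))
}

generic_wrong <- function(truth) {
  repeat {
    ans <- truth + sample(c(-9:-1, 1:9), 1L)
    if (ans >= 0L && ans != truth) return(ans)
  }
}

#' Practice-driven learning
#'
#' Practicing an unlearned skill (a STAY or REMEDIATE step on it) flips
#' its latent mastery to learned with probability `learn_rate`; mastery is
#' never unlearned. This gives the controller genuine learning dynamics to
#' induce.
#'
#' @param learner A [learner_profile()].
#' @param skill_id The practiced skill.
#' @param action The controller action for the step (`"STAY"`,
#'   `"REMEDIATE"`, `"ADVANCE"`); only the first two count as practice.
#' @return The (possibly updated) `learner_profile`.
#' @export
practice_update <- function(learner, skill_id, action = "STAY") {
  stopifnot(inherits(learner, "learner_profile"))
  if (!skill_id %in% names(learner$true_mastery))
    stop("unknown skill id: '", skill_id, "'")
  if (action %in% c("STAY", "REMEDIATE") &&
      !learner$true_mastery[[skill_id]] &&
      stats::runif(1) < learner$learn_rate) {
    learner$true_mastery[[skill_id]] <- TRUE
  }
  learner
}

#' Cohort configuration
#'
#' Parameters of a simulated cohort. Learners are split into a typical and
#' a dyscalculic group; each learner masters a prefix of every
#' within-operation skill chain up to a sampled frontier rank, with group
#' ranges reflecting that dyscalculic learners start further back, learn
#' more slowly, and slip more often.
#'
#' @param n_learners Number of learners (>= 1, default 50).
#' @param fraction_dyscalculic Fraction of the cohort with a dyscalculic
#'   profile (default 0.5).
#' @param seed Base integer seed; learner `i` runs under `seed + i`.
#' @param typical,dyscalculic Lists of profile ranges with elements
#'   `frontier` (inclusive rank range learned at start), `learn_rate`,
#'   `slip`, `guess` (each a `c(lo, hi)` range sampled uniformly).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_learners = 50L, fraction_dyscalculic = 0.5,
                          seed = 1L,
                          typical = list(frontier = c(8L, 16L),
                                         learn_rate = c(0.2, 0.4),
                                         slip = c(0.02, 0.08),
                                         guess = c(0.1, 0.25)),
                          dyscalculic = list(frontier = c(0L, 6L),
                                             learn_rate = c(0.005, 0.03),
                                             slip = c(0.1, 0.2),
                                             guess = c(0.1, 0.25))) {
  stopifnot(n_learners >= 1, fraction_dyscalculic >= 0,
            fraction_dyscalculic <= 1)
  structure(list(n_learners = as.integer(n_learners),
                 fraction_dyscalculic = fraction_dyscalculic,
                 seed = as.integer(seed), typical = typical,
                 dyscalculic = dyscalculic),
            class = "cohort_config")
}

#' Sample a learner profile for a graph
#'
#' @param graph A [skill_graph()].
#' @param ranges Profile ranges (`typical`/`dyscalculic` element of a
#'   [cohort_config()]).
#' @param subtype Memory-subtype preset for the error profile; `NULL`
#'   draws one uniformly at random.
#' @return A [learner_profile()] over the graph's skills.
#' @export
sample_learner_profile <- function(graph, ranges, subtype = NULL) {
  runifr <- function(r) stats::runif(1, r[1], r[2])
  frontier <- sample(ranges$frontier[1]:ranges$frontier[2], 1L)
  mastery <- stats::setNames(graph$skills$difficulty_rank <= frontier,
                             graph$skills$id)
  if (is.null(subtype))
    subtype <- sample(c("semantic", "visuospatial", "procedural", "mixed"),
                      1L)
  learner_profile(mastery,
                  learn_rate = runifr(ranges$learn_rate),
                  slip = max(0.001, runifr(ranges$slip)),
                  guess = max(0.001, runifr(ranges$guess)),
                  error_profile = memory_subtype_weights(subtype))
}

#' Simulate a cohort of tutoring sessions
#'
#' Runs [run_session()] for each of `n_learners` independently sampled
#' learners. Learner `i` is sampled and run under seed `config$seed + i`,
#' so the whole cohort is reproducible and individual sessions can be
#' re-run in isolation.
#'
#' @param graph A valid [skill_graph()].
#' @param config A [cohort_config()].
#' @param control A [controller_config()].
#' @param tparams,eparams Student-model parameters.
#' @return A list of `session_log`s (one per learner), with attribute
#'   `dyscalculic` (logical vector).
#' @export
simulate_cohort <- function(graph, config = cohort_config(),
                            control = controller_config(),
                            tparams = transition_params(),
                            eparams = emission_params()) {
  stopifnot(inherits(config, "cohort_config"))
  n_dys <- round(config$n_learners * config$fraction_dyscalculic)
  is_dys <- rep(c(TRUE, FALSE), c(n_dys, config$n_learners - n_dys))
  logs <- vector("list", config$n_learners)
  for (i in seq_len(config$n_learners)) {
    set.seed(config$seed + i)
    ranges <- if (is_dys[i]) config$dyscalculic else config$typical
    learner <- sample_learner_profile(graph, ranges)
    logs[[i]] <- run_session(graph, learner, control, tparams, eparams)
  }
  attr(logs, "dyscalculic") <- is_dys
  logs
}

#' Mastery-calibration metrics of a simulated cohort
#'
#' How well do the end-of-session mastery posteriors discriminate the
#' learners' true (latent) mastery? Pooled over all (learner, skill) pairs
#' with at least one observation in the session — unvisited skills remain
#' at the uninformed 0.5 prior and carry no information about
#' discrimination. Returns the ranking accuracy (probability a randomly
#' chosen truly-learned skill outranks a truly-unlearned one; the area
#' under the ROC curve, ties counted half) and the Brier score
#' (mean squared error of the posterior against the 0/1 truth; 0.25 for
#' the uninformed baseline).
#'
#' @param logs A list of `session_log`s from [simulate_cohort()].
#' @return A list with `ranking_accuracy`, `brier`, `n_pairs`.
#' @export
calibration_metrics <- function(logs) {
  p <- numeric(0)
  y <- logical(0)
  for (log in logs) {
    visited <- attr(log, "visited")
    if (length(visited) == 0L) next
    post <- attr(log, "final_posteriors")[visited]
    truth <- attr(log, "final_mastery")[visited]
    p <- c(p, post)
    y <- c(y, truth)
  }
  if (length(unique(y)) < 2L)
    stop("cohort contains only one mastery class among visited skills")
  pos <- p[y]
  neg <- p[!y]
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  list(ranking_accuracy = auc, brier = mean((p - as.numeric(y))^2),
       n_pairs = length(p))
}
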