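#' Pedagogical controller configuration
#'
#' Tunables of the rule-based task-selection controller. The controller
#' keeps two adaptive posterior thresholds, a lower one (`PLT`) and an
#' upper one (`PUT`), initialized to 0 and 1. When the current skill's
#' posterior leaves the band, the crossed threshold is pulled inwards by
#' `adapt_amount / n_samples` (a 1/n-decaying step), so the band tightens
#' as evidence accumulates.
#'
#' Two action semantics are provided. Under the default
#' `"mastery_advance"`, a posterior above `PUT` advances to a successor
#' skill and one below `PLT` remediates to the precursor with the lowest
#' mastery probability. `"as_printed"` swaps the two branches (advance on
#' low, remediate on high), matching the literal pseudocode of the source
#' control algorithm; see the methods vignette for why the default follows
#' the prose description instead.
#'
#' @param adapt_amount Threshold adaptation step (> 0, default 0.1).
#' @param semantics `"mastery_advance"` (default) or `"as_printed"`.
#' @param mastery_stop Posterior at or above which a skill counts as
#'   mastered (default 0.95).
#' @param consecutive_stop Number of consecutive mastered tasks that ends
#'   teaching of a skill (default 2).
#' @param step_cap Maximum number of tasks per session (default 500);
#'   guarantees termination.
#' @param lambda Damping of one-hop mastery propagation after each update
#'   (see [propagate_mastery()]; default 0.5).
#' @param memory Observation-window length of the student model.
#' @param plt0,put0 Initial threshold band of a session. The literal
#'   control algorithm initializes the band to `[0, 1]`, but a mastery
#'   posterior can never leave that band, so neither branching nor
#'   threshold adaptation would ever engage; the defaults (0.3, 0.95)
#'   start the band at pedagogically meaningful values: below 0.3 the
#'   skill is likely missing a prerequisite, above 0.95 it is mastered
#'   enough to move on.
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(adapt_amount = 0.1,
                              semantics = c("mastery_advance", "as_printed"),
                              mastery_stop = 0.95,
                              consecutive_stop = 2L,
                              step_cap = 500L,
                              lambda = 0.5,
                              memory = 5L,
                              plt0 = 0.3,
                              put0 = 0.95) {
  semantics <- match.arg(semantics)
  stopifnot(adapt_amount > 0, mastery_stop > 0, mastery_stop <= 1,
            consecutive_stop >= 1, step_cap >= 1,
            lambda >= 0, lambda <= 1, memory >= 1,
            plt0 >= 0, plt0 <= put0, put0 <= 1)
  structure(list(adapt_amount = adapt_amount, semantics = semantics,
                 mastery_stop = mastery_stop,
                 consecutive_stop = as.integer(consecutive_stop),
                 step_cap = as.integer(step_cap), lambda = lambda,
                 memory = as.integer(memory), plt0 = plt0, put0 = put0),
            class = "controller_config")
}

#' Controller state
#'
#' @param current_skill Skill currently being taught.
#' @param PLT,PUT Posterior lower/upper thresholds, `0 <= PLT <= PUT <= 1`.
#' @param n_samples Number of tasks played so far.
#' @return A list of class `controller_state`.
#' @export
controller_state <- function(current_skill, PLT = 0, PUT = 1,
                             n_samples = 0L) {
  stopifnot(PLT >= 0, PLT <= PUT, PUT <= 1, n_samples >= 0)
  structure(list(current_skill = current_skill, PLT = PLT, PUT = PUT,
                 n_samples = as.integer(n_samples),
                 training_level = "current"),
            class = "controller_state")
}

#' Choose the next pedagogical action
#'
#' Compares the current skill's mastery posterior with the controller's
#' threshold band and returns one of three actions: `ADVANCE` to a
#' successor skill, `STAY` on the current skill, or `REMEDIATE` to a
#' precursor. Target selection is deterministic: on advance, the successor
#' with the lowest `(difficulty_rank, id)`; on remediation, the precursor
#' with the minimum mastery posterior (ties by id) — the skill the learner
#' most plausibly lacks. At a leaf with nothing to advance to (or a root
#' with nothing to remediate to) the controller stays, flagged `terminal`
#' for the leaf case.
#'
#' @param cstate A [controller_state()].
#' @param posteriors Named numeric vector of mastery posteriors containing
#'   the current skill.
#' @param graph The [skill_graph()].
#' @param config A [controller_config()] (for the action semantics).
#' @return A list with `action` (`"ADVANCE"`, `"STAY"`, `"REMEDIATE"`),
#'   `target` (skill id), `band` (`"high"`, `"in"`, `"low"`) and
#'   `terminal` (logical).
#' @export
next_action <- function(cstate, posteriors, graph,
                        config = controller_config()) {
  skill <- cstate$current_skill
  if (!skill %in% names(posteriors))
    stop("no posterior for current skill '", skill, "'")
  p <- posteriors[[skill]]
  band <- if (p > cstate$PUT) "high" else if (p < cstate$PLT) "low" else "in"

  res <- function(action, target, terminal = FALSE)
    list(action = action, target = target, band = band, terminal = terminal)

  wants <- if (band == "in") "STAY"
           else if (config$semantics == "mastery_advance") {
             if (band == "high") "ADVANCE" else "REMEDIATE"
           } else {                       # literal pseudocode: swapped
             if (band == "high") "REMEDIATE" else "ADVANCE"
           }

  if (wants == "STAY") return(res("STAY", skill))
  if (wants == "ADVANCE") {
    succ <- skill_successors(graph, skill)
    if (length(succ) == 0L) return(res("STAY", skill, terminal = TRUE))
    rank_of <- stats::setNames(graph$skills$difficulty_rank, graph$skills$id)
    succ <- succ[order(rank_of[succ], succ)]
    return(res("ADVANCE", succ[1L]))
  }
  pre <- skill_precursors(graph, skill)
  if (length(pre) == 0L) return(res("STAY", skill))
  pp <- posteriors[pre]
  pp[is.na(pp)] <- 0.5
  pre <- pre[order(pp, pre)]
  res("REMEDIATE", pre[1L])
}

#' Adapt the posterior thresholds after an out-of-band event
#'
#' An out-of-band-high event (posterior above `PUT`) lowers `PUT` by
#' `adapt_amount / n_samples`; an out-of-band-low event raises `PLT` by the
#' same decaying step. `n_samples` is taken as at least 1 (the count is
#' incremented when a task is played, before any adaptation), and the
#' result is clamped so `0 <= PLT <= PUT <= 1` always holds. In-band steps
#' leave the thresholds unchanged.
#'
#' @param cstate A [controller_state()].
#' @param band `"high"`, `"in"` or `"low"` (as returned by [next_action()]).
#' @param config A [controller_config()].
#' @return The updated `controller_state`.
#' @export
update_thresholds <- function(cstate, band, config = controller_config()) {
  stopifnot(band %in% c("high", "in", "low"))
  step <- config$adapt_amount / max(cstate$n_samples, 1L)
  if (band == "high") cstate$PUT <- cstate$PUT - step
  if (band == "low") cstate$PLT <- cstate$PLT + step
  cstate$PUT <- min(max(cstate$PUT, 0), 1)
  cstate$PLT <- min(max(cstate$PLT, 0), 1)
  if (cstate$PLT > cstate$PUT) {
    mid <- (cstate$PLT + cstate$PUT) / 2
    cstate$PLT <- mid
    cstate$PUT <- mid
  }
  cstate
}

#' Run an adaptive tutoring session against a (simulated) learner
#'
#' Iterates the full teaching loop: generate a task for the current skill,
#' obtain the learner's response, diagnose it ([classify_error()]), fold
#' the evidence into the student model ([update_posterior()], with one-hop
#' propagation), pick the next action ([next_action()]) and adapt the
#' thresholds ([update_thresholds()]). The session starts at the first
#' skill in topological order (the lowest level of difficulty) and ends
#' when the final skill in that order satisfies the mastery-stop rule
#' (posterior at or above `mastery_stop` on `consecutive_stop` consecutive
#' tasks), or when `step_cap` is reached, in which case the log is flagged
#' truncated. When a non-terminal skill satisfies the stop rule, teaching
#' moves to the next unfinished skill in topological order.
#'
#' @param graph A valid [skill_graph()].
#' @param learner A [learner_profile()] (the simulated-response contract:
#'   [simulate_response()] and [practice_update()] must accept it).
#' @param config A [controller_config()].
#' @param tparams,eparams Student-model parameters.
#' @param seed Optional integer; when given, the session is reproducible.
#' @return A `session_log`: a data.frame with one row per step (columns
#'   `step`, `skill_id`, `task`, `answer`, `correct`, `error_case`,
#'   `posterior_before`, `posterior_after`, `action`, `PLT`, `PUT`,
#'   `rt_seconds`) and attributes `truncated` (logical),
#'   `final_posteriors`, `final_mastery` (the learner's true end-state) and
#'   `visited` (skills with at least one observation).
#' @export
run_session <- function(graph, learner, config = controller_config(),
                        tparams = transition_params(),
                        eparams = emission_params(),
                        seed = NULL) {
  stopifnot(inherits(graph, "skill_graph"))
  if (!is.null(seed)) set.seed(seed)

  empty_log <- function(truncated) {
    log <- data.frame(step = integer(), skill_id = character(),
                      task = character(), answer = integer(),
                      correct = logical(), error_case = character(),
                      posterior_before = numeric(),
                      posterior_after = numeric(), action = character(),
                      PLT = numeric(), PUT = numeric(),
                      rt_seconds = numeric(), stringsAsFactors = FALSE)
    structure(log, class = c("session_log", "data.frame"),
              truncated = truncated)
  }
  order <- topological_order(graph)
  if (length(order) == 0L) return(empty_log(FALSE))

  rank_of <- stats::setNames(graph$skills$difficulty_rank, graph$skills$id)
  state <- init_knowledge_state(graph, memory = config$memory)
  cstate <- controller_state(order[1L], PLT = config$plt0, PUT = config$put0)
  done <- character(0)
  streak <- stats::setNames(integer(length(order)), order)
  terminal_skill <- order[length(order)]
  rows <- vector("list", config$step_cap)
  truncated <- TRUE

  for (step in seq_len(config$step_cap)) {
    skill <- cstate$current_skill
    task <- generate_task(skill, graph)
    resp <- simulate_response(learner, task, rank = rank_of[[skill]])
    cls <- classify_error(task, resp$answer)
    is_correct <- cls$primary == "CORRECT"
    is_specific <- cls$primary %in% error_cases
    obs <- observation(skill, C = as.integer(is_correct),
                       W = as.integer(!is_correct),
                       SW = as.integer(is_specific),
                       H = resp$hints, A = max(1L, resp$attempts),
                       response_time = resp$rt_seconds)
    p_before <- state$posteriors[[skill]]
    state <- update_posterior(state, obs, tparams, eparams)
    state <- propagate_mastery(graph, state, skill, config$lambda)
    p_after <- state$posteriors[[skill]]

    cstate$n_samples <- cstate$n_samples + 1L
    act <- next_action(cstate, state$posteriors, graph, config)
    cstate <- update_thresholds(cstate, act$band, config)
    learner <- practice_update(learner, skill, act$action)

    rows[[step]] <- data.frame(step = step, skill_id = skill,
      task = format(task), answer = resp$answer, correct = is_correct,
      error_case = cls$primary, posterior_before = p_before,
      posterior_after = p_after, action = act$action,
      PLT = cstate$PLT, PUT = cstate$PUT, rt_seconds = resp$rt_seconds,
      stringsAsFactors = FALSE)

    streak[[skill]] <- if (p_after >= config$mastery_stop)
      streak[[skill]] + 1L else 0L

    if (streak[[skill]] >= config$consecutive_stop) {
      done <- union(done, skill)
      if (skill == terminal_skill || length(done) == length(order)) {
        truncated <- FALSE
        rows <- rows[seq_len(step)]
        break
      }
      remaining <- setdiff(order, done)
      cstate$current_skill <- remaining[1L]
    } else if (act$action %in% c("ADVANCE", "REMEDIATE")) {
      cstate$current_skill <- act$target
    }
  }

  log <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(log) <- NULL
  structure(log, class = c("session_log", "data.frame"),
            truncated = truncated,
            final_posteriors = state$posteriors,
            final_mastery = learner$true_mastery,
            visited = unique(log$skill_id))
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d steps, %d skills visited%s\n",
              nrow(x), length(unique(x$skill_id)),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  if (nrow(x) > 0L)
    cat(sprintf("  accuracy %.2f, final band [%.3f, %.3f]\n",
                mean(x$correct), x$PLT[nrow(x)], x$PUT[nrow(x)]))
  invisible(x)
}
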