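#' Transition parameters of the mastery chain
#'
#' Per time step, a mastered skill stays mastered with probability
#' `p_retain` and an unmastered skill is acquired with probability
#' `p_acquire`. The defaults (0.9 / 0.1) make the uninformed prior 0.5 the
#' fixed point of the chain.
#'
#' @param p_retain,p_acquire Probabilities in `[0, 1]`.
#' @return A list of class `transition_params`.
#' @export
transition_params <- function(p_retain = 0.9, p_acquire = 0.1) {
  stopifnot(p_retain >= 0, p_retain <= 1, p_acquire >= 0, p_acquire <= 1)
  structure(list(p_retain = p_retain, p_acquire = p_acquire),
            class = "transition_params")
}

#' Emission parameters of the response model
#'
#' Classic knowledge-tracing slip/guess emissions: a mastered learner
#' answers an item correctly with probability `1 - slip`, an unmastered one
#' with probability `guess`. `hint_discount` optionally down-weights
#' correct-answer evidence obtained with hints: each hint multiplies the
#' per-correct evidence weight by `hint_discount`, moving it toward
#' uninformativeness (1 = off).
#'
#' @param slip,guess Probabilities in `(0, 1)`.
#' @param hint_discount Multiplicative factor in `[0, 1]` per hint.
#' @return A list of class `emission_params`.
#' @export
emission_params <- function(slip = 0.10, guess = 0.20, hint_discount = 1) {
  stopifnot(slip > 0, slip < 1, guess > 0, guess < 1,
            hint_discount >= 0, hint_discount <= 1)
  structure(list(slip = slip, guess = guess, hint_discount = hint_discount),
            class = "emission_params")
}

#' One practice step's evidence
#'
#' Aggregated evidence from one practice step on one skill: attempt count
#' `A`, hint count `H`, and counts of correct (`C`), wrong (`W`) and
#' specific-wrong (`SW`) answers. A specific wrong answer (one matching a
#' recognizable error case) is also a wrong answer, so `SW <= W`, and
#' `C + W <= A`.
#'
#' @param skill_id Skill the evidence pertains to.
#' @param C,W,SW,H Non-negative integer counts.
#' @param A Attempt count, `>= max(1, C + W)`; defaults to `C + W`.
#' @param response_time Seconds, `>= 0` (`NA` allowed; not used in the
#'   likelihood).
#' @return A list of class `observation`.
#' @export
observation <- function(skill_id, C = 0L, W = 0L, SW = 0L, H = 0L,
                        A = NULL, response_time = NA_real_) {
  if (is.null(A)) A <- max(1L, C + W)
  stopifnot(C >= 0, W >= 0, SW >= 0, H >= 0, A >= 1,
            SW <= W, C + W <= A,
            is.na(response_time) || response_time >= 0)
  structure(list(skill_id = skill_id, C = as.integer(C), W = as.integer(W),
                 SW = as.integer(SW), H = as.integer(H), A = as.integer(A),
                 response_time = response_time),
            class = "observation")
}

#' Initialize the knowledge state
#'
#' Every skill's mastery posterior starts at the maximum-entropy value 0.5
#' (no prior information about the learner), with an empty observation
#' window.
#'
#' @param graph A [skill_graph()].
#' @param memory Observation-window length: posteriors are computed from at
#'   most this many recent observations per skill (default 5).
#' @param prior Initial mastery probability (default 0.5).
#' @return A list of class `knowledge_state` with fields `posteriors`
#'   (named numeric), `windows` (named list of observation lists),
#'   `last_message` (named numeric, the most recent transition message,
#'   diagnostic), `memory` and `prior`.
#' @export
init_knowledge_state <- function(graph, memory = 5L, prior = 0.5) {
  stopifnot(inherits(graph, "skill_graph"), memory >= 1, prior >= 0, prior <= 1)
  ids <- graph$skills$id
  structure(list(
    posteriors = stats::setNames(rep(prior, length(ids)), ids),
    windows = stats::setNames(replicate(length(ids), list(), simplify = FALSE),
                              ids),
    last_message = stats::setNames(rep(NA_real_, length(ids)), ids),
    memory = as.integer(memory),
    prior = prior
  ), class = "knowledge_state")
}

#' @export
print.knowledge_state <- function(x, ...) {
  cat(sprintf("<knowledge_state> %d skills, memory %d\n",
              length(x$posteriors), x$memory))
  p <- x$posteriors
  cat(sprintf("  posterior range [%.3f, %.3f], mean %.3f\n",
              min(p), max(p), mean(p)))
  invisible(x)
}

#' Transition message of the forward pass
#'
#' The predictive mastery probability before seeing the current step's
#' evidence: `p_retain * prior + p_acquire * (1 - prior)`. This is the
#' sum-product message passed from the previous time slice.
#'
#' @param prior Mastery probability at the previous step, in `[0, 1]`.
#' @param tparams A [transition_params()].
#' @return A probability between `p_acquire` and `p_retain` (for
#'   `p_acquire <= p_retain`).
#' @export
transition_message <- function(prior, tparams = transition_params()) {
  if (!is.numeric(prior) || any(prior < 0) || any(prior > 1))
    stop("prior must be a probability in [0, 1]")
  tparams$p_retain * prior + tparams$p_acquire * (1 - prior)
}

#' Emission likelihood of an observation
#'
#' Likelihood of the step's evidence given the latent mastery state `k`:
#' a product of `C` Bernoulli-correct terms and `W` Bernoulli-wrong terms
#' (specific wrongs are counted inside `W`), with
#' `P(correct | k = 1) = 1 - slip` and `P(correct | k = 0) = guess`.
#' When `hint_discount < 1`, each hint shrinks the exponent on the correct
#' terms by that factor, discounting hinted successes toward
#' uninformativeness. An empty observation (`C = W = 0`) has likelihood 1.
#'
#' @param obs An [observation()].
#' @param k Latent mastery state, 0 or 1.
#' @param eparams An [emission_params()].
#' @return A likelihood in `(0, 1]`.
#' @export
emission_likelihood <- function(obs, k, eparams = emission_params()) {
  stopifnot(inherits(obs, "observation"), k %in% c(0, 1))
  p_correct <- if (k == 1) 1 - eparams$slip else eparams$guess
  correct_weight <- eparams$hint_discount^obs$H
  p_correct^(obs$C * correct_weight) * (1 - p_correct)^obs$W
}

# forward recursion over a window of observations, starting from `prior`
forward_posterior <- function(window, prior, tparams, eparams) {
  p <- prior
  m <- NA_real_
  for (obs in window) {
    m <- transition_message(p, tparams)
    num <- emission_likelihood(obs, 1, eparams) * m
    den <- num + emission_likelihood(obs, 0, eparams) * (1 - m)
    p <- num / den
  }
  list(posterior = p, last_message = m)
}

#' Update the mastery posterior with one observation
#'
#' Implements the sum-product forward update of the dynamic Bayesian
#' network with a bounded memory: the observation is appended to the
#' skill's window, the window is trimmed to the most recent `memory`
#' observations (default five), and the posterior is recomputed by running
#' the forward recursion over the retained window from the maximum-entropy
#' prior. Each forward step computes the transition message
#' ([transition_message()]), multiplies in the emission likelihood of the
#' evidence, and normalizes over the two latent states. While the window is
#' not yet full this equals the incremental Bayes update from the current
#' posterior; once observations fall out of the window, re-anchoring at the
#' prior keeps the posterior a function of the last `memory` steps only.
#'
#' @param state A [init_knowledge_state()] state.
#' @param obs An [observation()] whose `skill_id` exists in the state.
#' @param tparams A [transition_params()].
#' @param eparams An [emission_params()].
#' @return The updated `knowledge_state`.
#' @export
update_posterior <- function(state, obs,
                             tparams = transition_params(),
                             eparams = emission_params()) {
  stopifnot(inherits(state, "knowledge_state"), inherits(obs, "observation"))
  id <- obs$skill_id
  if (!id %in% names(state$posteriors))
    stop("unknown skill id: '", id, "'")
  win <- c(state$windows[[id]], list(obs))
  if (length(win) > state$memory)
    win <- win[(length(win) - state$memory + 1L):length(win)]
  fwd <- forward_posterior(win, state$prior, tparams, eparams)
  state$windows[[id]] <- win
  state$posteriors[[id]] <- fwd$posterior
  state$last_message[[id]] <- fwd$last_message
  state
}

#' Propagate evidence one hop across the prerequisite graph
#'
#' Practicing a skill also carries information about its neighbours:
#' mastery of a skill implies some mastery of its prerequisites, and lack
#' of mastery bounds its successors. This damped one-hop heuristic moves
#' each direct precursor's posterior to
#' `max(own, lambda * p_skill)` and each direct successor's to
#' `min(own, 1 - lambda * (1 - p_skill))`. With `lambda = 0` the state is
#' unchanged; posteriors always remain in `[0, 1]`. (Full belief
#' propagation over the DAG is deliberately not attempted.)
#'
#' @param graph A [skill_graph()].
#' @param state A `knowledge_state`.
#' @param skill_id The skill whose posterior was just updated.
#' @param lambda Damping factor in `[0, 1]` (default 0.5).
#' @return The updated `knowledge_state`.
#' @export
propagate_mastery <- function(graph, state, skill_id, lambda = 0.5) {
  stopifnot(inherits(state, "knowledge_state"), lambda >= 0, lambda <= 1)
  check_skill(graph, skill_id)
  p <- state$posteriors[[skill_id]]
  for (pre in skill_precursors(graph, skill_id)) {
    if (pre %in% names(state$posteriors))
      state$posteriors[[pre]] <- max(state$posteriors[[pre]], lambda * p)
  }
  for (succ in skill_successors(graph, skill_id)) {
    if (succ %in% names(state$posteriors))
      state$posteriors[[succ]] <- min(state$posteriors[[succ]],
                                      1 - lambda * (1 - p))
  }
  state
}

#' Predicted probability of a correct answer
#'
#' Marginalizes the emission model over the current mastery posterior:
#' `p * (1 - slip) + (1 - p) * guess`.
#'
#' @param state A `knowledge_state`.
#' @param skill_id Skill id present in the state.
#' @param eparams An [emission_params()].
#' @return A probability.
#' @export
predict_correct <- function(state, skill_id, eparams = emission_params()) {
  stopifnot(inherits(state, "knowledge_state"))
  if (!skill_id %in% names(state$posteriors))
    stop("unknown skill id: '", skill_id, "'")
  p <- state$posteriors[[skill_id]]
  p * (1 - eparams$slip) + (1 - p) * eparams$guess
}
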