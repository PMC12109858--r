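test_that("initialization is the maximum-entropy state", {
  g <- default_skill_graph()
  st <- init_knowledge_state(g)
  expect_length(st$posteriors, 38L)
  expect_true(all(st$posteriors == 0.5))
  expect_true(all(vapply(st$windows, length, integer(1)) == 0L))
})

test_that("transition message is the two-term mixture with 0.5 as fixed point", {
  tp <- transition_params()  # 0.9 / 0.1
  expect_equal(transition_message(0.5, tp), 0.5)
  expect_equal(transition_message(1, tp), 0.9)
  expect_equal(transition_message(0, tp), 0.1)
  expect_error(transition_message(1.2, tp), "probability")
  # always within [p_acquire, p_retain]
  for (p in seq(0, 1, 0.1)) {
    m <- transition_message(p, tp)
    expect_gte(m, 0.1); expect_lte(m, 0.9)
  }
})

test_that("emission likelihood matches the slip/guess Bernoulli products", {
  ep <- emission_params(slip = 0.1, guess = 0.2)
  expect_equal(emission_likelihood(observation("s", C = 1), 1, ep), 0.9)
  expect_equal(emission_likelihood(observation("s", W = 1), 0, ep), 0.8)
  # symmetric slip/guess make the evidence uninformative
  ep5 <- emission_params(slip = 0.5, guess = 0.5)
  obs <- observation("s", C = 2, W = 1)
  expect_equal(emission_likelihood(obs, 1, ep5),
               emission_likelihood(obs, 0, ep5))
  # hint discount moves correct evidence toward uninformativeness
  eph <- emission_params(slip = 0.1, guess = 0.2, hint_discount = 0)
  expect_equal(emission_likelihood(observation("s", C = 3, H = 1), 1, eph), 1)
})

one_skill_state <- function(memory = 5L) {
  g <- skill_graph(data.frame(id = "s", name = "s", operation = "addition",
                              number_range = "0-10", difficulty_rank = 0L))
  init_knowledge_state(g, memory = memory)
}

test_that("a single correct answer updates 0.5 to 9/11", {
  st <- one_skill_state()
  st <- update_posterior(st, observation("s", C = 1),
                         transition_params(), emission_params(0.1, 0.2))
  # direct two-term Bayes: (0.5 * 0.9) / (0.5 * 0.9 + 0.5 * 0.2)
  expect_equal(st$posteriors[["s"]], 0.45 / 0.55, tolerance = 1e-12)
  expect_equal(round(st$posteriors[["s"]], 4), 0.8182)
})

test_that("consecutive correct answers increase the posterior monotonically", {
  st <- one_skill_state()
  p <- numeric(5)
  for (i in 1:5) {
    st <- update_posterior(st, observation("s", C = 1))
    p[i] <- st$posteriors[["s"]]
  }
  expect_true(all(diff(c(0.5, p)) > 0))
  # and the trajectory agrees with full-path marginalization at every step
  obs <- replicate(5, observation("s", C = 1), simplify = FALSE)
  for (t in 1:5) {
    expect_equal(p[t], oracle_posterior(obs[seq_len(t)], 0.5,
                                        transition_params(),
                                        emission_params()),
                 tolerance = 1e-12)
  }
})

test_that("windowed forward posterior equals brute-force path marginalization", {
  set.seed(51)
  tp <- transition_params()
  ep <- emission_params()
  for (rep in 1:60) {
    len <- sample(1:8, 1L)
    memory <- sample(1:5, 1L)
    stream <- replicate(len, random_observation("s"), simplify = FALSE)
    got <- stream_posterior(stream, memory, tp, ep)
    kept <- stream[max(1L, len - memory + 1L):len]
    expect_equal(got, oracle_posterior(kept, 0.5, tp, ep),
                 tolerance = 1e-12)
  }
})

test_that("uninformative emissions leave the posterior at the transition fixed point", {
  ep5 <- emission_params(slip = 0.5, guess = 0.5)
  st <- one_skill_state()
  for (i in 1:10) st <- update_posterior(st, random_observation("s"),
                                         eparams = ep5)
  expect_equal(st$posteriors[["s"]], 0.5, tolerance = 1e-12)
  # asymmetric transition: fixed point p* = p_acquire / (1 - p_retain + p_acquire);
  # a long memory is needed so the window does not re-anchor at 0.5
  tp <- transition_params(p_retain = 0.8, p_acquire = 0.05)
  st <- one_skill_state(memory = 100L)
  for (i in 1:100) st <- update_posterior(st, random_observation("s"),
                                          tparams = tp, eparams = ep5)
  expect_equal(st$posteriors[["s"]], 0.05 / (1 - 0.8 + 0.05),
               tolerance = 1e-9)
})

test_that("posterior is non-decreasing in correct count, wrongs held fixed", {
  ep <- emission_params(slip = 0.15, guess = 0.25)  # s + g < 1
  last <- -Inf
  for (C in 0:5) {
    st <- one_skill_state()
    st <- update_posterior(st, observation("s", C = C, W = 2),
                           eparams = ep)
    expect_gte(st$posteriors[["s"]], last)
    last <- st$posteriors[["s"]]
  }
})

test_that("identical observation streams give bit-identical trajectories", {
  set.seed(61)
  stream <- replicate(12, random_observation("s"), simplify = FALSE)
  run <- function() {
    st <- one_skill_state()
    out <- numeric(0)
    for (obs in stream) {
      st <- update_posterior(st, obs)
      out <- c(out, st$posteriors[["s"]])
    }
    out
  }
  expect_identical(run(), run())
})

test_that("one-hop propagation obeys the damped max/min rule and its bounds", {
  g <- skill_graph(
    data.frame(id = c("p", "c", "s"), name = c("p", "c", "s"),
               operation = "addition", number_range = "0-10",
               difficulty_rank = 0:2),
    data.frame(from = c("p", "c"), to = c("c", "s")))
  st <- init_knowledge_state(g)
  st$posteriors[["p"]] <- 0.3
  st$posteriors[["c"]] <- 1.0
  st$posteriors[["s"]] <- 0.9

  expect_identical(propagate_mastery(g, st, "c", lambda = 0)$posteriors,
                   st$posteriors)

  out <- propagate_mastery(g, st, "c", lambda = 0.5)
  expect_equal(out$posteriors[["p"]], 0.5)        # max(0.3, 0.5 * 1.0)
  expect_equal(out$posteriors[["s"]], 0.9)        # min(0.9, 1 - 0.5 * 0)

  st$posteriors[["c"]] <- 0.2
  out <- propagate_mastery(g, st, "c", lambda = 0.5)
  expect_equal(out$posteriors[["s"]], 0.6)        # min(0.9, 1 - 0.5 * 0.8)
  expect_equal(out$posteriors[["p"]], 0.3)        # max(0.3, 0.1)

  set.seed(71)
  for (rep in 1:20) {
    st$posteriors[] <- runif(3)
    out <- propagate_mastery(g, st, sample(c("p", "c", "s"), 1L),
                             lambda = runif(1))
    expect_true(all(out$posteriors >= 0 & out$posteriors <= 1))
  }
})

test_that("predicted correctness marginalizes the emission over the posterior", {
  st <- one_skill_state()
  ep <- emission_params(slip = 0.1, guess = 0.2)
  expect_equal(predict_correct(st, "s", ep), 0.55)  # p = 0.5
  st$posteriors[["s"]] <- 1
  expect_equal(predict_correct(st, "s", ep), 0.9)
  st$posteriors[["s"]] <- 0
  expect_equal(predict_correct(st, "s", ep), 0.2)
  expect_error(predict_correct(st, "nope", ep), "unknown skill")
})

test_that("observation invariants are enforced", {
  expect_error(observation("s", C = 1, W = 1, SW = 2), "SW")
  expect_error(observation("s", C = 2, W = 1, A = 2), ".")
  expect_error(update_posterior(one_skill_state(),
                                observation("ghost", C = 1)),
               "unknown skill")
})
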