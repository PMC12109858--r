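# Independent oracles and fixture generators used across the test files.
# These deliberately avoid the package's own computational paths.

# Random DAG fixture: edges always point from lower to higher rank, so the
# graph is acyclic and difficulty-monotone by construction.
random_dag <- function(n, p_edge = 0.3,
                       ops = c("addition", "subtraction", "multiplication")) {
  op <- sample(ops, n, replace = TRUE)
  rank <- integer(n)
  for (o in unique(op)) rank[op == o] <- seq_len(sum(op == o)) - 1L
  skills <- data.frame(
    id = sprintf("s%02d", seq_len(n)),
    name = sprintf("skill %02d", seq_len(n)),
    operation = op,
    number_range = sample(c("0-10", "0-100", "0-1000"), n, replace = TRUE),
    difficulty_rank = rank,
    stringsAsFactors = FALSE
  )
  skills$variant_tags <- replicate(n, sample(
    c("none", "support", "mental", "bridging_to_10"), 1L), simplify = FALSE)
  from <- character(0); to <- character(0)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      same_op <- op[i] == op[j]
      if ((!same_op || rank[i] < rank[j]) && runif(1) < p_edge) {
        from <- c(from, skills$id[i]); to <- c(to, skills$id[j])
      }
    }
  }
  edges <- if (length(from)) data.frame(from = from, to = to,
                                        stringsAsFactors = FALSE) else NULL
  skill_graph(skills, edges)
}

# Exhaustive pairwise-reachability oracle: TRUE iff `order` is a valid
# topological order of the graph (checks every edge, and that it is a
# permutation of all ids).
oracle_topo_ok <- function(graph, order) {
  if (!setequal(order, graph$skills$id) ||
      length(order) != nrow(graph$skills)) return(FALSE)
  pos <- stats::setNames(seq_along(order), order)
  if (nrow(graph$edges) == 0L) return(TRUE)
  all(pos[graph$edges$from] < pos[graph$edges$to])
}

# Random observation for a skill (valid by construction: SW <= W, C+W <= A).
random_observation <- function(skill_id) {
  C <- sample(0:2, 1L)
  W <- sample(0:2, 1L)
  if (C + W == 0L) C <- 1L
  observation(skill_id, C = C, W = W, SW = sample(0:W, 1L),
              H = sample(0:1, 1L), A = C + W + sample(0:1, 1L))
}

# Brute-force DBN posterior: marginalize over every latent mastery path
# k_0..k_T (2^(T+1) paths), with the emission terms coded independently of
# the package's emission_likelihood().
oracle_posterior <- function(window, prior, tp, ep) {
  Tn <- length(window)
  oracle_emis <- function(obs, k) {
    pc <- if (k == 1L) 1 - ep$slip else ep$guess
    pc^(obs$C * ep$hint_discount^obs$H) * (1 - pc)^obs$W
  }
  paths <- expand.grid(rep(list(0:1), Tn + 1L))
  top <- 0; tot <- 0
  for (r in seq_len(nrow(paths))) {
    k <- as.integer(paths[r, ])
    w <- if (k[1L] == 1L) prior else 1 - prior
    for (t in seq_len(Tn)) {
      ptr <- if (k[t] == 1L) {
        if (k[t + 1L] == 1L) tp$p_retain else 1 - tp$p_retain
      } else {
        if (k[t + 1L] == 1L) tp$p_acquire else 1 - tp$p_acquire
      }
      w <- w * ptr * oracle_emis(window[[t]], k[t + 1L])
    }
    tot <- tot + w
    if (k[Tn + 1L] == 1L) top <- top + w
  }
  top / tot
}

# Windowed posterior of a full observation stream as the package defines it:
# forward recursion from the 0.5 prior over the last `memory` observations.
# Computed here via repeated update_posterior on a 1-skill state.
stream_posterior <- function(stream, memory, tp, ep) {
  g <- skill_graph(data.frame(id = "s", name = "s", operation = "addition",
                              number_range = "0-10", difficulty_rank = 0L,
                              stringsAsFactors = FALSE))
  st <- init_knowledge_state(g, memory = memory)
  for (obs in stream) st <- update_posterior(st, obs, tp, ep)
  st$posteriors[["s"]]
}

# Independently coded textbook Welch statistic (same quantities, separate
# code path from the package, used as a second opinion next to oneway.test).
oracle_welch <- function(groups) {
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  k <- length(groups)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  f <- (sum(w * (m - mw)^2) / (k - 1)) / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2 <- (k^2 - 1) / (3 * lam)
  list(F = f, df1 = k - 1, df2 = df2,
       p = pf(f, k - 1, df2, lower.tail = FALSE))
}
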