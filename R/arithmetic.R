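#' Arithmetic tasks
#'
#' A task is a pair of non-negative integer operands and an operation,
#' optionally tied to the skill it exercises. Subtraction tasks keep
#' `operand_a >= operand_b` so results stay non-negative.
#'
#' @param operand_a,operand_b Non-negative integers.
#' @param operation `"addition"`, `"subtraction"` or `"multiplication"`.
#' @param skill_id Optional skill id the task belongs to.
#' @return An object of class `arith_task`.
#' @export
arith_task <- function(operand_a, operand_b,
                       operation = c("addition", "subtraction",
                                     "multiplication"),
                       skill_id = NA_character_) {
  operation <- match.arg(operation)
  stopifnot(operand_a >= 0, operand_b >= 0,
            operand_a == trunc(operand_a), operand_b == trunc(operand_b))
  if (operation == "subtraction" && operand_a < operand_b)
    stop("subtraction task requires operand_a >= operand_b")
  structure(list(operand_a = as.integer(operand_a),
                 operand_b = as.integer(operand_b),
                 operation = operation,
                 skill_id = skill_id),
            class = "arith_task")
}

#' @export
format.arith_task <- function(x, ...) {
  sym <- c(addition = "+", subtraction = "-", multiplication = "*")
  sprintf("%d %s %d", x$operand_a, sym[[x$operation]], x$operand_b)
}

#' @export
print.arith_task <- function(x, ...) {
  cat("<task>", format(x), if (!is.na(x$skill_id)) paste0("[", x$skill_id, "]"),
      "\n")
  invisible(x)
}

#' Parse a task from text such as "28+14"
#'
#' @param text A string `"a+b"`, `"a-b"` or `"a*b"`.
#' @param skill_id Optional skill id to attach.
#' @return An [arith_task()].
#' @export
parse_task <- function(text, skill_id = NA_character_) {
  m <- regexec("^\\s*(\\d+)\\s*([-+*])\\s*(\\d+)\\s*$", text)[[1L]]
  if (m[1L] == -1L) stop("cannot parse task: '", text, "'")
  parts <- regmatches(text, regexec("^\\s*(\\d+)\\s*([-+*])\\s*(\\d+)\\s*$",
                                    text))[[1L]]
  op <- switch(parts[3L], "+" = "addition", "-" = "subtraction",
               "*" = "multiplication")
  arith_task(as.integer(parts[2L]), as.integer(parts[4L]), op, skill_id)
}

#' Correct answer of a task
#'
#' @param task An [arith_task()].
#' @return The exact integer result.
#' @export
correct_answer <- function(task) {
  stopifnot(inherits(task, "arith_task"))
  switch(task$operation,
         addition = task$operand_a + task$operand_b,
         subtraction = task$operand_a - task$operand_b,
         multiplication = task$operand_a * task$operand_b)
}

#' The five dyscalculia error cases
#'
#' Wrong answers are diagnosed into five characteristic error patterns,
#' each tied to a memory subtype, via executable buggy rules:
#'
#' * `CASE1_OPERATION_MISATTRIBUTION` (semantic memory): the stated
#'   operation is replaced by multiplication, e.g. 3 + 5 = 15.
#' * `CASE2_NO_CARRY_CONCATENATION` (visuospatial memory): each column is
#'   computed independently and all digits of all column results are
#'   concatenated, no carrying/borrowing, e.g. 28 + 14 = 312.
#' * `CASE3_DIGIT_COLLAPSE` (procedural memory): every digit of both
#'   operands is combined into a single number, ignoring place value,
#'   e.g. 92 + 43 = 18.
#' * `CASE4_CARRY_OMISSION` (procedural memory, "vanishing digits"):
#'   per-column results keep only the units digit, carries/borrows are
#'   discarded, e.g. 39 + 25 = 54.
#' * `CASE5_ZERO_ABSORPTION` (semantic memory): any column containing a
#'   zero digit yields 0, other columns are computed normally,
#'   e.g. 26 + 20 = 40.
#'
#' @format Character vector of the five case labels, in precedence order.
#' @export
error_cases <- c("CASE1_OPERATION_MISATTRIBUTION",
                 "CASE2_NO_CARRY_CONCATENATION",
                 "CASE3_DIGIT_COLLAPSE",
                 "CASE4_CARRY_OMISSION",
                 "CASE5_ZERO_ABSORPTION")

digits_of <- function(x, width = NULL) {
  # least-significant first; zero-padded to width when requested
  d <- integer(0)
  x <- as.integer(x)
  repeat {
    d <- c(d, x %% 10L)
    x <- x %/% 10L
    if (x == 0L) break
  }
  if (!is.null(width) && length(d) < width)
    d <- c(d, rep(0L, width - length(d)))
  d
}

undigits <- function(d) sum(d * 10L^(seq_along(d) - 1L))

#' Apply a buggy rule to a task
#'
#' Computes the answer a learner exhibiting the given error case would
#' produce (see [error_cases] for the rule definitions). Cases 2-4 are
#' defined for addition and subtraction (the subtraction analogues are
#' borrow-omission mirrors: Case 2 concatenates absolute column
#' differences, Case 3 subtracts the digit sums, Case 4 keeps each
#' column's `(a - b) mod 10`). Case 1 replaces the operation with
#' multiplication and Case 5 zeroes any column containing a zero digit.
#'
#' A buggy answer is not guaranteed to differ from the correct one: on a
#' carry-free sum the no-carry rules coincide with the truth.
#'
#' @param task An addition or subtraction [arith_task()].
#' @param case One of [error_cases].
#' @return The integer answer the buggy rule produces.
#' @export
buggy_answer <- function(task, case) {
  stopifnot(inherits(task, "arith_task"))
  case <- match.arg(case, error_cases)
  if (task$operation == "multiplication")
    stop("buggy rules are defined for addition and subtraction tasks")
  a <- task$operand_a
  b <- task$operand_b
  w <- max(length(digits_of(a)), length(digits_of(b)))
  da <- digits_of(a, w) # least-significant first
  db <- digits_of(b, w)
  add <- task$operation == "addition"

  as.integer(switch(case,
    CASE1_OPERATION_MISATTRIBUTION = a * b,
    CASE2_NO_CARRY_CONCATENATION = {
      col <- if (add) da + db else abs(da - db)
      # concatenate all digits of all column results, most significant first
      as.integer(paste(rev(col), collapse = ""))
    },
    CASE3_DIGIT_COLLAPSE = {
      if (add) sum(da) + sum(db) else sum(da) - sum(db)
    },
    CASE4_CARRY_OMISSION = {
      col <- if (add) (da + db) %% 10L else (da - db) %% 10L
      undigits(col)
    },
    CASE5_ZERO_ABSORPTION = {
      res <- integer(w)
      carry <- 0L
      for (i in seq_len(w)) {
        if (da[i] == 0L || db[i] == 0L) {
          res[i] <- 0L
          carry <- 0L
        } else {
          s <- if (add) da[i] + db[i] + carry else da[i] - db[i] - carry
          res[i] <- s %% 10L
          carry <- if (add) s %/% 10L else as.integer(s < 0L)
        }
      }
      undigits(res) + if (add) carry * 10L^w else 0L
    }
  ))
}

#' Classify a learner's answer against the buggy rules
#'
#' Returns `CORRECT` when the answer equals the true result, regardless of
#' whether a buggy rule happens to coincide with it. Otherwise the five
#' buggy rules are evaluated in fixed precedence (Case 1 through Case 5);
#' every rule that reproduces the answer is recorded in `matches`, and the
#' first match is the `primary` diagnosis. When no rule matches the answer
#' is `GENERIC_WRONG`.
#'
#' @param task An [arith_task()].
#' @param answer Integer answer given by the learner.
#' @return A list of class `error_classification` with fields `primary`
#'   (one of [error_cases], `"GENERIC_WRONG"`, `"CORRECT"`) and `matches`
#'   (character vector of all matching rules, in precedence order).
#' @examples
#' classify_error(parse_task("28+14"), 312)$primary  # CASE2
#' @export
classify_error <- function(task, answer) {
  stopifnot(inherits(task, "arith_task"), is.numeric(answer))
  answer <- as.integer(answer)
  out <- function(primary, matches = character(0)) {
    structure(list(primary = primary, matches = matches,
                   task = format(task), answer = answer),
              class = "error_classification")
  }
  if (answer == correct_answer(task)) return(out("CORRECT"))
  if (task$operation == "multiplication") return(out("GENERIC_WRONG"))
  matches <- error_cases[vapply(error_cases, function(cs)
    buggy_answer(task, cs) == answer, logical(1))]
  if (length(matches) == 0L) return(out("GENERIC_WRONG"))
  out(matches[1L], matches)
}

#' @export
print.error_classification <- function(x, ...) {
  cat(sprintf("<classification> %s = %d : %s\n", x$task, x$answer, x$primary))
  if (length(x$matches) > 1L)
    cat("  also matches:", paste(x$matches[-1L], collapse = ", "), "\n")
  invisible(x)
}

# ---- task generation ------------------------------------------------------

range_cap <- function(number_range) {
  switch(number_range, "0-10" = 10L, "0-100" = 100L, "0-1000" = 1000L,
         stop("unknown number_range: ", number_range))
}

digit_bounds <- function(d) {
  if (d == 1L) c(0L, 9L) else c(10L^(d - 1L), 10L^d - 1L)
}

# Constraint specification for a default-roster skill, parsed from its name.
# Returns list(da, db, predicate(a, b)).
skill_task_spec <- function(skill) {
  nm <- skill$name
  op <- skill$operation
  cap <- range_cap(skill$number_range)
  add <- op == "addition"

  if (nm == "Addition to 10")
    return(list(da = c(0L, 10L), db = c(0L, 10L),
                pred = function(a, b) a + b == 10L))
  if (nm == "Subtraction from 10")
    return(list(da = c(10L, 10L), db = c(0L, 10L),
                pred = function(a, b) TRUE))

  m <- regmatches(nm, regexec("([0-9]),([0-9])", nm))[[1L]]
  if (length(m) < 3L) {
    # no digit pattern in the name: generic tasks within the skill's range
    bound <- c(0L, cap)
    pred <- function(a, b) {
      if (op == "multiplication") return(a * b <= cap)
      if (op == "subtraction") return(a >= b)
      a + b <= cap
    }
    return(list(da = bound, db = bound, pred = pred))
  }
  ba <- digit_bounds(as.integer(m[2L]))
  bb <- digit_bounds(as.integer(m[3L]))
  upto5 <- grepl("up to 5", nm)
  withzero <- grepl("with zero", nm)
  bridging <- grepl("bridging to 10", nm)
  mental <- grepl("mental", nm)
  multi <- as.integer(m[2L]) > 1L || as.integer(m[3L]) > 1L

  pred <- function(a, b) {
    if (op == "multiplication") return(a * b <= cap)
    if (op == "subtraction" && a < b) return(FALSE)
    result <- if (add) a + b else a - b
    if (result < 0L || result > cap) return(FALSE)
    if (upto5 && (a > 5L || b > 5L || result > 5L)) return(FALSE)
    if (withzero && !(a == 0L || b == 0L)) return(FALSE)
    units_bridge <- if (add) (a %% 10L) + (b %% 10L) >= 10L
                    else (a %% 10L) < (b %% 10L)
    if (bridging && !units_bridge) return(FALSE)
    # plain/support variants of multi-digit skills stay carry-free;
    # "mental" variants allow either
    if (multi && !bridging && !mental && units_bridge) return(FALSE)
    TRUE
  }
  list(da = ba, db = bb, pred = pred)
}

#' Generate a task for a skill
#'
#' Draws operands uniformly from the skill's constraint set (digit pattern,
#' number range, carrying/borrowing variant) by rejection sampling from the
#' digit-pattern box. Deterministic under a fixed R random seed.
#'
#' @param skill Either a skill id from the default roster (see
#'   [default_skill_graph()]) or a one-row subset of `graph$skills`.
#' @param graph The graph the id is resolved against (default roster by
#'   default).
#' @return An [arith_task()] satisfying the skill's constraints.
#' @export
generate_task <- function(skill, graph = default_skill_graph()) {
  if (is.character(skill)) {
    check_skill(graph, skill)
    skill <- graph$skills[graph$skills$id == skill, ]
  }
  spec <- skill_task_spec(skill)
  for (i in 1:10000) {
    a <- sample.int(spec$da[2L] - spec$da[1L] + 1L, 1L) + spec$da[1L] - 1L
    b <- sample.int(spec$db[2L] - spec$db[1L] + 1L, 1L) + spec$db[1L] - 1L
    if (skill$operation == "subtraction" && a < b &&
        identical(spec$da, spec$db)) { tmp <- a; a <- b; b <- tmp }
    if (spec$pred(a, b))
      return(arith_task(a, b, skill$operation, skill$id))
  }
  stop("could not generate a task satisfying constraints of '", skill$id, "'")
}
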