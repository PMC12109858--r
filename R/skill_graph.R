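#' Construct a prerequisite skill graph
#'
#' A skill graph is a directed acyclic graph (DAG) over named arithmetic
#' skills. An edge `A -> B` states that mastering skill `A` is a necessary
#' condition for mastering skill `B` (precursor -> successor). The student
#' model and the pedagogical controller both operate on this structure.
#'
#' @param skills A data.frame with columns `id` (unique character), `name`
#'   (human label), `operation` (one of `"addition"`, `"subtraction"`,
#'   `"multiplication"`), `number_range` (one of `"0-10"`, `"0-100"`,
#'   `"0-1000"`), `difficulty_rank` (integer >= 0, ordered within its
#'   operation), and optionally `variant_tags` (a list column of character
#'   vectors drawn from `"support"`, `"bridging_to_10"`, `"mental"`,
#'   `"none"`).
#' @param edges A two-column data.frame (or matrix) of character ids,
#'   `from` (precursor) and `to` (successor). May have zero rows.
#' @return An object of class `skill_graph`.
#' @seealso [validate_skill_graph()], [default_skill_graph()],
#'   [topological_order()]
#' @export
skill_graph <- function(skills, edges = NULL) {
  stopifnot(is.data.frame(skills), all(c("id", "name", "operation",
    "number_range", "difficulty_rank") %in% names(skills)))
  skills$id <- as.character(skills$id)
  skills$name <- as.character(skills$name)
  skills$operation <- as.character(skills$operation)
  skills$number_range <- as.character(skills$number_range)
  skills$difficulty_rank <- as.integer(skills$difficulty_rank)
  if (is.null(skills$variant_tags)) {
    skills$variant_tags <- replicate(nrow(skills), "none", simplify = FALSE)
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  rownames(skills) <- NULL
  rownames(edges) <- NULL
  structure(list(skills = skills, edges = edges), class = "skill_graph")
}

#' @export
print.skill_graph <- function(x, ...) {
  cat(sprintf("<skill_graph> %d skills, %d edges\n",
              nrow(x$skills), nrow(x$edges)))
  ops <- table(x$skills$operation)
  cat("  operations:", paste(sprintf("%s (%d)", names(ops), ops),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Validate a skill graph
#'
#' Checks the structural invariants of a prerequisite graph and reports every
#' violation found instead of stopping at the first. A graph is valid iff the
#' returned report has zero rows.
#'
#' Checked invariants: skill ids are unique; every edge endpoint names an
#' existing skill; the graph is acyclic; and `difficulty_rank` strictly
#' increases along every same-operation edge (hence along every directed path
#' within one operation).
#'
#' @param graph A [skill_graph()].
#' @return A data.frame with columns `type` (one of `"duplicate_id"`,
#'   `"dangling_edge"`, `"cycle"`, `"difficulty_order"`) and `detail`
#'   (a human-readable description). Zero rows means the graph is valid.
#' @export
validate_skill_graph <- function(graph) {
  stopifnot(inherits(graph, "skill_graph"))
  viol <- list()
  add <- function(type, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(type = type, detail = detail,
                                             stringsAsFactors = FALSE)
  }
  ids <- graph$skills$id
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("duplicate_id", sprintf("skill id '%s' appears more than once", d))

  known <- unique(ids)
  if (nrow(graph$edges) > 0L) {
    for (i in seq_len(nrow(graph$edges))) {
      e <- graph$edges[i, ]
      for (endpoint in c(e$from, e$to)) {
        if (!endpoint %in% known)
          add("dangling_edge",
              sprintf("edge %s -> %s references unknown skill '%s'",
                      e$from, e$to, endpoint))
      }
    }
  }

  # cycle check on the subgraph of well-formed edges (Kahn's algorithm)
  ok_edges <- graph$edges[graph$edges$from %in% known &
                          graph$edges$to %in% known, , drop = FALSE]
  leftover <- kahn_order(known, ok_edges)$leftover
  if (length(leftover) > 0L)
    add("cycle", sprintf("cycle detected among skills: %s",
                         paste(sort(leftover), collapse = ", ")))

  if (nrow(ok_edges) > 0L) {
    rank_of <- stats::setNames(graph$skills$difficulty_rank, graph$skills$id)
    op_of <- stats::setNames(graph$skills$operation, graph$skills$id)
    same_op <- op_of[ok_edges$from] == op_of[ok_edges$to]
    bad <- same_op & rank_of[ok_edges$from] >= rank_of[ok_edges$to]
    for (i in which(bad))
      add("difficulty_order",
          sprintf("edge %s -> %s does not increase difficulty_rank (%d >= %d)",
                  ok_edges$from[i], ok_edges$to[i],
                  rank_of[[ok_edges$from[i]]], rank_of[[ok_edges$to[i]]]))
  }

  if (length(viol) == 0L)
    return(data.frame(type = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

# Kahn's algorithm with a caller-supplied priority for deterministic ties.
# Returns list(order, leftover): leftover non-empty iff a cycle exists.
kahn_order <- function(ids, edges, priority = NULL) {
  ids <- unique(ids)
  n <- length(ids)
  if (n == 0L) return(list(order = character(), leftover = character()))
  indeg <- stats::setNames(integer(n), ids)
  succ <- stats::setNames(vector("list", n), ids)
  if (NROW(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      f <- edges$from[i]; t <- edges$to[i]
      indeg[[t]] <- indeg[[t]] + 1L
      succ[[f]] <- c(succ[[f]], t)
    }
  }
  if (is.null(priority)) priority <- stats::setNames(numeric(n), ids)
  order_key <- function(v) order(priority[v], v)
  frontier <- ids[indeg[ids] == 0L]
  out <- character(0)
  while (length(frontier) > 0L) {
    frontier <- frontier[order_key(frontier)]
    v <- frontier[1L]
    frontier <- frontier[-1L]
    out <- c(out, v)
    for (s in succ[[v]]) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) frontier <- c(frontier, s)
    }
  }
  list(order = out, leftover = setdiff(ids, out))
}

#' Topological order of a skill graph
#'
#' Returns a linear ordering of skill ids in which every precursor appears
#' before all of its successors. Ties between simultaneously available skills
#' are broken deterministically by `(difficulty_rank, id)`, so repeated calls
#' and tutoring sessions are reproducible.
#'
#' @param graph A valid [skill_graph()].
#' @return Character vector of all skill ids, a permutation respecting every
#'   edge.
#' @export
topological_order <- function(graph) {
  stopifnot(inherits(graph, "skill_graph"))
  priority <- stats::setNames(graph$skills$difficulty_rank, graph$skills$id)
  res <- kahn_order(graph$skills$id, graph$edges, priority)
  if (length(res$leftover) > 0L)
    stop("graph contains a cycle; topological order undefined (skills: ",
         paste(sort(res$leftover), collapse = ", "), ")")
  res$order
}

check_skill <- function(graph, skill_id) {
  if (!skill_id %in% graph$skills$id)
    stop("unknown skill id: '", skill_id, "'")
  invisible(TRUE)
}

#' Direct precursors and successors of a skill
#'
#' One-hop neighbourhood queries on the prerequisite DAG: `skill_precursors`
#' returns the skills whose mastery is a direct prerequisite for `skill_id`;
#' `skill_successors` returns the skills that directly depend on it.
#'
#' @param graph A [skill_graph()].
#' @param skill_id A skill id present in the graph.
#' @return Character vector of skill ids (possibly empty), sorted.
#' @export
skill_precursors <- function(graph, skill_id) {
  check_skill(graph, skill_id)
  sort(unique(graph$edges$from[graph$edges$to == skill_id]))
}

#' @rdname skill_precursors
#' @export
skill_successors <- function(graph, skill_id) {
  check_skill(graph, skill_id)
  sort(unique(graph$edges$to[graph$edges$from == skill_id]))
}

# canonical form used for round-trip equality checks
normalize_skill_graph <- function(graph) {
  sk <- graph$skills[order(graph$skills$id), , drop = FALSE]
  sk$variant_tags <- lapply(sk$variant_tags, function(v) sort(as.character(v)))
  ed <- graph$edges
  if (nrow(ed) > 0L) ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(sk) <- NULL
  rownames(ed) <- NULL
  list(skills = sk, edges = ed)
}

#' Test two skill graphs for equality up to ordering
#'
#' @param a,b [skill_graph()] objects.
#' @param structure_only Compare only ids and edges (used for formats, such
#'   as the DAGitty text dialect, that carry no skill metadata).
#' @return `TRUE` or `FALSE`.
#' @export
skill_graph_equal <- function(a, b, structure_only = FALSE) {
  na <- normalize_skill_graph(a)
  nb <- normalize_skill_graph(b)
  if (structure_only) {
    return(identical(na$skills$id, nb$skills$id) &&
           identical(na$edges, nb$edges))
  }
  isTRUE(all.equal(na, nb, check.attributes = FALSE))
}
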