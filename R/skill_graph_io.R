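#' Read and write skill graphs
#'
#' Two serializations are supported:
#'
#' * `"json"` — the full graph, schema
#'   `{"skills": [{"id","name","operation","number_range","difficulty_rank",
#'   "variant_tags"}], "edges": [["pre","succ"], ...]}`. Lossless.
#' * `"dagitty"` — the DAGitty text dialect, `dag { "A" "B" "A" -> "B" }`,
#'   with quoted node labels and one `->` statement per edge. The dialect
#'   carries structure only; on import, skill metadata is reconstructed:
#'   the operation is parsed from the leading word of the label when it is
#'   Addition/Subtraction/Multiplication (default `"addition"`), the
#'   difficulty rank is the longest-path depth from a root (which always
#'   respects edge monotonicity), and the number range defaults to
#'   `"0-100"`.
#'
#' @param source For `read_skill_graph`, a file path or a character scalar
#'   containing the serialized text.
#' @param format `"json"` or `"dagitty"`.
#' @param graph A [skill_graph()].
#' @param file Optional path; when given the text is also written there.
#' @return `read_skill_graph`: a [skill_graph()]. `write_skill_graph`: the
#'   serialized text, invisibly when `file` is given.
#' @export
read_skill_graph <- function(source, format = c("json", "dagitty")) {
  format <- match.arg(format)
  text <- if (length(source) == 1L && !grepl("[{\n]", source) &&
              file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  if (format == "json") parse_graph_json(text) else parse_graph_dagitty(text)
}

#' @rdname read_skill_graph
#' @export
write_skill_graph <- function(graph, format = c("json", "dagitty"),
                              file = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "skill_graph"))
  g <- normalize_skill_graph(graph)
  text <- if (format == "json") {
    payload <- list(
      skills = lapply(seq_len(nrow(g$skills)), function(i) {
        s <- g$skills[i, ]
        list(id = s$id, name = s$name, operation = s$operation,
             number_range = s$number_range,
             difficulty_rank = s$difficulty_rank,
             variant_tags = as.list(s$variant_tags[[1L]]))
      }),
      edges = lapply(seq_len(nrow(g$edges)),
                     function(i) list(g$edges$from[i], g$edges$to[i]))
    )
    jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  } else {
    q <- function(x) paste0('"', x, '"')
    lines <- c("dag {",
               paste0("  ", q(g$skills$id)),
               if (nrow(g$edges) > 0L)
                 paste0("  ", q(g$edges$from), " -> ", q(g$edges$to)),
               "}")
    paste(lines, collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

parse_graph_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(obj$skills))
    stop("JSON graph parse error: missing 'skills' array")
  skills <- do.call(rbind, lapply(obj$skills, function(s) {
    data.frame(id = s$id, name = s$name %||% s$id,
               operation = s$operation %||% "addition",
               number_range = s$number_range %||% "0-100",
               difficulty_rank = as.integer(s$difficulty_rank %||% 0L),
               stringsAsFactors = FALSE)
  }))
  skills$variant_tags <- lapply(obj$skills, function(s) {
    v <- unlist(s$variant_tags)
    if (length(v) == 0L) "none" else as.character(v)
  })
  edges <- if (length(obj$edges) > 0L) {
    do.call(rbind, lapply(obj$edges, function(e) {
      if (length(e) != 2L)
        stop("JSON graph parse error: edge must be a pair, got length ",
             length(e))
      data.frame(from = e[[1L]], to = e[[2L]], stringsAsFactors = FALSE)
    }))
  } else NULL
  skill_graph(skills, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_graph_dagitty <- function(text) {
  body <- regmatches(text, regexec("dag\\s*\\{(.*)\\}", text))[[1L]]
  if (length(body) < 2L) {
    nline <- which(!grepl("\\{", strsplit(text, "\n")[[1L]]))[1L]
    stop("DAGitty parse error: no balanced 'dag { ... }' block",
         if (!is.na(nline)) sprintf(" (near line %d)", nline))
  }
  body <- body[2L]
  # tokens: quoted labels, bare words, '->'; attribute blocks [...] dropped
  body <- gsub("\\[[^]]*\\]", " ", body)
  tokens <- regmatches(body,
    gregexpr('"[^"]*"|->|<-|[^\\s;,]+', body, perl = TRUE))[[1L]]
  unquote <- function(x) gsub('^"|"$', "", x)
  nodes <- character(0)
  edges_from <- character(0)
  edges_to <- character(0)
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (tok %in% c("->", "<-"))
      stop("DAGitty parse error: dangling '", tok, "' at token ", i)
    a <- unquote(tok)
    nodes <- c(nodes, a)
    if (i + 1L <= length(tokens) && tokens[i + 1L] %in% c("->", "<-")) {
      if (i + 2L > length(tokens))
        stop("DAGitty parse error: edge operator at end of input")
      b <- unquote(tokens[i + 2L])
      nodes <- c(nodes, b)
      if (tokens[i + 1L] == "->") {
        edges_from <- c(edges_from, a); edges_to <- c(edges_to, b)
      } else {
        edges_from <- c(edges_from, b); edges_to <- c(edges_to, a)
      }
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  nodes <- unique(nodes)
  edges <- if (length(edges_from) > 0L)
    unique(data.frame(from = edges_from, to = edges_to,
                      stringsAsFactors = FALSE)) else NULL

  depth <- longest_path_depth(nodes, edges)
  op_guess <- function(nm) {
    w <- tolower(strsplit(nm, "[ _]")[[1L]][1L])
    if (w %in% c("addition", "subtraction", "multiplication")) w else "addition"
  }
  skills <- data.frame(id = nodes, name = nodes,
                       operation = vapply(nodes, op_guess, character(1)),
                       number_range = "0-100",
                       difficulty_rank = as.integer(depth[nodes]),
                       stringsAsFactors = FALSE)
  skill_graph(skills, edges)
}

# longest-path depth from any root; 0 for roots, used as a rank surrogate
longest_path_depth <- function(ids, edges) {
  depth <- stats::setNames(integer(length(ids)), ids)
  if (NROW(edges) > 0L) {
    ord <- kahn_order(ids, edges)
    if (length(ord$leftover) > 0L)
      stop("DAGitty parse error: imported graph contains a cycle")
    for (v in ord$order) {
      pre <- edges$from[edges$to == v]
      if (length(pre) > 0L) depth[[v]] <- max(depth[pre]) + 1L
    }
  }
  depth
}
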