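#' Read and write session logs as JSONL
#'
#' One JSON object per line, one line per step, with the session-log
#' columns (`step`, `skill_id`, `task`, `answer`, `correct`, `error_case`,
#' `posterior_before`, `posterior_after`, `action`, `PLT`, `PUT`,
#' `rt_seconds`). Multiple sessions in one file are distinguished by a
#' `session` field.
#'
#' @param logs A `session_log` or a list of them.
#' @param path File path.
#' @return `write_session_logs`: the path, invisibly.
#'   `read_session_logs`: a list of `session_log` data.frames.
#' @export
write_session_logs <- function(logs, path) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(logs)) {
    log <- logs[[i]]
    for (j in seq_len(nrow(log))) {
      rec <- c(list(session = i), as.list(log[j, , drop = FALSE]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_session_logs
#' @export
read_session_logs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l,
                                                       simplifyVector = TRUE))
  df <- do.call(rbind, lapply(recs, as.data.frame, stringsAsFactors = FALSE))
  lapply(split(df, df$session), function(g) {
    g$session <- NULL
    rownames(g) <- NULL
    structure(g, class = c("session_log", "data.frame"))
  })
}

#' Read and write observation streams as JSONL
#'
#' One [observation()] per line, fields `skill_id`, `C`, `W`, `SW`, `H`,
#' `A`, `response_time`.
#'
#' @param observations A list of [observation()] objects.
#' @param path File path.
#' @return `write_observations`: the path, invisibly.
#'   `read_observations`: a list of observations.
#' @export
write_observations <- function(observations, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (obs in observations) {
    writeLines(jsonlite::toJSON(unclass(obs), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    observation(o$skill_id, C = o$C, W = o$W, SW = o$SW, H = o$H, A = o$A,
                response_time = o$response_time %||% NA_real_)
  })
}

#' Snapshot a knowledge state to JSON (and back)
#'
#' Serializes the mastery posteriors and per-skill observation windows so
#' a tutoring session can be suspended and resumed.
#'
#' @param state A `knowledge_state`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return `knowledge_state_json`: JSON text (invisibly when written to a
#'   file). `read_knowledge_state`: a `knowledge_state`.
#' @export
knowledge_state_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "knowledge_state"))
  payload <- list(
    memory = state$memory,
    prior = state$prior,
    posteriors = as.list(state$posteriors),
    last_message = as.list(state$last_message),
    windows = lapply(state$windows, function(w) lapply(w, unclass))
  )
  text <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' @rdname knowledge_state_json
#' @param source JSON text or a file path.
#' @export
read_knowledge_state <- function(source) {
  text <- if (length(source) == 1L && !grepl("[{\n]", source) &&
              file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else source
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  ids <- names(obj$posteriors)
  structure(list(
    posteriors = stats::setNames(vapply(obj$posteriors, as.numeric,
                                        numeric(1)), ids),
    windows = stats::setNames(lapply(obj$windows, function(w)
      lapply(w, function(o)
        observation(o$skill_id, C = o$C, W = o$W, SW = o$SW, H = o$H,
                    A = o$A,
                    response_time = if (is.null(o$response_time))
                      NA_real_ else o$response_time))), names(obj$windows)),
    last_message = stats::setNames(vapply(obj$last_message, function(x)
      if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)), ids),
    memory = as.integer(obj$memory),
    prior = as.numeric(obj$prior)
  ), class = "knowledge_state")
}
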