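#' The packaged 38-skill arithmetic topology
#'
#' Builds the default prerequisite graph used throughout the package: 38
#' arithmetic skills ordered hierarchically by number range (0-10, 0-100,
#' 0-1000), with addition and subtraction mirroring each other (18 skills
#' each, six per range) plus two multiplication skills ("Multiplication 1,1"
#' and "Multiplication 2,2").
#'
#' Within the 0-100 range the addition chain runs
#' `Addition 1,1 -> Addition 2,1 with support -> Addition 2,1 ->
#' Addition 2,1 with bridging to 10 -> Addition 2,2 -> ...`, i.e. tasks with
#' larger operands, and tasks requiring a carry ("bridging to 10"), rank as
#' harder. The subtraction structure is derived by substituting Subtraction
#' for Addition ("bridging" then denotes a borrow). Skills are chained
#' linearly within each operation; no cross-operation prerequisite edges are
#' created.
#'
#' The exact 38-skill membership is a documented fixture reconstruction: the
#' source system reports the count and the 0-100 addition chain but does not
#' enumerate the full roster. Edit the JSON serialization
#' ([write_skill_graph()]) to adapt the roster.
#'
#' @return A valid [skill_graph()] with 38 skills. Deterministic: repeated
#'   calls return identical graphs.
#' @examples
#' g <- default_skill_graph()
#' nrow(g$skills)              # 38
#' skill_precursors(g, "Addition 2,2")
#' @export
default_skill_graph <- function() {
  ladder <- function(op) {
    # six skills per number range, ranks 0..17 along the chain
    to10 <- if (op == "Addition") "Addition to 10" else "Subtraction from 10"
    data.frame(
      name = c(
        paste(op, "1,1 up to 5"),
        paste(op, "1,1 with zero"),
        paste(op, "1,1 with support"),
        paste(op, "1,1"),
        paste(op, "1,1 mental"),
        to10,
        paste(op, "2,1 with support"),
        paste(op, "2,1"),
        paste(op, "2,1 with bridging to 10"),
        paste(op, "2,2"),
        paste(op, "2,2 with bridging to 10"),
        paste(op, "2,2 mental"),
        paste(op, "3,1"),
        paste(op, "3,2"),
        paste(op, "3,2 with bridging to 10"),
        paste(op, "3,3"),
        paste(op, "3,3 with bridging to 10"),
        paste(op, "3,3 mental")
      ),
      operation = tolower(op),
      number_range = rep(c("0-10", "0-100", "0-1000"), each = 6L),
      difficulty_rank = 0:17,
      stringsAsFactors = FALSE
    )
  }
  skills <- rbind(
    ladder("Addition"),
    ladder("Subtraction"),
    data.frame(
      name = c("Multiplication 1,1", "Multiplication 2,2"),
      operation = "multiplication",
      number_range = c("0-100", "0-1000"),
      difficulty_rank = 0:1,
      stringsAsFactors = FALSE
    )
  )
  skills$id <- skills$name
  skills$variant_tags <- lapply(skills$name, function(nm) {
    tags <- character(0)
    if (grepl("with support", nm)) tags <- c(tags, "support")
    if (grepl("bridging to 10", nm)) tags <- c(tags, "bridging_to_10")
    if (grepl("mental", nm)) tags <- c(tags, "mental")
    if (length(tags) == 0L) tags <- "none"
    tags
  })
  skills <- skills[, c("id", "name", "operation", "number_range",
                       "difficulty_rank", "variant_tags")]

  chain_edges <- function(ids) {
    if (length(ids) < 2L) return(NULL)
    data.frame(from = ids[-length(ids)], to = ids[-1L],
               stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, lapply(split(skills$id, skills$operation),
    function(ids) chain_edges(ids[order(skills$difficulty_rank[
      match(ids, skills$id)])])))
  rownames(edges) <- NULL
  skill_graph(skills, edges)
}
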