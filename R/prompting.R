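#' Default task description for the re-ranking prompt
#'
#' A one-sentence instruction to order the choices from most to least specific
#' match for the query. Overridable wherever a prompt is assembled.
#' @export
default_task_description <- function() {
  paste("Rank the given choices from the most specific matching term for the",
        "query to the least specific, and output the full ordered list.")
}

#' Construct a demonstration (worked example) for the prompt
#'
#' A demonstration pairs a query entity name with an ordered choice list and
#' an ordered answer list. A real demonstration (from a labelled pair) must
#' answer with names drawn from its choices; a pseudo demonstration
#' (`is_pseudo = TRUE`) is exempt since it only conveys output format.
#'
#' @param query_name query entity surface name.
#' @param choice_names ordered candidate names (nonempty).
#' @param answer_names ordered answer names.
#' @param is_pseudo whether this is a format-only out-of-domain example.
#' @return object of class `bkf_demo`.
#' @export
demonstration <- function(query_name, choice_names, answer_names,
                          is_pseudo = FALSE) {
  if (length(choice_names) == 0L)
    abort_bkf("demonstration needs at least one choice", "bkf_validation_error")
  if (!is_pseudo && !all(answer_names %in% choice_names))
    abort_bkf(sprintf("answer name '%s' is not among the choices",
                      setdiff(answer_names, choice_names)[[1]]),
              "bkf_validation_error")
  structure(list(query_name = query_name,
                 choice_names = as.character(choice_names),
                 answer_names = as.character(answer_names),
                 is_pseudo = isTRUE(is_pseudo)),
            class = "bkf_demo")
}

#' Render a demonstration as its three-line prompt block
#'
#' Exactly three lines: `Query: {q}`, `Choices: {c1; c2; ...}`,
#' `Answer: {a1; a2; ...}`, with "; " separating names.
#'
#' @param d a [demonstration()].
#' @return a single string with embedded newlines.
#' @export
render_demonstration <- function(d) {
  paste0("Query: ", d$query_name, "\n",
         "Choices: ", paste(d$choice_names, collapse = "; "), "\n",
         "Answer: ", paste(d$answer_names, collapse = "; "))
}

#' Built-in pseudo demonstration for the zero-shot setting
#'
#' With no labelled pairs (M = 0) the prompt still needs one worked example so
#' the backend produces answers in a parseable format. This fixed,
#' deterministic example is deliberately out of domain — musical instruments,
#' sharing no vocabulary with biomedical data — so it cannot leak task
#' knowledge, only the output format.
#'
#' @return a [demonstration()] with `is_pseudo = TRUE`.
#' @export
make_pseudo_demonstration <- function() {
  demonstration(
    query_name = "violin",
    choice_names = c("bowed string instrument", "plucked string instrument",
                     "keyboard instrument", "woodwind instrument"),
    answer_names = c("bowed string instrument", "plucked string instrument",
                     "keyboard instrument", "woodwind instrument"),
    is_pseudo = TRUE)
}

#' Hierarchy context lines for a candidate list
#'
#' One line per candidate, in candidate order:
#' `{name} isA {parent name, parent name, ...}` with parents in lexicographic
#' id order; a root candidate gets the placeholder `{name} isA ROOT`.
#' `depth > 1` extends each line through grandparent layers, each introduced
#' by a further ` isA `.
#'
#' @param h the `bkf_hierarchy`.
#' @param candidates a `bkf_candidates`.
#' @param depth how many hypernym layers to include (default 1: direct
#'   parents).
#' @return character vector, one entry per candidate.
#' @export
make_hierarchy_context <- function(h, candidates, depth = 1L) {
  vapply(candidates$ranked$term_id, function(tid) {
    check_term(h, tid)
    line <- h$terms[[tid]]$name
    frontier <- tid
    for (lvl in seq_len(depth)) {
      ps <- lex_sort(unique(unlist(lapply(frontier, term_parents, h = h),
                                   use.names = FALSE)))
      if (length(ps) == 0L) {
        if (lvl == 1L) line <- paste0(line, " isA ROOT")
        break
      }
      nms <- vapply(h$terms[ps], `[[`, "", "name")
      line <- paste0(line, " isA ", paste(nms, collapse = ", "))
      frontier <- ps
    }
    line
  }, "", USE.NAMES = FALSE)
}

#' Assemble the full re-ranking prompt
#'
#' Layout: task description, blank line, each demonstration block, blank
#' line, the optional `Contexts: {...}` line (context entries joined by "; "),
#' then the test block `Query: ...` / `Choices: ...` and the terminal line
#' `Answer:` left open for the backend to complete.
#'
#' @param candidates a `bkf_candidates` (nonempty).
#' @param kg the source `bkf_kg` (for the query entity's name).
#' @param h the target `bkf_hierarchy` (for candidate names and context).
#' @param demos list of [demonstration()]s; default one pseudo demonstration.
#' @param with_context include the hierarchy context line.
#' @param task_description instruction text; see [default_task_description()].
#' @param budget_chars hard cap on prompt length. The default 16000 chars
#'   approximates a 4096-token completion window at ~4 chars/token. Overflow
#'   is an error, never a silent truncation.
#' @param context_depth hypernym layers in the context lines.
#' @return object of class `bkf_prompt` with the rendered string and its
#'   components.
#' @export
assemble_prompt <- function(candidates, kg, h,
                            demos = list(make_pseudo_demonstration()),
                            with_context = TRUE,
                            task_description = default_task_description(),
                            budget_chars = 16000L, context_depth = 1L) {
  if (nrow(candidates$ranked) == 0L)
    abort_bkf("cannot build a prompt from an empty candidate list",
              "bkf_validation_error")
  check_entity(kg, candidates$entity_id)
  test_query <- kg$entities[[candidates$entity_id]]$name
  test_choices <- vapply(candidates$ranked$term_id, function(tid) {
    check_term(h, tid)
    h$terms[[tid]]$name
  }, "", USE.NAMES = FALSE)
  context_lines <- NULL
  if (isTRUE(with_context))
    context_lines <- make_hierarchy_context(h, candidates, context_depth)

  blocks <- c(task_description,
              vapply(demos, render_demonstration, ""))
  test_block <- paste0(
    if (!is.null(context_lines))
      paste0("Contexts: ", paste(context_lines, collapse = "; "), "\n"),
    "Query: ", test_query, "\n",
    "Choices: ", paste(test_choices, collapse = "; "), "\n",
    "Answer:")
  rendered <- paste(c(blocks, test_block), collapse = "\n\n")
  if (nchar(rendered) > budget_chars)
    abort_bkf(sprintf("rendered prompt is %d chars, %d over the %d budget",
                      nchar(rendered), nchar(rendered) - budget_chars,
                      budget_chars),
              "bkf_budget_error")
  structure(list(task_description = task_description, demonstrations = demos,
                 context_lines = context_lines, test_query = test_query,
                 test_choices = test_choices, entity_id = candidates$entity_id,
                 term_ids = candidates$ranked$term_id, rendered = rendered),
            class = "bkf_prompt")
}

#' @export
print.bkf_prompt <- function(x, ...) {
  cat(x$rendered, "\n")
  invisible(x)
}
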