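#' @section Domain model:
#' The source side of a fusion task is a multi-relational knowledge graph
#' (entities with textual attributes plus relational triples); the target side
#' is a hierarchy: terms connected by hypernym (child -> parent, "is-a") edges
#' forming a directed acyclic graph with at least one root. Gold alignments
#' link each entity to its most specific term, one-to-one.
#'
#' @name bkfuse-model
NULL

new_entity <- function(id, name, synonyms = character(0), definition = "",
                       semantic_types = character(0)) {
  list(id = as.character(id), name = as.character(name),
       synonyms = as.character(synonyms), definition = as.character(definition),
       semantic_types = as.character(semantic_types))
}

new_term <- function(id, name, synonyms = character(0), definition = "") {
  list(id = as.character(id), name = as.character(name),
       synonyms = as.character(synonyms), definition = as.character(definition))
}

check_names <- function(items, what) {
  ids <- vapply(items, `[[`, "", "id")
  nms <- vapply(items, `[[`, "", "name")
  if (any(!nzchar(ids)))
    abort_bkf(sprintf("%s with empty id", what), "bkf_validation_error")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    abort_bkf(sprintf("duplicate %s id: %s", what, dup[[1]]),
              "bkf_validation_error")
  if (any(!nzchar(nms)))
    abort_bkf(sprintf("%s '%s' has empty name", what, ids[!nzchar(nms)][[1]]),
              "bkf_validation_error")
  bad <- grepl(";", nms, fixed = TRUE)
  if (any(bad))
    abort_bkf(sprintf(
      "%s '%s' has a name containing ';', which is reserved as the prompt choice separator",
      what, ids[bad][[1]]), "bkf_validation_error")
  ids
}

#' Construct a validated knowledge graph
#'
#' @param entities list of entity records (each a list with `id`, `name`, and
#'   optional `synonyms`, `definition`, `semantic_types`).
#' @param triples data.frame with character columns `head`, `relation`, `tail`.
#' @return an object of class `bkf_kg` with fields `entities` (named list),
#'   `relations` (distinct relation names) and `triples`.
#' @export
knowledge_graph <- function(entities, triples = NULL) {
  entities <- lapply(entities, function(e)
    new_entity(e$id, e$name, e$synonyms %||% character(0),
               e$definition %||% "", e$semantic_types %||% character(0)))
  ids <- check_names(entities, "entity")
  names(entities) <- ids
  if (is.null(triples))
    triples <- data.frame(head = character(0), relation = character(0),
                          tail = character(0))
  triples <- data.frame(head = as.character(triples$head),
                        relation = as.character(triples$relation),
                        tail = as.character(triples$tail))
  for (col in c("head", "tail")) {
    missing <- !(triples[[col]] %in% ids)
    if (any(missing)) {
      i <- which(missing)[[1]]
      abort_bkf(sprintf("triple %d references unknown entity '%s'",
                        i, triples[[col]][[i]]), "bkf_validation_error")
    }
  }
  structure(list(entities = entities,
                 relations = lex_sort(unique(triples$relation)),
                 triples = triples),
            class = "bkf_kg")
}

#' Construct a validated hierarchy
#'
#' Validates referential integrity, duplicate edges, acyclicity (reporting one
#' offending cycle on failure) and the existence of at least one root, then
#' precomputes parent/child adjacency, depths and ancestor closures.
#'
#' Depth convention: a root has depth 1 and `depth(t)` is 1 plus the length of
#' the shortest child-to-parent path from `t` to the nearest root. Rooting the
#' scale at 1 keeps Wu-Palmer similarity strictly positive for co-rooted terms.
#'
#' @param terms list of term records (`id`, `name`, optional `synonyms`,
#'   `definition`).
#' @param edges data.frame with character columns `child`, `parent`
#'   (hypernym pairs).
#' @return an object of class `bkf_hierarchy`.
#' @export
hierarchy <- function(terms, edges = NULL) {
  terms <- lapply(terms, function(t)
    new_term(t$id, t$name, t$synonyms %||% character(0), t$definition %||% ""))
  ids <- check_names(terms, "term")
  names(terms) <- ids
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0))
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent))
  for (col in c("child", "parent")) {
    missing <- !(edges[[col]] %in% ids)
    if (any(missing))
      abort_bkf(sprintf("edge references unknown term '%s'",
                        edges[[col]][which(missing)[[1]]]),
                "bkf_validation_error")
  }
  key <- paste(edges$child, edges$parent, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][[1]], "\r", fixed = TRUE)[[1]]
    abort_bkf(sprintf("duplicate edge (%s -> %s)", d[[1]], d[[2]]),
              "bkf_validation_error")
  }
  if (any(edges$child == edges$parent))
    abort_bkf(sprintf("self-loop at term '%s'",
                      edges$child[edges$child == edges$parent][[1]]),
              "bkf_validation_error")

  parents_of <- lapply(split(edges$parent, factor(edges$child, levels = ids)),
                       lex_sort)
  children_of <- lapply(split(edges$child, factor(edges$parent, levels = ids)),
                        lex_sort)

  # Kahn's algorithm over the parent -> child orientation: peels roots first,
  # yields depths (1 + min over parents) and a topological order for the
  # ancestor closure; leftover nodes expose a cycle.
  n_par <- vapply(parents_of, length, 0L)
  depths <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ancestors_of <- stats::setNames(vector("list", length(ids)), ids)
  # A finite graph with no parentless term necessarily contains a cycle, so
  # the rootless case is diagnosed below with the offending cycle spelled out.
  queue <- lex_sort(ids[n_par == 0L])
  remaining <- n_par
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    ps <- parents_of[[t]]
    if (length(ps) == 0L) {
      depths[[t]] <- 1L
      ancestors_of[[t]] <- character(0)
    } else {
      depths[[t]] <- 1L + min(depths[ps])
      ancestors_of[[t]] <- lex_sort(unique(c(ps, unlist(ancestors_of[ps],
                                                        use.names = FALSE))))
    }
    for (ch in children_of[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    cyc <- find_cycle(parents_of, names(remaining)[remaining > 0L])
    abort_bkf(sprintf("hierarchy contains a cycle: %s",
                      paste(cyc, collapse = " -> ")),
              "bkf_cycle_error")
  }
  structure(list(terms = terms, edges = edges, parents_of = parents_of,
                 children_of = children_of, depths = depths,
                 ancestors_of = ancestors_of),
            class = "bkf_hierarchy")
}

# Walk child -> parent among unresolved nodes until a repeat closes the loop.
find_cycle <- function(parents_of, stuck) {
  cur <- lex_sort(stuck)[[1]]
  path <- character(0)
  while (!(cur %in% path)) {
    path <- c(path, cur)
    cur <- intersect(parents_of[[cur]], stuck)[[1]]
  }
  i <- match(cur, path)
  c(path[i:length(path)], cur)
}

check_term <- function(h, id) {
  if (!(id %in% names(h$terms)))
    abort_bkf(sprintf("unknown term id '%s'", id), "bkf_lookup_error")
}

check_entity <- function(kg, id) {
  if (!(id %in% names(kg$entities)))
    abort_bkf(sprintf("unknown entity id '%s'", id), "bkf_lookup_error")
}

#' Hierarchy accessors
#'
#' `term_depth` follows the root-depth-1 convention (shortest path to the
#' nearest root on DAGs); `term_parents` returns direct hypernyms in
#' lexicographic id order; `term_ancestors` is the transitive closure of
#' `term_parents`, excluding the term itself; `hier_roots` lists the terms
#' with no parent.
#'
#' @param h a `bkf_hierarchy`.
#' @param id a term id present in `h`.
#' @return integer depth, character vector of ids, or character vector of ids.
#' @export
term_depth <- function(h, id) {
  check_term(h, id)
  h$depths[[id]]
}

#' @rdname term_depth
#' @export
term_parents <- function(h, id) {
  check_term(h, id)
  h$parents_of[[id]]
}

#' @rdname term_depth
#' @export
term_ancestors <- function(h, id) {
  check_term(h, id)
  h$ancestors_of[[id]]
}

#' @rdname term_depth
#' @export
term_children <- function(h, id) {
  check_term(h, id)
  h$children_of[[id]]
}

#' @rdname term_depth
#' @export
hier_roots <- function(h) {
  lex_sort(names(h$terms)[vapply(h$parents_of, length, 0L) == 0L])
}

#' Construct a validated one-to-one alignment set
#'
#' @param pairs data.frame with character columns `entity_id`, `term_id`.
#' @param few_shot_size number of pairs reserved as demonstrations (M).
#' @param kg,h optional graph and hierarchy to check id resolution against.
#' @return object of class `bkf_alignment` with fields `pairs`, `few_shot_size`.
#' @export
alignment_set <- function(pairs, few_shot_size = 0L, kg = NULL, h = NULL) {
  pairs <- data.frame(entity_id = as.character(pairs$entity_id),
                      term_id = as.character(pairs$term_id))
  if (anyDuplicated(pairs$entity_id))
    abort_bkf(sprintf("entity '%s' aligned more than once",
                      pairs$entity_id[duplicated(pairs$entity_id)][[1]]),
              "bkf_validation_error")
  if (anyDuplicated(pairs$term_id))
    abort_bkf(sprintf("term '%s' aligned more than once",
                      pairs$term_id[duplicated(pairs$term_id)][[1]]),
              "bkf_validation_error")
  if (!is.null(kg)) for (e in pairs$entity_id) check_entity(kg, e)
  if (!is.null(h)) for (t in pairs$term_id) check_term(h, t)
  structure(list(pairs = pairs, few_shot_size = as.integer(few_shot_size)),
            class = "bkf_alignment")
}

#' @export
print.bkf_kg <- function(x, ...) {
  cat(sprintf("<knowledge graph: %d entities, %d relations, %d triples>\n",
              length(x$entities), length(x$relations), nrow(x$triples)))
  invisible(x)
}

#' @export
print.bkf_hierarchy <- function(x, ...) {
  cat(sprintf("<hierarchy: %d terms, %d hypernym edges, %d root(s), max depth %d>\n",
              length(x$terms), nrow(x$edges), length(hier_roots(x)),
              if (length(x$depths)) max(x$depths) else 0L))
  invisible(x)
}

#' @export
print.bkf_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d one-to-one pairs, %d few-shot>\n",
              nrow(x$pairs), x$few_shot_size))
  invisible(x)
}
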