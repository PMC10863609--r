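#' Expansion strategies for retrieval documents
#'
#' The coarse retriever ranks hierarchy terms against a query entity by BM25
#' over textual documents. Both sides can be expanded beyond the bare name:
#' attributive expansion appends synonyms and the definition; structural
#' expansion appends the names of one-hop graph neighbours (for an entity:
#' both triple directions; for a term: parents and/or children).
#'
#' @param use_attributes append synonyms then definition.
#' @param use_structure append one-hop neighbour names.
#' @return object of class `bkf_strategy`.
#' @export
expansion_strategy <- function(use_attributes = FALSE, use_structure = FALSE) {
  structure(list(use_attributes = isTRUE(use_attributes),
                 use_structure = isTRUE(use_structure)),
            class = "bkf_strategy")
}

#' @rdname expansion_strategy
#' @param name one of `"name"`, `"atr"`, `"str"`, `"atr+str"`.
#' @export
strategy_from_name <- function(name) {
  switch(name,
         "name" = expansion_strategy(FALSE, FALSE),
         "atr" = expansion_strategy(TRUE, FALSE),
         "str" = expansion_strategy(FALSE, TRUE),
         "atr+str" = expansion_strategy(TRUE, TRUE),
         abort_bkf(sprintf("unknown strategy '%s'", name), "bkf_config_error"))
}

#' Build the retrieval document for an entity or term
#'
#' Concatenates, in fixed order: the name; if attributive expansion, all
#' synonyms then the definition; if structural expansion, the names of one-hop
#' neighbours, deduplicated, in lexicographic id order, capped at `n_max`.
#' For an entity the neighbours are the endpoints of its triples in both
#' directions; for a term they are its parents then its children (each group
#' ordered and capped jointly).
#'
#' @param item an entity or term record (a list with at least `id`, `name`).
#' @param graph_context the `bkf_kg` or `bkf_hierarchy` the item belongs to.
#' @param strategy an [expansion_strategy()].
#' @param n_max cap on structural neighbours (bounds document length).
#' @param term_structure which term neighbours structural expansion uses:
#'   `"parents+children"` (default) or `"parents"`.
#' @return a single space-joined document string.
#' @export
build_document <- function(item, graph_context, strategy = expansion_strategy(),
                           n_max = 16L,
                           term_structure = c("parents+children", "parents")) {
  term_structure <- match.arg(term_structure)
  parts <- item$name
  if (strategy$use_attributes) {
    parts <- c(parts, item$synonyms)
    if (nzchar(item$definition %||% "")) parts <- c(parts, item$definition)
  }
  if (strategy$use_structure) {
    if (inherits(graph_context, "bkf_kg")) {
      check_entity(graph_context, item$id)
      tr <- graph_context$triples
      nb <- c(tr$tail[tr$head == item$id], tr$head[tr$tail == item$id])
      nb <- lex_sort(unique(setdiff(nb, item$id)))
      nb <- utils::head(nb, n_max)
      parts <- c(parts, vapply(graph_context$entities[nb], `[[`, "", "name"))
    } else if (inherits(graph_context, "bkf_hierarchy")) {
      check_term(graph_context, item$id)
      nb <- term_parents(graph_context, item$id)
      if (term_structure == "parents+children")
        nb <- c(nb, term_children(graph_context, item$id))
      nb <- utils::head(unique(nb), n_max)
      parts <- c(parts, vapply(graph_context$terms[nb], `[[`, "", "name"))
    } else {
      abort_bkf("graph_context must be a bkf_kg or bkf_hierarchy",
                "bkf_lookup_error")
    }
  }
  paste(parts, collapse = " ")
}

#' Index hierarchy terms for Okapi BM25 retrieval
#'
#' One document per term via [build_document()]. The index stores per-document
#' term frequencies, document frequencies, document lengths, their mean and
#' the corpus size, plus the `k1`/`b` parameters. Default `k1 = 1.5`,
#' `b = 0.75` (the common Okapi operating point).
#'
#' @param h a `bkf_hierarchy` (nonempty).
#' @inheritParams build_document
#' @param k1 term-frequency saturation, nonnegative.
#' @param b document-length normalization in `[0, 1]`.
#' @return object of class `bkf_bm25` whose `doc_ids` align with term ids.
#' @export
index_terms <- function(h, strategy = expansion_strategy(), k1 = 1.5, b = 0.75,
                        n_max = 16L,
                        term_structure = c("parents+children", "parents")) {
  term_structure <- match.arg(term_structure)
  if (length(h$terms) == 0L)
    abort_bkf("cannot index an empty hierarchy", "bkf_validation_error")
  stopifnot(k1 >= 0, b >= 0, b <= 1)
  doc_ids <- lex_sort(names(h$terms))
  docs <- lapply(h$terms[doc_ids], function(t)
    tokenize(build_document(t, h, strategy, n_max, term_structure)))
  doc_len <- vapply(docs, length, 0L)
  tf <- lapply(docs, function(tk) table(tk))
  # postings: token -> (doc index, term frequency), for scoring all docs fast
  tok <- unlist(docs, use.names = FALSE)
  if (length(tok)) {
    doc_of <- rep.int(seq_along(docs), doc_len)
    key <- split(doc_of, tok)
    postings <- lapply(key, function(ix) {
      tb <- tabulate(ix, nbins = length(docs))
      nz <- which(tb > 0L)
      list(doc = nz, tf = tb[nz])
    })
    df <- vapply(postings, function(p) length(p$doc), 0L)
  } else {
    postings <- list()
    df <- integer(0)
  }
  structure(list(doc_ids = doc_ids, doc_len = doc_len,
                 avgdl = if (length(doc_len)) mean(doc_len) else 0,
                 n_docs = length(docs), tf = tf, df = df, postings = postings,
                 k1 = k1, b = b, strategy = strategy, n_max = n_max,
                 term_structure = term_structure),
            class = "bkf_bm25")
}

bm25_idf <- function(index, token) {
  df <- index$df[[token]] %||% 0L
  log(1 + (index$n_docs - df + 0.5) / (df + 0.5))
}

#' Okapi BM25 score of one document for a tokenized query
#'
#' `sum over query tokens q of idf(q) * tf(q,d) * (k1 + 1) /
#' (tf(q,d) + k1 * (1 - b + b * len(d) / avgdl))` with the nonnegative
#' `idf(q) = ln(1 + (N - df(q) + 0.5) / (df(q) + 0.5))`. Tokens absent from
#' the corpus contribute 0, so a query sharing nothing with a document scores
#' exactly 0.
#'
#' @param index a `bkf_bm25`.
#' @param query_tokens character vector (repeat a token to weight it).
#' @param doc_id a term id present in the index.
#' @return a nonnegative score.
#' @export
bm25_score <- function(index, query_tokens, doc_id) {
  i <- match(doc_id, index$doc_ids)
  if (is.na(i))
    abort_bkf(sprintf("unknown doc id '%s'", doc_id), "bkf_lookup_error")
  tf <- index$tf[[i]]
  norm <- index$k1 * (1 - index$b + index$b * index$doc_len[[i]] / index$avgdl)
  s <- 0
  for (q in query_tokens) {
    f <- if (q %in% names(tf)) as.numeric(tf[[q]]) else 0
    if (f == 0) next
    s <- s + bm25_idf(index, q) * f * (index$k1 + 1) / (f + norm)
  }
  s
}

# Scores for every document at once via postings lists.
bm25_score_all <- function(index, query_tokens) {
  s <- numeric(index$n_docs)
  norm <- index$k1 *
    (1 - index$b + index$b * index$doc_len / index$avgdl)
  for (q in unique(query_tokens)) {
    p <- index$postings[[q]]
    if (is.null(p)) next
    w <- sum(query_tokens == q)  # repeated query tokens accumulate
    contrib <- bm25_idf(index, q) * p$tf * (index$k1 + 1) /
      (p$tf + norm[p$doc])
    s[p$doc] <- s[p$doc] + w * contrib
  }
  stats::setNames(s, index$doc_ids)
}

#' Retrieve the top-K candidate terms for a query entity
#'
#' The query is the tokenized expansion document of the entity (same strategy
#' as the index). Terms are ranked by BM25 score, ties broken by lexicographic
#' term id so runs are reproducible across platforms.
#'
#' @param kg the source `bkf_kg`.
#' @param index a `bkf_bm25` built from the target hierarchy.
#' @param entity_id id of the query entity in `kg`.
#' @param k number of candidates (default 20); if it exceeds the number of
#'   terms, all terms are returned with a warning.
#' @return object of class `bkf_candidates`: fields `entity_id`, `ranked`
#'   (data.frame `term_id`, `score` with non-increasing scores), `strategy`.
#' @export
retrieve <- function(kg, index, entity_id, k = 20L) {
  check_entity(kg, entity_id)
  if (k < 1L) abort_bkf("k must be >= 1", "bkf_config_error")
  if (k > index$n_docs) {
    warning(sprintf("k = %d exceeds the %d indexed terms; returning all",
                    k, index$n_docs))
    k <- index$n_docs
  }
  query <- tokenize(build_document(kg$entities[[entity_id]], kg,
                                   index$strategy, index$n_max))
  scores <- bm25_score_all(index, query)
  ord <- lex_order(-scores, index$doc_ids)[seq_len(k)]
  structure(list(entity_id = entity_id,
                 ranked = data.frame(term_id = index$doc_ids[ord],
                                     score = unname(scores[ord])),
                 strategy = index$strategy),
            class = "bkf_candidates")
}

#' @export
print.bkf_candidates <- function(x, ...) {
  cat(sprintf("<candidates for '%s': top %d>\n", x$entity_id, nrow(x$ranked)))
  print(utils::head(x$ranked, 5L))
  invisible(x)
}

#' Recall@k of a retrieval run against gold links
#'
#' Fraction of gold entities whose gold term appears among their top-k
#' candidates.
#'
#' @param candidates list of `bkf_candidates`, named or keyed by `entity_id`.
#' @param gold a `bkf_alignment`.
#' @param k cutoff (defaults to the full candidate list).
#' @return a fraction in `[0, 1]`.
#' @export
retrieval_recall <- function(candidates, gold, k = Inf) {
  by_entity <- stats::setNames(candidates,
                               vapply(candidates, `[[`, "", "entity_id"))
  hit <- vapply(seq_len(nrow(gold$pairs)), function(i) {
    cl <- by_entity[[gold$pairs$entity_id[[i]]]]
    if (is.null(cl)) return(FALSE)
    tops <- utils::head(cl$ranked$term_id, k)
    gold$pairs$term_id[[i]] %in% tops
  }, logical(1))
  mean(hit)
}
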