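# Canonical file formats are plain JSONL + TSV:
#   entities.jsonl / terms.jsonl  one JSON record per line
#   triples.tsv                   head <TAB> relation <TAB> tail
#   edges.tsv                     child <TAB> parent
#   links.tsv                     entity_id <TAB> term_id

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con,
               sep = "\n")
  invisible(path)
}

read_tsv2 <- function(path, cols) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          header = FALSE, colClasses = "character",
                          col.names = cols, blank.lines.skip = TRUE)
  df
}

write_tsv2 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Load a knowledge graph from JSONL entities and TSV triples
#'
#' @param entity_path JSONL file, one record per entity with keys `id`, `name`
#'   and optional `synonyms`, `definition`, `semantic_types`.
#' @param triple_path TSV file with three columns head/relation/tail; may be
#'   empty or `NULL` for a triple-free graph.
#' @return a validated [knowledge_graph()].
#' @export
load_kg <- function(entity_path, triple_path = NULL) {
  entities <- read_jsonl(entity_path)
  triples <- NULL
  if (!is.null(triple_path) && file.size(triple_path) > 0)
    triples <- read_tsv2(triple_path, c("head", "relation", "tail"))
  knowledge_graph(entities, triples)
}

#' Load a hierarchy from JSONL terms and a TSV hypernym edge list
#'
#' @param term_path JSONL file, one record per term (`id`, `name`, optional
#'   `synonyms`, `definition`).
#' @param edge_path TSV file with two columns child/parent.
#' @return a validated [hierarchy()]; acyclicity is verified and a cycle, if
#'   present, is reported in the error message.
#' @export
load_hierarchy <- function(term_path, edge_path = NULL) {
  terms <- read_jsonl(term_path)
  edges <- NULL
  if (!is.null(edge_path) && file.size(edge_path) > 0)
    edges <- read_tsv2(edge_path, c("child", "parent"))
  hierarchy(terms, edges)
}

#' Load / write gold alignment links
#'
#' `links.tsv` holds one `entity_id<TAB>term_id` pair per line.
#'
#' @param path TSV file path.
#' @param few_shot_size M, the number of pairs intended as demonstrations.
#' @param kg,h optional structures to resolve ids against.
#' @return a validated [alignment_set()].
#' @export
load_links <- function(path, few_shot_size = 0L, kg = NULL, h = NULL) {
  pairs <- if (file.size(path) > 0) {
    read_tsv2(path, c("entity_id", "term_id"))
  } else {
    data.frame(entity_id = character(0), term_id = character(0))
  }
  alignment_set(pairs, few_shot_size, kg = kg, h = h)
}

#' @rdname load_links
#' @param links a `bkf_alignment`.
#' @export
write_links <- function(links, path) {
  write_tsv2(links$pairs, path)
}

#' Write a knowledge graph / hierarchy back to the canonical formats
#'
#' Round trip is lossless: loading what was written reproduces the object
#' field for field.
#'
#' @param kg a `bkf_kg`.
#' @param entity_path,triple_path output paths.
#' @export
write_kg <- function(kg, entity_path, triple_path) {
  recs <- lapply(kg$entities, function(e)
    list(id = e$id, name = e$name, synonyms = e$synonyms,
         definition = e$definition, semantic_types = e$semantic_types))
  write_jsonl(unname(recs), entity_path)
  write_tsv2(kg$triples, triple_path)
  invisible(entity_path)
}

#' @rdname write_kg
#' @param h a `bkf_hierarchy`.
#' @param term_path,edge_path output paths.
#' @export
write_hierarchy <- function(h, term_path, edge_path) {
  recs <- lapply(h$terms, function(t)
    list(id = t$id, name = t$name, synonyms = t$synonyms,
         definition = t$definition))
  write_jsonl(unname(recs), term_path)
  write_tsv2(h$edges, edge_path)
  invisible(term_path)
}

#' Import an OBO 1.4 ontology as a hierarchy
#'
#' A minimal converter for the common tag subset: `[Term]` stanzas with `id`,
#' `name`, `is_a` (hypernym pairs), `synonym` (quoted text) and `def` (quoted
#' text). Obsolete terms are skipped. This is an optional convenience import;
#' the canonical interchange formats remain JSONL + TSV.
#'
#' @param path an OBO file.
#' @return a validated [hierarchy()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list(); edges_child <- character(0); edges_parent <- character(0)
  cur <- NULL; in_term <- FALSE
  flush <- function(cur) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id))
      terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(cur); cur <- list(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, target)
    } else if (grepl("^synonym:", ln)) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    } else if (grepl("^def:", ln)) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$definition <- gsub('"', "", m)
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  flush(cur)
  kept <- vapply(terms, `[[`, "", "id")
  for (t in terms)
    for (p in t$is_a) if (p %in% kept) {
      edges_child <- c(edges_child, t$id); edges_parent <- c(edges_parent, p)
    }
  hierarchy(lapply(terms, function(t)
    new_term(t$id, t$name %||% t$id, t$synonyms %||% character(0),
             t$definition %||% "")),
    data.frame(child = edges_child, parent = edges_parent))
}
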