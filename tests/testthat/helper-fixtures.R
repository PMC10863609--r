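# Small hand-built fixtures shared across test files.

# chain: r -> a -> b -> c (child -> parent edges point upward)
chain_hierarchy <- function() {
  hierarchy(
    list(list(id = "r", name = "disease"),
         list(id = "a", name = "infectious disease",
              synonyms = "transmissible disease"),
         list(id = "b", name = "epidemic typhus",
              synonyms = "louse-borne typhus"),
         list(id = "c", name = "recurrent typhus")),
    data.frame(child = c("a", "b", "c"), parent = c("r", "a", "b")))
}

# diamond: d has parents b and c; b and c are children of r
diamond_hierarchy <- function() {
  hierarchy(
    list(list(id = "r", name = "disease"),
         list(id = "b", name = "immune system disease"),
         list(id = "c", name = "allergic disease"),
         list(id = "d", name = "allergic asthma")),
    data.frame(child = c("b", "c", "d", "d"),
               parent = c("r", "r", "b", "c")))
}

tiny_kg <- function() {
  knowledge_graph(
    list(list(id = "e1", name = "immune suppression",
              synonyms = c("immunosuppression"),
              definition = "reduced activation of the immune system"),
         list(id = "e2", name = "epidemic typhus louse borne",
              synonyms = character(0), definition = ""),
         list(id = "e3", name = "asthma attack")),
    data.frame(head = c("e1", "e2"), relation = c("associated_with", "treats"),
               tail = c("e2", "e3")))
}

fake_candidates <- function(ids, entity_id = "e1",
                            scores = rev(seq_along(ids))) {
  structure(list(entity_id = entity_id,
                 ranked = data.frame(term_id = ids, score = scores),
                 strategy = expansion_strategy()),
            class = "bkf_candidates")
}

# The default synthetic benchmark plus derived objects, computed once per
# test run (several files exercise the same study conditions).
bench_cache <- new.env(parent = emptyenv())

default_bench <- function() {
  if (is.null(bench_cache$bench))
    bench_cache$bench <- generate_benchmark(generator_config())
  bench_cache$bench
}

default_candidates <- function(strategy = "atr+str", k = 20L) {
  key <- paste0("cand_", strategy, "_", k)
  if (is.null(bench_cache[[key]])) {
    b <- default_bench()
    index <- index_terms(b$hierarchy, strategy_from_name(strategy))
    cl <- lapply(b$gold$pairs$entity_id, function(e)
      retrieve(b$kg, index, e, k))
    names(cl) <- b$gold$pairs$entity_id
    bench_cache[[key]] <- cl
  }
  bench_cache[[key]]
}
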