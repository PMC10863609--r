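test_that("tokenize casefolds and splits on non-alphanumeric runs", {
  expect_equal(tokenize("Typhus, Epidemic Louse-Borne"),
               c("typhus", "epidemic", "louse", "borne"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("immune   system–disease"),
               c("immune", "system", "disease"))
  expect_equal(tokenize("BRCA1-mutant"), c("brca1", "mutant"))
})

test_that("build_document concatenates name, attributes, structure in order", {
  kg <- tiny_kg()
  e1 <- kg$entities$e1
  expect_equal(build_document(e1, kg, expansion_strategy()), "immune suppression")
  expect_equal(build_document(e1, kg, expansion_strategy(use_attributes = TRUE)),
               "immune suppression immunosuppression reduced activation of the immune system")
  # +Str on an entity: one-hop neighbour names, both directions
  e2 <- kg$entities$e2
  expect_equal(build_document(e2, kg, expansion_strategy(use_structure = TRUE)),
               "epidemic typhus louse borne immune suppression asthma attack")
  # +Str on a mid-chain term: parent and child names, never the grandparent
  h <- chain_hierarchy()
  doc <- build_document(h$terms$b, h, expansion_strategy(use_structure = TRUE))
  expect_equal(doc, "epidemic typhus infectious disease recurrent typhus")
  expect_false(grepl("\\bdisease$", doc))  # root name absent
  # parents-only structural expansion
  expect_equal(build_document(h$terms$b, h, expansion_strategy(use_structure = TRUE),
                              term_structure = "parents"),
               "epidemic typhus infectious disease")
})

test_that("index statistics: corpus size, avgdl, determinism", {
  h <- hierarchy(list(list(id = "t1", name = "lung cancer"),
                      list(id = "t2", name = "breast cancer"),
                      list(id = "t3", name = "immune system disease gone bad")),
                 NULL)
  idx <- index_terms(h)
  expect_equal(idx$n_docs, 3L)
  expect_equal(idx$avgdl, 3)  # lengths 2, 2, 5
  expect_identical(idx[setdiff(names(idx), "strategy")],
                   index_terms(h)[setdiff(names(idx), "strategy")])
  expect_error(index_terms(hierarchy(list(), NULL)), "empty")
})

test_that("bm25 scores: zero overlap is exactly 0, symmetric docs tie", {
  h <- hierarchy(list(list(id = "t1", name = "lung cancer"),
                      list(id = "t2", name = "breast cancer"),
                      list(id = "t3", name = "immune system disease")),
                 NULL)
  idx <- index_terms(h)
  expect_identical(bm25_score(idx, c("cancer"), "t3"), 0)
  s1 <- bm25_score(idx, "cancer", "t1")
  expect_equal(s1, bm25_score(idx, "cancer", "t2"))
  expect_gt(s1, 0)
  expect_error(bm25_score(idx, "cancer", "t9"), "unknown doc")
})

test_that("bm25 matches a naive transcription on random corpora", {
  vocab <- c("gene", "tumor", "liver", "cell", "acute", "renal", "viral",
             "nodal", "cystic", "focal")
  for (seed in 1:10) {
    set.seed(seed)
    nd <- sample(2:8, 1)
    docs <- lapply(seq_len(nd), function(i)
      sample(vocab, sample(1:8, 1), replace = TRUE))
    terms <- lapply(seq_len(nd), function(i)
      list(id = sprintf("d%02d", i), name = paste(docs[[i]], collapse = " ")))
    idx <- index_terms(hierarchy(terms, NULL), k1 = 1.2, b = 0.6)
    query <- sample(vocab, sample(1:5, 1), replace = TRUE)
    for (i in seq_len(nd)) {
      expect_equal(bm25_score(idx, query, sprintf("d%02d", i)),
                   oracle_bm25(docs, query, i, k1 = 1.2, b = 0.6),
                   tolerance = 1e-12)
    }
  }
})

test_that("retrieve ranks the overlapping term first and breaks ties lexicographically", {
  h <- hierarchy(list(list(id = "t1", name = "renal fibrosis"),
                      list(id = "t2", name = "cardiac arrest"),
                      list(id = "t3", name = "biliary atresia")),
                 NULL)
  kg <- knowledge_graph(list(list(id = "e1", name = "fibrosis of kidney renal")))
  idx <- index_terms(h)
  cand <- retrieve(kg, idx, "e1", 3L)
  expect_equal(cand$ranked$term_id[[1]], "t1")
  expect_true(all(diff(cand$ranked$score) <= 0))

  # no token overlap at all: scores are all 0, order is lexicographic
  kg0 <- knowledge_graph(list(list(id = "e1", name = "xylophone")))
  cand0 <- retrieve(kg0, idx, "e1", 3L)
  expect_equal(cand0$ranked$term_id, c("t1", "t2", "t3"))
  expect_equal(cand0$ranked$score, c(0, 0, 0))

  expect_warning(big <- retrieve(kg, idx, "e1", 10L), "exceeds")
  expect_equal(nrow(big$ranked), 3L)
})

test_that("retrieve is deterministic and recall is monotone in k", {
  bench <- generate_benchmark(generator_config(n_terms = 120L, n_entities = 30L,
                                               seed = 5L))
  idx <- index_terms(bench$hierarchy, strategy_from_name("atr"))
  run <- function() lapply(bench$gold$pairs$entity_id, function(e)
    retrieve(bench$kg, idx, e, 10L))
  c1 <- run(); c2 <- run()
  expect_identical(c1, c2)
  names(c1) <- bench$gold$pairs$entity_id
  recalls <- vapply(1:10, function(k) retrieval_recall(c1, bench$gold, k), 0)
  expect_true(all(diff(recalls) >= 0))
})

test_that("duplicating every document preserves relative score order", {
  h <- hierarchy(list(list(id = "t1", name = "renal cystic fibrosis"),
                      list(id = "t2", name = "renal failure"),
                      list(id = "t3", name = "cardiac arrest")), NULL)
  dup <- hierarchy(list(list(id = "t1", name = "renal cystic fibrosis"),
                        list(id = "t2", name = "renal failure"),
                        list(id = "t3", name = "cardiac arrest"),
                        list(id = "u1", name = "renal cystic fibrosis"),
                        list(id = "u2", name = "renal failure"),
                        list(id = "u3", name = "cardiac arrest")), NULL)
  q <- c("renal", "fibrosis")
  s <- vapply(c("t1", "t2", "t3"), bm25_score, 0, index = index_terms(h),
              query_tokens = q)
  sd <- vapply(c("t1", "t2", "t3"), bm25_score, 0, index = index_terms(dup),
               query_tokens = q)
  expect_equal(order(-s), order(-sd))
})
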