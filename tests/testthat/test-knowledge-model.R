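test_that("loading a KG counts entities, relations and triples", {
  dir <- withr::local_tempdir()
  writeLines(c('{"id":"e1","name":"lung cancer"}',
               '{"id":"e2","name":"gefitinib","synonyms":["iressa"]}'),
             file.path(dir, "entities.jsonl"))
  writeLines("e2\ttreats\te1", file.path(dir, "triples.tsv"))
  kg <- load_kg(file.path(dir, "entities.jsonl"), file.path(dir, "triples.tsv"))
  expect_length(kg$entities, 2L)
  expect_equal(kg$relations, "treats")
  expect_equal(nrow(kg$triples), 1L)
  expect_equal(kg$entities$e2$synonyms, "iressa")

  file.create(file.path(dir, "empty.tsv"))
  kg0 <- load_kg(file.path(dir, "entities.jsonl"), file.path(dir, "empty.tsv"))
  expect_equal(nrow(kg0$triples), 0L)
  expect_length(kg0$relations, 0L)
})

test_that("KG validation names the offending record", {
  ents <- list(list(id = "e1", name = "x"), list(id = "e1", name = "y"))
  expect_error(knowledge_graph(ents), "duplicate entity id: e1")
  ents2 <- list(list(id = "e1", name = "x"))
  tr <- data.frame(head = "e1", relation = "treats", tail = "eX")
  expect_error(knowledge_graph(ents2, tr), "triple 1 .* 'eX'")
  expect_error(knowledge_graph(list(list(id = "e1", name = "a; b"))),
               "';'")
})

test_that("hierarchy validation: roots, cycles, duplicate edges", {
  h <- hierarchy(list(list(id = "a", name = "na"), list(id = "b", name = "nb"),
                      list(id = "c", name = "nc")),
                 data.frame(child = c("b", "c"), parent = c("a", "a")))
  expect_equal(hier_roots(h), "a")

  expect_error(
    hierarchy(list(list(id = "a", name = "na"), list(id = "b", name = "nb")),
              data.frame(child = c("a", "b"), parent = c("b", "a"))),
    "cycle.*(a -> b -> a|b -> a -> b)")
  expect_error(
    hierarchy(list(list(id = "a", name = "na"), list(id = "b", name = "nb")),
              data.frame(child = c("b", "b"), parent = c("a", "a"))),
    "duplicate edge")
  # a term with two parents is a legal DAG
  h2 <- hierarchy(list(list(id = "a", name = "na"), list(id = "b", name = "nb"),
                       list(id = "c", name = "nc")),
                  data.frame(child = c("c", "c"), parent = c("a", "b")))
  expect_setequal(hier_roots(h2), c("a", "b"))
})

test_that("depth follows the root-depth-1, shortest-path convention", {
  h <- chain_hierarchy()
  expect_equal(term_depth(h, "r"), 1L)
  expect_equal(term_depth(h, "a"), 2L)
  expect_equal(term_depth(h, "b"), 3L)
  expect_equal(term_depth(h, "c"), 4L)

  d <- diamond_hierarchy()
  expect_equal(term_depth(d, "d"), 3L)

  forest <- hierarchy(list(list(id = "x", name = "nx"),
                           list(id = "y", name = "ny")), NULL)
  expect_equal(term_depth(forest, "y"), 1L)
  expect_error(term_depth(h, "zz"), "unknown term")
})

test_that("parents and ancestors are ordered and transitive", {
  h <- chain_hierarchy()
  expect_equal(term_parents(h, "b"), "a")
  expect_equal(term_ancestors(h, "b"), c("a", "r"))
  expect_equal(term_parents(h, "r"), character(0))
  expect_equal(term_ancestors(h, "r"), character(0))
  d <- diamond_hierarchy()
  expect_equal(term_parents(d, "d"), c("b", "c"))  # lexicographic
})

test_that("ancestors and depth match brute-force fixed points on random DAGs", {
  for (seed in 1:5) {
    h <- random_dag(50, seed)
    for (t in sample(names(h$terms), 10)) {
      expect_equal(term_ancestors(h, t), oracle_ancestors(h$edges, t))
      expect_equal(term_depth(h, t), oracle_depth(h$edges, t))
    }
    # non-root depth recurrence
    for (t in names(h$terms)) {
      ps <- term_parents(h, t)
      if (length(ps))
        expect_equal(term_depth(h, t),
                     1L + min(vapply(ps, term_depth, 0L, h = h)))
    }
  }
})

test_that("KG, hierarchy and links survive a write/load round trip", {
  dir <- withr::local_tempdir()
  bench <- generate_benchmark(generator_config(n_terms = 40L, n_entities = 15L,
                                               seed = 3L))
  write_benchmark(bench, dir)
  h2 <- load_hierarchy(file.path(dir, "terms.jsonl"), file.path(dir, "edges.tsv"))
  kg2 <- load_kg(file.path(dir, "entities.jsonl"), file.path(dir, "triples.tsv"))
  g2 <- load_links(file.path(dir, "links.tsv"), kg = kg2, h = h2)
  expect_equal(h2$terms, bench$hierarchy$terms)
  expect_equal(h2$edges, bench$hierarchy$edges)
  expect_equal(kg2$entities, bench$kg$entities)
  expect_equal(kg2$triples, bench$kg$triples)
  expect_equal(g2$pairs, bench$gold$pairs)
})

test_that("alignment sets enforce the one-to-one assumption", {
  expect_error(alignment_set(data.frame(entity_id = c("e1", "e1"),
                                        term_id = c("t1", "t2"))),
               "aligned more than once")
  expect_error(alignment_set(data.frame(entity_id = c("e1", "e2"),
                                        term_id = c("t1", "t1"))),
               "aligned more than once")
})

test_that("OBO import maps is_a, synonym and def tags", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.4", "",
    "[Term]", "id: DO:1", "name: disease", "",
    "[Term]", "id: DO:2", "name: infectious disease",
    'synonym: "transmissible disease" EXACT []',
    'def: "a disease caused by a pathogen" [url:x]',
    "is_a: DO:1 ! disease", "",
    "[Term]", "id: DO:9", "name: gone", "is_obsolete: true",
    "is_a: DO:1", "",
    "[Typedef]", "id: part_of"), obo)
  h <- read_obo(obo)
  expect_setequal(names(h$terms), c("DO:1", "DO:2"))
  expect_equal(term_parents(h, "DO:2"), "DO:1")
  expect_equal(h$terms[["DO:2"]]$synonyms, "transmissible disease")
  expect_match(h$terms[["DO:2"]]$definition, "pathogen")
})
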