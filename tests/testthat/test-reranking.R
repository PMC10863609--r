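name_table <- function(ids, names) setNames(names, ids)

test_that("parse_answer maps fragments to candidates and backfills the rest", {
  cand <- fake_candidates(c("t1", "t2", "t3"))
  nm <- name_table(c("t1", "t2", "t3"),
                   c("allergic disease", "immune system disease",
                     "immune system cancer"))
  rr <- parse_answer("Answer: immune system disease; allergic disease", cand, nm)
  expect_equal(rr$ranked_terms, c("t2", "t1", "t3"))
  expect_equal(unname(rr$parse_report), c(2, 0, 1))

  # identity completion -> identity permutation
  rr2 <- parse_answer(paste0("Answer: ", paste(nm[cand$ranked$term_id],
                                               collapse = "; ")), cand, nm)
  expect_equal(rr2$ranked_terms, cand$ranked$term_id)

  # garbage falls back to retrieval order with a truthful report
  rr3 <- parse_answer("garbage text", cand, nm)
  expect_equal(rr3$ranked_terms, cand$ranked$term_id)
  expect_equal(unname(rr3$parse_report[["matched"]]), 0)
  expect_equal(unname(rr3$parse_report[["backfilled"]]), 3)

  # normalization: case, whitespace; duplicates keep first occurrence
  rr4 <- parse_answer("Answer:  Immune   System Disease ;IMMUNE system disease\nallergic disease",
                      cand, nm)
  expect_equal(rr4$ranked_terms, c("t2", "t1", "t3"))
})

test_that("parse_answer output is always a permutation (fuzz)", {
  set.seed(42)
  cand <- fake_candidates(sprintf("t%d", 1:5))
  nm <- name_table(cand$ranked$term_id,
                   c("renal fibrosis", "lung cancer", "viral fever",
                     "cystic lesion", "focal atrophy"))
  pieces <- c(unname(nm), "hallucinated term", "Answer:", ";", "\n", "typhus",
              "RENAL FIBROSIS", "", "  lung   cancer  ")
  for (i in 1:50) {
    comp <- paste(sample(pieces, sample(1:8, 1), replace = TRUE),
                  collapse = sample(c("; ", "\n", " "), 1))
    rr <- parse_answer(comp, cand, nm)
    expect_setequal(rr$ranked_terms, cand$ranked$term_id)
    expect_equal(anyDuplicated(rr$ranked_terms), 0L)
  }
})

test_that("the answer mapping is idempotent on well-formed answers", {
  # exhaustive over all permutations of up to 5 candidates here; the full
  # depth-6 sweep runs in the acceptance suite
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  for (k in 1:5) {
    ids <- sprintf("t%d", 1:k)
    nm <- name_table(ids, paste("term", letters[1:k]))
    cand <- fake_candidates(ids)
    for (p in perms(ids)) {
      rr <- parse_answer(paste0("Answer: ", paste(nm[p], collapse = "; ")),
                         cand, nm)
      expect_identical(rr$ranked_terms, p)
    }
  }
})

test_that("builtin backends behave as documented", {
  d <- diamond_hierarchy()
  kg <- tiny_kg()
  cand <- fake_candidates(c("b", "c", "d"), entity_id = "e1")
  prompt <- assemble_prompt(cand, kg, d)

  rr_noop <- rerank(prompt, cand, backend_noop(), h = d)
  expect_equal(rr_noop$ranked_terms, c("b", "c", "d"))

  gold <- alignment_set(data.frame(entity_id = "e1", term_id = "d"))
  rr_or <- rerank(prompt, cand, backend_oracle(gold, d), h = d)
  expect_equal(rr_or$ranked_terms[[1]], "d")
  expect_equal(rr_or$ranked_terms[-1], c("b", "c"))

  # oracle without a gold entry falls back to the given order, with a message
  gold2 <- alignment_set(data.frame(entity_id = "eX", term_id = "d"))
  expect_message(rr_fb <- rerank(prompt, cand, backend_oracle(gold2, d), h = d),
                 "absent from gold")
  expect_equal(rr_fb$ranked_terms, c("b", "c", "d"))

  # deterministic backends reproduce results exactly
  expect_identical(rr_or, rerank(prompt, cand, backend_oracle(gold, d), h = d))
})

test_that("token_overlap ranks by Jaccard similarity with stable ties", {
  h <- hierarchy(list(list(id = "t1", name = "typhus"),
                      list(id = "t2", name = "epidemic typhus"),
                      list(id = "t3", name = "scrub typhus")), NULL)
  kg <- knowledge_graph(list(list(id = "e1", name = "epidemic typhus")))
  cand <- fake_candidates(c("t1", "t2", "t3"), entity_id = "e1")
  prompt <- assemble_prompt(cand, kg, h, with_context = FALSE)
  rr <- rerank(prompt, cand, backend_token_overlap(), h = h)
  expect_equal(rr$ranked_terms[[1]], "t2")           # Jaccard 1.0
  expect_equal(rr$ranked_terms[-1], c("t1", "t3"))   # 1/2 each; given order
})

test_that("http backend honors temperature 0, retries, and structured failure", {
  calls <- list()
  ok_transport <- function(body) {
    calls[[length(calls) + 1L]] <<- body
    list(status = 200L,
         text = jsonlite::toJSON(
           list(choices = list(list(text = "Answer: b; a"))),
           auto_unbox = TRUE))
  }
  be <- http_backend("http://localhost:9/v1/complete", transport = ok_transport)
  expect_false(be$deterministic)
  out <- be$complete("PROMPT")
  expect_equal(out, "Answer: b; a")
  expect_equal(calls[[1]]$temperature, 0)
  expect_equal(calls[[1]]$prompt, "PROMPT")

  be2 <- http_backend("http://x", temperature = 0.7, transport = ok_transport)
  be2$complete("p")
  expect_equal(calls[[2]]$temperature, 0.7)

  n_fail <- 0L
  failing <- function(body) { n_fail <<- n_fail + 1L; list(status = 500L, text = "boom") }
  be3 <- http_backend("http://x", retries = 3L, backoff = 0, transport = failing)
  expect_error(be3$complete("p"), "failed after 3 attempts")
  expect_equal(n_fail, 3L)
})

test_that("rerank surfaces backend failures with the entity id", {
  d <- diamond_hierarchy()
  cand <- fake_candidates(c("b", "c"), entity_id = "e1")
  prompt <- assemble_prompt(cand, tiny_kg(), d)
  boom <- completion_backend("boom", function(p) stop("socket lost"))
  expect_error(rerank(prompt, cand, boom, h = d), "entity 'e1'.*socket lost")
})
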