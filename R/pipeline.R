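#' Configure an end-to-end fusion run
#'
#' A run executes: load (or synthesize) the data, retrieve top-K candidates
#' per test entity, assemble prompts, re-rank through a backend, and
#' evaluate against the gold links. Every stage writes a plain JSONL/JSON
#' artifact stamped with the configuration hash, so any stage can be re-run
#' or inspected in isolation and identical configurations with a
#' deterministic backend reproduce identical outputs.
#'
#' @param data_dir directory with the canonical benchmark files
#'   (`terms.jsonl`, `edges.tsv`, `entities.jsonl`, `triples.tsv`,
#'   `links.tsv`), or `NULL` to generate a synthetic benchmark.
#' @param generator a [generator_config()] used when `data_dir` is `NULL`.
#' @param strategy expansion strategy name: "name", "atr", "str", "atr+str".
#' @param k candidate list size.
#' @param shots number of real demonstrations M (0 = zero-shot with a pseudo
#'   demonstration; demonstrations are drawn from the gold links and the
#'   remainder becomes the test set).
#' @param with_context include hierarchy context lines in prompts.
#' @param backend a [completion_backend()] or a builtin name ("noop",
#'   "oracle", "token-overlap").
#' @param hits_ks,ndcg_ks evaluation cutoffs.
#' @param out_dir artifact directory, or `NULL` to keep everything in memory.
#' @param seed seed for the few-shot split (and the generator, unless the
#'   generator config carries its own).
#' @return object of class `bkf_run_config`.
#' @export
run_config <- function(data_dir = NULL, generator = generator_config(),
                       strategy = "atr+str", k = 20L, shots = 0L,
                       with_context = TRUE, backend = "noop",
                       hits_ks = c(1, 3, 5, 10, 20), ndcg_ks = c(1, 3),
                       out_dir = NULL, seed = 17L) {
  structure(list(data_dir = data_dir, generator = generator,
                 strategy = strategy, k = as.integer(k),
                 shots = as.integer(shots), with_context = isTRUE(with_context),
                 backend = backend, hits_ks = hits_ks, ndcg_ks = ndcg_ks,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "bkf_run_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

demo_from_pair <- function(entity_id, term_id, kg, h, index, k) {
  cand <- retrieve(kg, index, entity_id, k)
  gname <- h$terms[[term_id]]$name
  choice_names <- vapply(cand$ranked$term_id, function(t) h$terms[[t]]$name,
                         "", USE.NAMES = FALSE)
  if (!(gname %in% choice_names))  # ensure the worked example is answerable
    choice_names <- c(gname, utils::head(choice_names, length(choice_names) - 1L))
  i <- match(gname, choice_names)
  demonstration(kg$entities[[entity_id]]$name, choice_names,
                c(gname, choice_names[-i]))
}

#' Execute a configured fusion run
#'
#' @param cfg a [run_config()].
#' @return `list(report = bkf_eval_report, candidates, prompts, rerank,
#'   preds, gold_test, benchmark, config_hash)`.
#' @export
run_pipeline <- function(cfg) {
  # out_dir is where artifacts land, not part of the run's identity
  hash <- config_hash(list(unclass(cfg)[setdiff(names(cfg),
                                                c("backend", "out_dir"))],
                           backend = if (is.character(cfg$backend))
                             cfg$backend else cfg$backend$name))
  t0 <- proc.time()[["elapsed"]]

  if (is.null(cfg$data_dir)) {
    bench <- generate_benchmark(cfg$generator)
    stage_msg("data", "synthesized benchmark %s", format(bench$manifest$stats$n_terms))
  } else {
    h <- load_hierarchy(file.path(cfg$data_dir, "terms.jsonl"),
                        file.path(cfg$data_dir, "edges.tsv"))
    kg <- load_kg(file.path(cfg$data_dir, "entities.jsonl"),
                  file.path(cfg$data_dir, "triples.tsv"))
    gold <- load_links(file.path(cfg$data_dir, "links.tsv"), kg = kg, h = h)
    bench <- structure(list(hierarchy = h, kg = kg, gold = gold,
                            manifest = list(loaded_from = cfg$data_dir)),
                       class = "bkf_benchmark")
  }
  h <- bench$hierarchy; kg <- bench$kg
  split <- split_few_shot(bench$gold, cfg$shots, seed = cfg$seed)
  gold_test <- split$test
  stage_msg("data", "%d terms, %d entities, %d test queries, M=%d",
            length(h$terms), length(kg$entities), nrow(gold_test$pairs),
            cfg$shots)

  strategy <- strategy_from_name(cfg$strategy)
  index <- index_terms(h, strategy)
  candidates <- lapply(gold_test$pairs$entity_id, function(e)
    retrieve(kg, index, e, cfg$k))
  names(candidates) <- gold_test$pairs$entity_id
  stage_msg("retrieve", "top-%d candidates for %d queries (recall@%d = %.3f)",
            cfg$k, length(candidates), cfg$k,
            retrieval_recall(candidates, gold_test, cfg$k))

  demos <- if (cfg$shots == 0L) {
    list(make_pseudo_demonstration())
  } else {
    lapply(seq_len(nrow(split$demos$pairs)), function(i)
      demo_from_pair(split$demos$pairs$entity_id[[i]],
                     split$demos$pairs$term_id[[i]], kg, h, index, cfg$k))
  }
  prompts <- lapply(candidates, assemble_prompt, kg = kg, h = h, demos = demos,
                    with_context = cfg$with_context)
  stage_msg("prompt", "%d prompts (%s, %s demonstration)", length(prompts),
            if (cfg$with_context) "with context" else "no context",
            if (cfg$shots == 0L) "pseudo" else sprintf("%d real", cfg$shots))

  backend <- if (is.character(cfg$backend)) {
    switch(cfg$backend,
           "noop" = backend_noop(),
           "oracle" = backend_oracle(bench$gold, h),
           "token-overlap" = backend_token_overlap(),
           abort_bkf(sprintf("unknown builtin backend '%s'", cfg$backend),
                     "bkf_config_error"))
  } else cfg$backend
  rr <- lapply(names(prompts), function(e)
    rerank(prompts[[e]], candidates[[e]], backend, h = h))
  names(rr) <- names(prompts)
  preds <- lapply(rr, `[[`, "ranked_terms")
  stage_msg("rerank", "backend '%s' re-ranked %d lists", backend$name,
            length(rr))

  report <- evaluate_run(preds, gold_test, h, cfg$hits_ks, cfg$ndcg_ks)
  stage_msg("eval", "Hits@1 = %.3f, MRR = %.3f, WuP = %.3f (%.1fs elapsed)",
            report$hits[["hits@1"]], report$mrr, report$wup,
            proc.time()[["elapsed"]] - t0)

  if (!is.null(cfg$out_dir))
    write_run_artifacts(cfg$out_dir, hash, candidates, prompts, rr, report)
  list(report = report, candidates = candidates, prompts = prompts,
       rerank = rr, preds = preds, gold_test = gold_test, benchmark = bench,
       config_hash = hash)
}

write_run_artifacts <- function(dir, hash, candidates, prompts, rr, report) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_jsonl(lapply(unname(candidates), function(cl)
    list(config_hash = hash, entity_id = cl$entity_id,
         ranked = lapply(seq_len(nrow(cl$ranked)), function(i)
           list(cl$ranked$term_id[[i]], cl$ranked$score[[i]])))),
    file.path(dir, "candidates.jsonl"))
  write_jsonl(lapply(unname(prompts), function(p)
    list(config_hash = hash, entity_id = p$entity_id, rendered = p$rendered,
         choices = p$test_choices)),
    file.path(dir, "prompts.jsonl"))
  write_jsonl(lapply(unname(rr), function(r)
    list(config_hash = hash, entity_id = r$entity_id,
         ranked_terms = r$ranked_terms, raw_completion = r$raw_completion,
         parse_report = as.list(r$parse_report))),
    file.path(dir, "predictions.jsonl"))
  jsonlite::write_json(list(config_hash = hash, hits = as.list(report$hits),
                            mrr = report$mrr, ndcg = as.list(report$ndcg),
                            wup = report$wup, n_queries = report$n_queries),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
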