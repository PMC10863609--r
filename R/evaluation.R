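#' Strict ranking metrics: Hits@k and MRR
#'
#' `hits_at_k` is the fraction of gold entities whose gold term appears in the
#' top k of their prediction list; `mrr` is the mean reciprocal rank of the
#' gold term (0 for a query whose gold term is never predicted). Entities in
#' `gold` with no prediction list count as misses.
#'
#' @param preds named list: entity id -> ordered character vector of predicted
#'   term ids (no duplicates).
#' @param gold a `bkf_alignment`.
#' @param k cutoff, `k >= 1`.
#' @return a fraction in `[0, 1]`.
#' @export
hits_at_k <- function(preds, gold, k) {
  if (k < 1) abort_bkf("k must be >= 1", "bkf_config_error")
  mean(gold_ranks(preds, gold) <= k)
}

#' @rdname hits_at_k
#' @export
mrr <- function(preds, gold) {
  mean(1 / gold_ranks(preds, gold))
}

# Rank of the gold term per gold entity; Inf when absent or no prediction.
gold_ranks <- function(preds, gold) {
  vapply(seq_len(nrow(gold$pairs)), function(i) {
    p <- preds[[gold$pairs$entity_id[[i]]]]
    r <- match(gold$pairs$term_id[[i]], p)
    if (is.na(r)) Inf else as.numeric(r)
  }, 0)
}

#' Wu-Palmer similarity between two hierarchy terms
#'
#' `2 * depth(lcs) / (depth(a) + depth(b))`, where the lcs is the common
#' ancestor of `a` and `b` (each term counting as its own ancestor) with
#' maximal depth, depths following the root-depth-1 convention. Terms in
#' disjoint components share no ancestor and score 0.
#'
#' On a multi-parent DAG with shortest-path depths, an ancestor can be
#' nominally deeper than a descendant that owns a shortcut to the root; the
#' lcs depth is therefore capped at `min(depth(a), depth(b))`, which keeps
#' the similarity in `[0, 1]` and `wup(t, t) == 1`, and changes nothing on
#' trees. A depth tie among maximal common ancestors never changes the
#' numeric value.
#'
#' @param h a `bkf_hierarchy`.
#' @param a,b term ids.
#' @return a similarity in `[0, 1]`; `wup(t, t) == 1`.
#' @export
wup <- function(h, a, b) {
  check_term(h, a); check_term(h, b)
  common <- intersect(c(a, h$ancestors_of[[a]]), c(b, h$ancestors_of[[b]]))
  if (length(common) == 0L) return(0)
  da <- h$depths[[a]]; db <- h$depths[[b]]
  2 * min(max(h$depths[common]), da, db) / (da + db)
}

# Wu-Palmer of one gold term against every term in the hierarchy, vectorized
# over precomputed ancestor closures (used by nDCG's ideal ranking).
wup_all <- function(h, gold_id) {
  check_term(h, gold_id)
  ga <- c(gold_id, h$ancestors_of[[gold_id]])
  dg <- h$depths[[gold_id]]
  vapply(names(h$terms), function(t) {
    common <- intersect(c(t, h$ancestors_of[[t]]), ga)
    if (length(common) == 0L) return(0)
    dt <- h$depths[[t]]
    2 * min(max(h$depths[common]), dg, dt) / (dg + dt)
  }, 0)
}

#' Lenient metrics: exponential-decay nDCG and top-1 Wu-Palmer
#'
#' `ndcg_at_k` grades each predicted term by its Wu-Palmer similarity to the
#' query's gold term, so near-misses in the hierarchy earn partial credit:
#' `DCG@k = sum_i (2^rel_i - 1) / log2(i + 1)`. The ideal DCG is computed over
#' the k highest-relevance terms of the whole hierarchy — not just the
#' retrieved candidates — so a weak retriever cannot inflate the score.
#' `top1_wup` is the mean Wu-Palmer similarity of each query's first
#' prediction to its gold term (0 for empty prediction lists).
#'
#' @inheritParams hits_at_k
#' @param h the `bkf_hierarchy` the gold terms live in.
#' @return a fraction in `[0, 1]`, averaged over gold entities.
#' @export
ndcg_at_k <- function(preds, gold, h, k) {
  if (k < 1) abort_bkf("k must be >= 1", "bkf_config_error")
  disc <- 1 / log2(seq_len(k) + 1)
  per_query <- vapply(seq_len(nrow(gold$pairs)), function(i) {
    gt <- gold$pairs$term_id[[i]]
    rel_all <- wup_all(h, gt)
    ideal <- sort(rel_all, decreasing = TRUE)[seq_len(min(k, length(rel_all)))]
    idcg <- sum((2^ideal - 1) * disc[seq_along(ideal)])
    if (idcg == 0) return(0)
    p <- utils::head(preds[[gold$pairs$entity_id[[i]]]], k)
    if (length(p) == 0L) return(0)
    rel <- rel_all[p]
    sum((2^rel - 1) * disc[seq_along(rel)]) / idcg
  }, 0)
  mean(per_query)
}

#' @rdname ndcg_at_k
#' @export
top1_wup <- function(preds, gold, h) {
  per_query <- vapply(seq_len(nrow(gold$pairs)), function(i) {
    p <- preds[[gold$pairs$entity_id[[i]]]]
    if (is.null(p) || length(p) == 0L) return(0)
    wup(h, p[[1]], gold$pairs$term_id[[i]])
  }, 0)
  mean(per_query)
}

#' Evaluate a prediction set against gold links
#'
#' Assembles the strict and lenient metrics into one report. Entities in
#' `preds` without a gold link are dropped with a warning (they cannot be
#' scored); gold entities without predictions count as misses.
#'
#' @inheritParams ndcg_at_k
#' @param hits_ks cutoffs for Hits@k.
#' @param ndcg_ks cutoffs for nDCG@k.
#' @return object of class `bkf_eval_report`: named `hits` and `ndcg`
#'   vectors, `mrr`, `wup`, `n_queries`.
#' @export
evaluate_run <- function(preds, gold, h, hits_ks = c(1, 3, 5, 10, 20),
                         ndcg_ks = c(1, 3)) {
  extra <- setdiff(names(preds), gold$pairs$entity_id)
  if (length(extra)) {
    warning(sprintf("%d predicted entities have no gold link and are ignored",
                    length(extra)))
    preds <- preds[setdiff(names(preds), extra)]
  }
  structure(list(
    hits = stats::setNames(vapply(hits_ks, hits_at_k, 0, preds = preds,
                                  gold = gold),
                           paste0("hits@", hits_ks)),
    mrr = mrr(preds, gold),
    ndcg = stats::setNames(vapply(ndcg_ks, ndcg_at_k, 0, preds = preds,
                                  gold = gold, h = h),
                           paste0("ndcg@", ndcg_ks)),
    wup = top1_wup(preds, gold, h),
    n_queries = nrow(gold$pairs)),
    class = "bkf_eval_report")
}

#' @export
print.bkf_eval_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.bkf_eval_report <- function(x, ...) {
  vals <- c(x$hits, x$ndcg, WuP = x$wup, MRR = x$mrr)
  c(paste(formatC(names(vals), width = 8), collapse = " "),
    paste(formatC(sprintf("%.4f", vals), width = 8), collapse = " "),
    sprintf("(n = %d queries)", x$n_queries))
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `bkf_eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(hits = as.list(report$hits), mrr = report$mrr,
                            ndcg = as.list(report$ndcg), wup = report$wup,
                            n_queries = report$n_queries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
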