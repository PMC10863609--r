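# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (edge lists, naive loops) and never touch
# the package's index/closure internals.

# Literal Okapi BM25 transcription over a list of token vectors.
oracle_bm25 <- function(docs, query, doc_i, k1, b) {
  n <- length(docs)
  avgdl <- mean(vapply(docs, length, 0L))
  s <- 0
  for (q in query) {
    df <- sum(vapply(docs, function(d) q %in% d, logical(1)))
    idf <- log(1 + (n - df + 0.5) / (df + 0.5))
    f <- sum(docs[[doc_i]] == q)
    if (f > 0)
      s <- s + idf * f * (k1 + 1) /
        (f + k1 * (1 - b + b * length(docs[[doc_i]]) / avgdl))
  }
  s
}

# Ancestor set as the fixed point of repeated parent lookups on the raw edges.
oracle_ancestors <- function(edges, t) {
  anc <- character(0)
  frontier <- t
  repeat {
    ps <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(ps, anc)
    if (length(new) == 0L) return(sort(anc))
    anc <- c(anc, new)
    frontier <- new
  }
}

# Depth by naive recursion on the raw edges (root depth 1, min over parents).
oracle_depth <- function(edges, t) {
  ps <- edges$parent[edges$child == t]
  if (length(ps) == 0L) return(1L)
  1L + min(vapply(ps, oracle_depth, 0L, edges = edges))
}

# Wu-Palmer by exhaustive common-ancestor enumeration, same depth-cap
# convention as the package (lcs depth capped at the endpoint depths).
oracle_wup <- function(edges, a, b) {
  ca <- intersect(c(a, oracle_ancestors(edges, a)),
                  c(b, oracle_ancestors(edges, b)))
  if (length(ca) == 0L) return(0)
  da <- oracle_depth(edges, a); db <- oracle_depth(edges, b)
  best <- max(vapply(ca, oracle_depth, 0L, edges = edges))
  2 * min(best, da, db) / (da + db)
}

# Direct-summation DCG oracle.
oracle_dcg <- function(rels) {
  if (length(rels) == 0L) return(0)
  sum((2^rels - 1) / log2(seq_along(rels) + 1))
}

oracle_ndcg_query <- function(pred_ids, gold_id, h, k) {
  all_ids <- names(h$terms)
  rel_all <- vapply(all_ids, function(t) oracle_wup(h$edges, t, gold_id), 0)
  idcg <- oracle_dcg(sort(rel_all, decreasing = TRUE)[seq_len(min(k, length(rel_all)))])
  if (idcg == 0) return(0)
  p <- head(pred_ids, k)
  oracle_dcg(rel_all[p]) / idcg
}

# Random DAG on n nodes: node i may take 1-2 parents among earlier nodes.
# detached_prob leaves some nodes parentless (multi-root / disjoint parts).
random_dag <- function(n, seed, detached_prob = 0.1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in seq(2L, length.out = max(0L, n - 1L))) {
    if (runif(1) < detached_prob) next
    np <- min(i - 1L, sample(1:2, 1L))
    for (p in sample(seq_len(i - 1L), np)) {
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
    }
  }
  terms <- lapply(ids, function(id) list(id = id, name = paste("node", id)))
  hierarchy(terms, data.frame(child = child, parent = parent))
}
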