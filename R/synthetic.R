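# Built-in biomedical-flavoured vocabulary for synthetic names. Tokens are
# deliberately disjoint from the pseudo-demonstration's (musical) vocabulary
# so out-of-domain checks are meaningful.
bkf_vocab <- function() {
  c("disease", "syndrome", "disorder", "infection", "carcinoma", "cancer",
    "tumor", "lesion", "fever", "typhus", "hepatitis", "nephritis",
    "dermatitis", "arthritis", "anemia", "leukemia", "lymphoma", "melanoma",
    "fibrosis", "sclerosis", "stenosis", "atrophy", "dystrophy", "neuropathy",
    "myopathy", "cardiopathy", "pulmonary", "hepatic", "renal", "cardiac",
    "gastric", "neural", "immune", "allergic", "chronic", "acute", "epidemic",
    "congenital", "idiopathic", "autoimmune", "viral", "bacterial", "fungal",
    "parasitic", "cutaneous", "vascular", "lymphatic", "metabolic",
    "endocrine", "respiratory", "intestinal", "cerebral", "spinal", "ocular",
    "auditory", "dental", "skeletal", "muscular", "glandular", "thyroid",
    "adrenal", "pancreatic", "biliary", "urinary", "ovarian", "prostate",
    "mammary", "pleural", "synovial", "septic", "malignant", "benign",
    "primary", "secondary", "recessive", "dominant", "familial", "juvenile",
    "senile", "recurrent", "systemic", "focal", "diffuse", "obstructive",
    "degenerative", "inflammatory", "ischemic", "hemorrhagic", "embolic",
    "thrombotic", "ulcerative", "necrotic", "cystic", "nodular", "papillary",
    "follicular", "medullary", "cortical", "basal", "squamous", "ductal",
    "lobular", "mucosal", "serous", "membranous", "interstitial", "alveolar",
    "bronchial", "tracheal", "esophageal", "duodenal", "colonic", "rectal",
    "splenic", "lumbar", "cranial", "femoral", "dermal", "plantar", "palmar",
    "orbital", "nasal", "lingual", "pharyngeal")
}

#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the structure of real fusion benchmarks: a rooted
#' multi-level DAG hierarchy with rich attributes, a KG of entities whose
#' names diverge from their gold terms by naming-convention noise, and a
#' one-to-one gold linkage.
#'
#' Default shape: 1000 terms with maximum depth 13 (the depth of the disease
#' hierarchy that motivates the task), 200 entities, occasional multiple
#' parenthood, two synonyms per term, about two relational triples per entity,
#' and moderate noise on every corruption channel.
#'
#' @param n_terms number of hierarchy terms.
#' @param max_depth maximum term depth (root depth 1).
#' @param branching nominal mean children per term (recorded in the manifest;
#'   growth is by uniform attachment, so realized branching follows from
#'   `n_terms`).
#' @param multi_parent_prob probability a new term gains a second parent.
#' @param n_entities number of KG entities (`<= n_terms`, one-to-one gold).
#' @param noise named probabilities for the corruption pipeline, applied
#'   independently in fixed order: `synonym_swap` (start from a synonym
#'   instead of the name), `token_shuffle`, `token_drop`, `abbreviation`
#'   (first letters of a multi-token name, e.g. "epidemic typhus" -> "ET").
#' @param n_synonyms synonyms generated per term.
#' @param triple_density mean relational triples per entity.
#' @param seed mandatory RNG seed; full determinism under a fixed seed.
#' @return object of class `bkf_gen_config`.
#' @export
generator_config <- function(n_terms = 1000L, max_depth = 13L, branching = 3,
                             multi_parent_prob = 0.05, n_entities = 200L,
                             noise = c(synonym_swap = 0.3, token_shuffle = 0.2,
                                       token_drop = 0.15, abbreviation = 0.1),
                             n_synonyms = 2L, triple_density = 2,
                             seed = 17L) {
  noise_full <- c(synonym_swap = 0, token_shuffle = 0, token_drop = 0,
                  abbreviation = 0)
  noise_full[names(noise)] <- noise
  if (any(noise_full < 0 | noise_full > 1))
    abort_bkf("noise probabilities must lie in [0, 1]", "bkf_config_error")
  if (n_entities > n_terms)
    abort_bkf("n_entities must not exceed n_terms (one-to-one gold links)",
              "bkf_config_error")
  if (n_terms < 1L) abort_bkf("n_terms must be >= 1", "bkf_config_error")
  if (is.null(seed) || is.na(seed))
    abort_bkf("a seed is mandatory", "bkf_config_error")
  structure(list(n_terms = as.integer(n_terms),
                 max_depth = as.integer(max_depth), branching = branching,
                 multi_parent_prob = multi_parent_prob,
                 n_entities = as.integer(n_entities), noise = noise_full,
                 n_synonyms = as.integer(n_synonyms),
                 triple_density = triple_density, seed = as.integer(seed)),
            class = "bkf_gen_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

sample_tokens <- function(n, exclude = character(0)) {
  pool <- setdiff(bkf_vocab(), exclude)
  sample(pool, n)
}

# Token-level paraphrase: replace one token with a fresh vocabulary token,
# or prepend a qualifier for single-token names.
make_synonym <- function(name_tokens) {
  if (length(name_tokens) > 1L && stats::runif(1) < 0.5) {
    i <- sample.int(length(name_tokens), 1L)
    name_tokens[i] <- sample_tokens(1L, exclude = name_tokens)
  } else {
    name_tokens <- c(sample_tokens(1L, exclude = name_tokens), name_tokens)
  }
  paste(name_tokens, collapse = " ")
}

#' Generate a synthetic hierarchy
#'
#' Seeded growth from a single root: each new term attaches to a uniformly
#' chosen existing term of depth below `max_depth`, and with
#' `multi_parent_prob` gains a second parent at depth no greater than its
#' first (preserving acyclicity by construction — edges always point from the
#' new term to existing terms). Names are 1-3 vocabulary tokens; a child
#' inherits one token of its first parent with probability 0.5, emulating
#' compositional ontology names. Synonyms are token-level paraphrases and the
#' definition concatenates the parent name with the term's distinguishing
#' tokens.
#'
#' @param cfg a [generator_config()].
#' @return a validated `bkf_hierarchy`.
#' @export
generate_hierarchy <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_terms
    ids <- sprintf("T%04d", seq_len(n))
    depths <- integer(n)
    name_tok <- vector("list", n)
    parent1 <- rep(NA_integer_, n)
    edges_child <- character(0); edges_parent <- character(0)
    terms <- vector("list", n)
    for (i in seq_len(n)) {
      if (i == 1L) {
        depths[i] <- 1L
        name_tok[[i]] <- "disease"
        def <- "root of the synthetic disease hierarchy"
      } else {
        eligible <- which(depths[seq_len(i - 1L)] < cfg$max_depth)
        p <- eligible[sample.int(length(eligible), 1L)]
        parent1[i] <- p
        depths[i] <- depths[p] + 1L
        inherit <- if (stats::runif(1) < 0.5)
          name_tok[[p]][sample.int(length(name_tok[[p]]), 1L)] else character(0)
        fresh <- sample_tokens(sample.int(2L, 1L), exclude = inherit)
        name_tok[[i]] <- c(fresh, inherit)
        edges_child <- c(edges_child, ids[i]); edges_parent <- c(edges_parent, ids[p])
        if (stats::runif(1) < cfg$multi_parent_prob) {
          second <- which(depths[seq_len(i - 1L)] <= depths[p] &
                            seq_len(i - 1L) != p)
          if (length(second)) {
            q <- second[sample.int(length(second), 1L)]
            edges_child <- c(edges_child, ids[i])
            edges_parent <- c(edges_parent, ids[q])
            depths[i] <- min(depths[i], depths[q] + 1L)
          }
        }
        def <- paste(c("a", paste(name_tok[[p]], collapse = " "),
                       "characterized as", fresh), collapse = " ")
      }
      nm <- paste(name_tok[[i]], collapse = " ")
      syns <- if (cfg$n_synonyms > 0L)
        unique(vapply(seq_len(cfg$n_synonyms), function(j)
          make_synonym(name_tok[[i]]), "")) else character(0)
      terms[[i]] <- new_term(ids[i], nm, syns, def)
    }
    # Duplicate names are legal in real ontologies but would make exact-name
    # answer parsing ambiguous (and names sharing a token multiset tie under
    # BM25); disambiguate on the sorted-token key with an extra fresh token.
    nms <- vapply(terms, `[[`, "", "name")
    tok_key <- function(x) paste(sort(strsplit(x, " ", fixed = TRUE)[[1]]),
                                 collapse = " ")
    keys <- vapply(nms, tok_key, "")
    while (anyDuplicated(keys)) {
      i <- which(duplicated(keys))[[1]]
      extra <- sample_tokens(1L, exclude = strsplit(nms[i], " ")[[1]])
      terms[[i]]$name <- paste(extra, terms[[i]]$name)
      nms[i] <- terms[[i]]$name
      keys[i] <- tok_key(nms[i])
    }
    hierarchy(terms, data.frame(child = edges_child, parent = edges_parent))
  })
}

corrupt_name <- function(name, synonyms, noise) {
  toks <- strsplit(name, " ", fixed = TRUE)[[1]]
  if (length(synonyms) && stats::runif(1) < noise[["synonym_swap"]])
    toks <- strsplit(sample(synonyms, 1L), " ", fixed = TRUE)[[1]]
  if (length(toks) > 1L && stats::runif(1) < noise[["token_shuffle"]])
    toks <- sample(toks)
  if (length(toks) > 1L && stats::runif(1) < noise[["token_drop"]])
    toks <- toks[-sample.int(length(toks), 1L)]
  if (length(toks) > 1L && stats::runif(1) < noise[["abbreviation"]])
    toks <- toupper(paste(substr(toks, 1L, 1L), collapse = ""))
  paste(toks, collapse = " ")
}

#' Generate a synthetic KG aligned one-to-one to a hierarchy
#'
#' Samples `n_entities` distinct gold terms uniformly; each entity's name is
#' the gold term's name (or a synonym) passed through the corruption pipeline
#' in fixed order synonym_swap -> token_shuffle -> token_drop -> abbreviation.
#' Entity attributes: with probability 0.5 the uncorrupted term name is among
#' the synonyms; the definition is the term definition with light token noise.
#' Triples labelled `associated_with` connect entities whose gold terms share
#' an ancestor within two hops, until `triple_density` is met.
#'
#' @param h a hierarchy from [generate_hierarchy()].
#' @param cfg the same [generator_config()].
#' @return `list(kg = bkf_kg, gold = bkf_alignment)`.
#' @export
generate_kg <- function(h, cfg) {
  if (cfg$n_entities > length(h$terms))
    abort_bkf("n_entities exceeds the number of terms", "bkf_config_error")
  with_seed(cfg$seed + 1L, {
    term_ids <- lex_sort(names(h$terms))
    gold_terms <- sort(sample(term_ids, cfg$n_entities))
    eids <- sprintf("E%04d", seq_len(cfg$n_entities))
    entities <- vector("list", cfg$n_entities)
    for (i in seq_len(cfg$n_entities)) {
      t <- h$terms[[gold_terms[i]]]
      nm <- corrupt_name(t$name, t$synonyms, cfg$noise)
      if (!nzchar(nm)) nm <- t$name
      syns <- character(0)
      if (stats::runif(1) < 0.5) syns <- t$name
      if (length(t$synonyms)) syns <- c(syns, sample(t$synonyms, 1L))
      def_tok <- strsplit(t$definition, " ", fixed = TRUE)[[1]]
      if (length(def_tok) > 2L) def_tok <- def_tok[-sample.int(length(def_tok), 1L)]
      entities[[i]] <- new_entity(eids[i], nm, unique(syns),
                                  paste(def_tok, collapse = " "),
                                  semantic_types = "synthetic concept")
    }
    # triples among entities whose gold terms are close in the hierarchy
    near_anc <- lapply(gold_terms, function(t)
      c(t, term_parents(h, t),
        unlist(lapply(term_parents(h, t), term_parents, h = h),
               use.names = FALSE)))
    n_triples_target <- round(cfg$triple_density * cfg$n_entities)
    th <- character(0); tt <- character(0)
    if (cfg$n_entities > 1L) {
      pairs_seen <- character(0)
      attempts <- 0L
      while (length(th) < n_triples_target &&
             attempts < 50L * n_triples_target) {
        attempts <- attempts + 1L
        i <- sample.int(cfg$n_entities, 1L)
        j <- sample.int(cfg$n_entities, 1L)
        if (i == j) next
        if (!length(intersect(near_anc[[i]], near_anc[[j]]))) next
        key <- paste(i, j)
        if (key %in% pairs_seen) next
        pairs_seen <- c(pairs_seen, key)
        th <- c(th, eids[i]); tt <- c(tt, eids[j])
      }
    }
    kg <- knowledge_graph(entities,
                          data.frame(head = th,
                                     relation = rep("associated_with",
                                                    length(th)),
                                     tail = tt))
    gold <- alignment_set(data.frame(entity_id = eids, term_id = gold_terms),
                          kg = kg, h = h)
    list(kg = kg, gold = gold)
  })
}

#' Generate a complete synthetic benchmark
#'
#' @param cfg a [generator_config()].
#' @return object of class `bkf_benchmark`: `hierarchy`, `kg`, `gold`, and a
#'   `manifest` echoing the configuration plus dataset statistics.
#' @export
generate_benchmark <- function(cfg = generator_config()) {
  h <- generate_hierarchy(cfg)
  kgg <- generate_kg(h, cfg)
  manifest <- list(config = unclass(cfg),
                   config_hash = config_hash(unclass(cfg)),
                   stats = list(n_terms = length(h$terms),
                                n_edges = nrow(h$edges),
                                max_depth = max(h$depths),
                                n_entities = length(kgg$kg$entities),
                                n_relations = length(kgg$kg$relations),
                                n_triples = nrow(kgg$kg$triples),
                                n_links = nrow(kgg$gold$pairs)))
  structure(list(hierarchy = h, kg = kgg$kg, gold = kgg$gold,
                 manifest = manifest),
            class = "bkf_benchmark")
}

#' @export
print.bkf_benchmark <- function(x, ...) {
  s <- x$manifest$stats
  cat(sprintf("<synthetic benchmark: %d terms / %d entities / %d links, %d triples, depth %d>\n",
              s$n_terms, s$n_entities, s$n_links, s$n_triples, s$max_depth))
  invisible(x)
}

#' Write a benchmark to a directory in the canonical formats
#'
#' Emits `terms.jsonl`, `edges.tsv`, `entities.jsonl`, `triples.tsv`,
#' `links.tsv` and `manifest.json`.
#'
#' @param bench a `bkf_benchmark`.
#' @param dir output directory (created if missing).
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hierarchy(bench$hierarchy, file.path(dir, "terms.jsonl"),
                  file.path(dir, "edges.tsv"))
  write_kg(bench$kg, file.path(dir, "entities.jsonl"),
           file.path(dir, "triples.tsv"))
  write_links(bench$gold, file.path(dir, "links.tsv"))
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Split gold links into few-shot demonstrations and a test set
#'
#' A seeded uniform sample of `m` pairs becomes the demonstration pool; the
#' remainder is the test set. The two are disjoint and their union is the
#' input.
#'
#' @param gold a `bkf_alignment`.
#' @param m number of demonstration pairs, `0 <= m < |gold|`.
#' @param seed RNG seed for the sample.
#' @return `list(demos = bkf_alignment, test = bkf_alignment)`.
#' @export
split_few_shot <- function(gold, m, seed = 1L) {
  n <- nrow(gold$pairs)
  if (m < 0L || m >= n)
    abort_bkf(sprintf("m must satisfy 0 <= m < %d", n), "bkf_config_error")
  with_seed(seed, {
    idx <- if (m > 0L) sort(sample.int(n, m)) else integer(0)
    list(demos = alignment_set(gold$pairs[idx, , drop = FALSE],
                               few_shot_size = m),
         test = alignment_set(gold$pairs[setdiff(seq_len(n), idx), ,
                                         drop = FALSE]))
  })
}
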