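---
title: "Hierarchy-oriented knowledge fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchy-oriented knowledge fusion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bkfuse)
```

## The task and its assumptions

Biomedical knowledge fusion aligns each entity of a source knowledge graph
(KG) to the most specific term of a target hierarchy — a DAG of is-a edges
such as a disease ontology. `bkfuse` assumes:

* **One-to-one gold linkage.** Each entity has at most one gold term and
  vice versa. The evaluator scores per-query rankings; it never decodes a
  global bipartite matching.
* **Rich attributes.** Entities and terms carry synonyms and definitions;
  these are what the expansion retriever exploits to bridge naming
  conventions.
* **Scarce supervision.** The two supported settings are zero-shot (M = 0,
  a pseudo demonstration conveys the output format) and few-shot (M ≥ 1 real
  demonstrations drawn from held-out gold pairs).
* **Closed candidate set.** The re-ranker permutes the retrieved top-K; it
  cannot introduce a term retrieval missed. The oracle backend therefore
  attains Hits@1 equal to the retriever's recall@K — the re-ranking ceiling.

## Retrieval

Each term is serialized to a document: name; then (attributive expansion)
synonyms and definition; then (structural expansion) one-hop neighbour
names. Queries are built from entities the same way, using KG triples in
both directions for neighbours. Tokenization casefolds and splits on
non-alphanumeric runs — no stemming and no stopword list, so scores are
reproducible and language-resource-free.

Okapi BM25 parameters and their defaults:

| parameter | default | role |
|---|---|---|
| `k1` | 1.5 | term-frequency saturation; larger rewards repeated tokens |
| `b` | 0.75 | length normalization; 0 ignores document length |
| `k` (top-K) | 20 | candidate list length handed to the re-ranker |
| `n_max` | 16 | cap on structural neighbours per document |

`k1` and `b` sit at the common Okapi operating point; nothing in the package
tunes them. The idf is the nonnegative form `ln(1 + (N − df + 0.5)/(df + 0.5))`,
so a query sharing no token with a document scores exactly 0 and
ties are broken by lexicographic term id — rankings are bit-reproducible
across platforms. Structural expansion uses neighbour *names* only; relation
labels vary per KG and would pollute the shared lexical space. For terms the
default is parents *and* children (a flag restricts it to parents): a term's
children often share the very tokens a more specific query uses.

## Prompting and the answer mapping

A prompt is: task description, blank line, demonstration blocks
(`Query:` / `Choices:` / `Answer:`, names joined by `"; "`), blank line, an
optional `Contexts:` line with one `X isA parents` entry per candidate
(`ROOT` for parentless candidates, direct parents by default —
`context_depth` extends the chain), then the open test block ending in
`Answer:`. The separator `"; "` is reserved: names containing `;` are
rejected at load time rather than silently corrupting prompts. Prompts over
`budget_chars` (default 16000 characters, approximating a 4096-token
completion window at ~4 characters per token) raise an error — truncation
would silently delete candidates.

The completion is mapped back to a ranking by exact *normalized* name
matching (casefold, trim, collapse whitespace) after the first `Answer:`.
Fuzzy matching is deliberately avoided: it could silently reward
hallucinated near-names and corrupt the evaluation. Unmatched fragments are
counted and dropped; unmentioned candidates are backfilled in retrieval
order, so the result is always a permutation of the candidates and the
re-ranker is strictly a permutation layer over retrieval.

The pseudo demonstration is a fixed musical-instruments example; its
vocabulary is disjoint from the generator's biomedical token pool, so in the
zero-shot setting the demonstration can convey only format, never task
knowledge.

## Evaluation

Hits@k and MRR are strict: only the exact gold term counts, and a gold term
missing from a prediction list contributes rank ∞ (reciprocal rank 0) rather
than an error — retrieval misses must be punished, not crash.

The lenient metrics grade by Wu-Palmer similarity,
`2·depth(lcs)/(depth(a)+depth(b))`, under a root-depth-1 convention: rooting
depth at 1 keeps the similarity strictly positive for any co-rooted pair.
Depth is the shortest child-to-parent distance to the nearest root. Two
DAG-specific decisions:

* **Depth cap.** With shortest-path depths, a multi-parent shortcut can make
  a common ancestor nominally deeper than an endpoint, pushing the raw ratio
  above 1. The lcs depth is capped at `min(depth(a), depth(b))`, which is
  exact on trees and restores the `[0, 1]` bound (and `wup(t, t) = 1`) on
  DAGs.
* **Disjoint components score 0.** Multi-root forests are legal; terms with
  no common ancestor are maximally unrelated.

nDCG@k uses exponential decay, `DCG@k = Σ (2^rel − 1)/log₂(i+1)`, with
`rel(t) = wup(t, gold)`. The ideal DCG ranges over the *whole* hierarchy,
not the retrieved candidates, so a poor retriever cannot inflate its own
normalizer. One consequence worth knowing: a prediction list containing only
the gold term scores nDCG@1 = 1 but nDCG@3 < 1, because the ideal ranking
also fills ranks 2–3 with the gold term's closest relatives. The exact fixed
point of all metrics is the ideal full ranking (gold first, then terms by
decreasing relatedness), and the test suite asserts precisely that.

## The synthetic benchmark

The generator emulates the *structure* of real fusion benchmarks: a
single-root DAG grown by uniform attachment (max depth 13, the depth of the
disease hierarchy that motivates the task; multiple parents with probability
0.05), compositional names over a built-in biomedical-flavoured vocabulary
with ancestor-token inheritance, token-level synonyms, definitions derived
from parent names, a one-to-one gold linkage, and `associated_with` triples
between entities whose gold terms are hierarchically close. Entity names
diverge from term names through a fixed-order corruption pipeline — synonym
swap (0.3), token shuffle (0.2), token drop (0.15), abbreviation (0.1) —
chosen as moderate rates a curator would recognize: most names differ
somewhat from the index term, a minority are reordered or clipped, and an
occasional record is an initialism ("epidemic typhus" → "ET"). Defaults of
1000 terms and 200 entities keep a full pipeline plus evaluation around ten
seconds on one CPU while leaving headroom for ranking error.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: real synonym vocabularies (Latin/Greek variants,
eponyms), cross-lingual names, entities whose gold term is genuinely absent,
many-to-many raw linkages needing curation, and the scale of real ontologies
(10⁴–10⁵ terms). Passing the suite shows the machinery is correct and the
expansion/noise directions behave as theory predicts, not that any
particular accuracy transfers to a real KG.

## Numerical and degenerate-input choices

* Oracle-equivalence tests compare at 1e−9 absolute; the implementations and
  the brute-force oracles share no code path.
* All ordering ties (BM25 scores, parent lists, backfill) break by
  lexicographic id or original order — never by hash order or locale.
* Empty triple/edge files are valid (a KG may be attribute-only); an empty
  hierarchy cannot be indexed; `k` larger than the term count returns all
  terms with a warning.
* Cycles are reported with one offending cycle spelled out; a rootless input
  is necessarily cyclic and is diagnosed the same way.
* The generator's RNG use is wrapped so global seed state is saved and
  restored; identical configurations produce byte-identical artifact files.

## Problem sizes used by the test suite

Unit tests run on hand-built 3–6 node fixtures and 20–50 node random DAGs;
pipeline tests use a 150-term / 40-entity benchmark; the acceptance
properties run on the full default conditions (seed 17, 1000 terms, 200
entities) plus a three-point noise grid. The whole suite completes in about
a minute on one CPU.

## Known limitations

* The HTTP backend implements one generic completion POST; provider-specific
  schemas need a custom `transport` function.
* Wu-Palmer on multi-parent DAGs follows the capped-depth convention above;
  other toolkits differ in how they resolve the same ambiguity, so absolute
  WuP values are comparable only within one convention.
* The OBO importer covers the common tag subset (`is_a`, `synonym`, `def`,
  `is_obsolete`), not the full 1.4 grammar; OWL is out of scope.
* Token-level BM25 cannot bridge a pure initialism whose expansion shares no
  token with any attribute; such queries rely entirely on the re-ranker.
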