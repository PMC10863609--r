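Package: bkfuse
Title: Few-Shot Biomedical Knowledge Fusion by Retrieval and Prompt Re-Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns entities of a biomedical knowledge graph to the most
    specific term of a biomedical hierarchy (a DAG of is-a relations, such as
    a disease ontology). Candidate terms are generated by Okapi BM25 retrieval
    over expansion-enriched documents (names, synonyms, definitions, one-hop
    graph neighbours), then re-ranked by a pluggable text-completion backend
    driven by hierarchy-oriented prompts that expose each candidate's
    hypernyms. Includes strict (Hits@k, MRR) and lenient (exponential-decay
    nDCG, Wu-Palmer) ranking metrics, a seeded synthetic benchmark generator
    with one-to-one gold links and naming-convention noise, and a command-line
    pipeline runner.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    httr,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
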