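Package: phylotrg
Title: Phylome Reconciliation and Taxonomically Restricted Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylome-scale gene-tree analysis and the discovery of
    taxonomically restricted genes (TRGs). Implements species-overlap calling
    of speciation and duplication events on gene trees, mapping of
    duplications onto a species tree with per-node duplication ratios, Dollo
    gain/loss inference from ortholog presence patterns, a
    duplication-minimizing species-tree search, single-copy family selection
    and supermatrix concatenation, a multi-tool consensus orthology filtering
    cascade with annotation, isoform, expression and reciprocal-best-hit
    evidence, hypergeometric GO-term enrichment, and summarization of
    site-level selection posteriors. Includes simulators for gene families
    evolving by duplication and loss along a species tree, multi-tool
    orthology calls with configurable error, and developmental expression
    time courses, so every stage can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
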