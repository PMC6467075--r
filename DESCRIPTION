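Package: megaor
Title: Multi-Omics Evidence Integration and Consensus Candidate-Gene
    Prioritization by Mega-Analysis of Odds Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates heterogeneous gene-level association evidence
    (GWAS gene scores, eQTL-GWAS integration, transcriptome-wide
    association, differential expression, differential methylation)
    into a binary evidence matrix and prioritizes consensus candidate
    gene sets by maximizing a penalized combined odds ratio (cOR) with
    multi-restart hill climbing.  Includes tissue-specific enrichment
    analysis against an expression reference panel, pairwise
    evidence-association tests, protein-protein interaction resampling
    tests, drug-target crosstalk filtering, generic gene-set
    enrichment, and a synthetic-study generator with planted disease
    genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
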