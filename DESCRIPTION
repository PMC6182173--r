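Package: cytgrn
Title: Construction and Analysis of Literature-Curated Cytokine Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing bipartite gene regulatory
    networks between transcription factors (TFs) and cytokine genes curated
    from the literature. Provides evidence-level classification of
    protein-DNA interactions (PDIs), network connectivity statistics,
    tissue-specificity (TSPS), expression-enrichment (EES) and inflammatory
    (IS) scores per TF, cell-type and disease enrichment tests with
    Benjamini-Hochberg correction, a degree-preserving edge-switch null
    model for shared TF-cytokine-disease triplets, log-odds position weight
    matrix scanning of promoter sequences, and a co-expression plus
    motif-based pipeline predicting novel PDIs with confidence tiers.
    Includes a seeded synthetic-data generator emulating every input with
    known ground truth, and a desk-scale literature triage that flags
    articles co-mentioning a cytokine, a TF and an assay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
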