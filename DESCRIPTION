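Package: repstress
Title: Replication-Stress Gene Signature Derivation and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a replication-stress ("repstress") transcriptional
    signature from a characterized cell-line cohort and scores arbitrary
    expression cohorts with it. The derivation stratifies samples by four
    replication-stress characteristics (MYC-paralog amplification,
    checkpoint-inhibitor sensitivity, phosphorylated-Chk1 level and
    neuroendocrine differentiation), intersects leading-edge genes of
    commonly enriched gene sets across the four contrasts, adds
    DNA-repair genes differentially expressed with neuroendocrine state,
    and weights genes by first-principal-component loadings. Includes
    classic two-group GSEA with leading-edge extraction and permutation
    significance, single-sample GSEA, rank-based differential expression
    with Benjamini-Hochberg control, drug-sensitivity contrasts,
    Kaplan-Meier/log-rank survival stratification, and a seeded synthetic
    cohort generator with a planted latent replication-stress factor for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
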