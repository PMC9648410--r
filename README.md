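# repstress

Derivation and scoring of a replication-stress ("repstress")
transcriptional signature, for computational biologists who need a
scalable proxy for replication stress and its cellular response
(the ATR–CHK1–WEE1 axis) in bulk expression cohorts — cell-line panels
or tumors — where assay-based readouts such as γH2AX or ssDNA-bound
RPA are impractical.

## What it computes

**Scoring.** For a signature with gene weights $w_g$ and a log-scale
expression matrix, each sample is z-scored across all of its measured
genes and the score is the weighted sum over signature genes,

$$\mathrm{score}_j = \sum_{g \in S} w_g\, z_{gj},$$

then z-normalised across the analysis samples. Samples at or above the
75th score percentile are "high", strictly below the 25th are "low".

**Derivation.** `derive_signature()` rebuilds such a signature from a
characterized cohort: samples are stratified by four replication-stress
characteristics (MYC-paralog copy-number ≥ 0.7; checkpoint-inhibitor
drug activity > 6 for AZD-7762 or MK-1775; Chk1_pS345 RPPA > 0.15;
neuroendocrine differentiation by paired 25-gene ssGSEA scores); each
characteristic defines a two-group GSEA contrast; gene sets positively
enriched at adjusted P < 0.05 in all four contrasts contribute their
shared leading-edge genes; DNA-repair genes up in NE-high samples at
Mann–Whitney/BH FDR < 10% in every cohort are added; a prevalence
filter and explicit exclusions are applied; and each retained gene is
weighted by its first-principal-component loading computed jointly
with the four characteristic scores. The result is an S3
`repstress_signature` with `print`, `summary`, `coef`, `plot` and
`predict` methods.

Supporting modules: classic GSEA with leading-edge extraction and
permutation significance, single-sample GSEA, BH adjustment,
drug-sensitivity contrasts, paired treatment dynamics, group
comparisons and trend tests, Kaplan–Meier/log-rank survival, readers
and writers for GMT/TSV/GCT/JSON, and a seeded synthetic cohort
generator with a planted latent replication-stress factor used
throughout the tests. The packaged `default_signature()` carries the
published 17 gene symbols with sign-only placeholder weights
(see `?default_signature`).

## Worked example

```r
library(repstress)

co  <- simulate_cohort(cohort_config(seed = 1))   # planted cohort
sig <- derive_signature(co$expr, co$cn, co$drug, co$rppa, co$sets,
                        co$ne_high_set, co$ne_low_set,
                        ddr_genes = repstress_gene_lists()$ne_repair,
                        config = derivation_config(seed = 1))
#> derivation cohort: 60/60 sample(s) complete in all four characteristics
#> shared enriched sets: 2 (MOCK_E2F_SIGNAL, MOCK_G2M_SIGNAL)
#> shared leading-edge genes: 11
#> NE DE cohort 1: 37 gene(s) up in NE-high at FDR 0.1
#> NE-associated repair genes: 5

scores <- predict(sig, co$expr)
head(scores, 4)
#>   sample_id  raw_score norm_score group
#> 1      S001 -0.4168272 -0.7713663   low
#> 2      S002  1.6559341  0.2094449   mid
#> 3      S003 -1.6111180 -1.3364935   low
#> 4      S004  4.8677520  1.7292470  high

cor(scores$norm_score, co$truth$factor, method = "spearman")
#> [1] 0.976
```

The pipeline recovers exactly the two planted mock hallmark sets and
the 11 planted leading-edge genes, and the normalised score tracks the
generating latent factor (Spearman 0.976 here). The derived signature
has 16 genes on synthetic cohorts because the two negative-loading
planted genes are correctly rejected by the NE direction rule; the
published assembly (11 leading-edge ∪ 7 repair genes minus KPNA2)
yields the 17-gene list via `repstress_gene_lists()`.

A thin command-line wrapper ships in `exec/repstress` with `score` and
`simulate` subcommands over the same functions.

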