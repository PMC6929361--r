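Package: agestrat
Title: Gene-Age Stratified Analysis of Molecular Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies genes by taxonomic age (phylostratigraphy) and relates
    gene age to molecular attributes such as protein turnover, protein and mRNA
    half-life, intrinsic disorder, aggregation propensity, abundance and
    conservation. Provides age-group summaries with ANOVA/Bonferroni and
    Mann-Whitney comparisons, Spearman age correlations, a normalized
    peptide-variance statistic with turnover binning, bootstrap-null ranking of
    GO categories by turnover, steady-state transcription-rate derivation,
    cross-species ortholog turnover-ratio analysis with disease binning,
    post-translational-modification class analyses, and a synthetic-data
    generator with planted age-dependent structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
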