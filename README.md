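# agestrat

Gene-age stratified analysis of molecular attributes.

## The problem

Protein turnover, protein and mRNA half-lives, intrinsic disorder,
aggregation propensity, abundance and sequence conservation vary over orders
of magnitude between genes of the same cell, and gene function alone does not
explain the spread. A complementary axis is *gene age*: the evolutionary
branch on which a gene first appeared (phylostratigraphy). When human genes
are grouped into five taxonomic age classes — genes already present in
unicellular organisms (`u_org`), unicellular eukaryotes (`u_euk`),
Ophistokonta/Bilateria/Deuterostomia (`OBD`), chordates (`chor`) and mammals
(`mamm`) — older genes tend to produce more stable, more structured and more
abundant products, and the spread of those attributes shrinks with age.

`agestrat` packages that analysis path for anyone relating a per-gene age
table (e.g. ProteinHistorian output) to per-gene molecular attribute tables:

* **Age stratification** — ordered age-group schemes, branch-label mapping,
  merging of groups below a minimum size (default 10) into their older
  neighbour.
* **Group statistics** — per-group medians/means and sample variances,
  Spearman age correlation (`r` on average ranks, two-sided p from the
  t approximation), one-way ANOVA with Bonferroni-corrected pairwise t tests
  (rank-based Kruskal–Wallis/Mann–Whitney alternative behind a flag), and a
  Mann–Whitney test with an exact-enumeration branch that is valid under
  ties.
* **Normalized peptide variance** — per protein,
  `variance / median_turnover^2` of its peptide-level turnover values
  (proteins with < 3 peptides dropped), aggregated as bin medians over
  proteins sorted by turnover (93 per bin).
* **GO category ranking** — category mean (or median) turnover against a
  bootstrap null of 1000 matched-size resamples from the full turnover pool;
  significance as standard-deviation distance `z`, two-sided normal tail
  probability and stars (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05).
* **Steady-state transcription rates** — `ln(2) / half-life`, optionally
  scaled by abundance, from the proportionality of transcription and decay
  at steady state.
* **Cross-species ortholog analysis** — paired human/mouse turnover
  comparison, turnover-ratio bins (30 pairs each) with disease-count sums,
  and binned fractions of pairs whose turnover decreases from human to
  mouse (210 pairs per bin).
* **PTM classes** — exclusive methylated/acetylated/phosphorylated
  assignment, class-wise turnover comparison, and per-age-group PTM shares
  under both normalization conventions.
* **A synthetic-data generator** — all six input tables with planted,
  configurable age-dependent structure (defaults emulate the published
  study conditions), so the entire pipeline is testable end to end without
  the original proteomics datasets.

## Worked example

```r
library(agestrat)

cfg   <- simulation_config(seed = 42)          # the default study conditions
genes <- generate_gene_table(cfg)
age_attribute_analysis(genes, setNames(genes$turnover, genes$gene_id))
```

```
Age-group analysis of 3853 genes
 group    n central_value variance
 u_org  918         2.047   0.1195
 u_euk 1714         2.184   0.2072
   OBD  765         2.264   0.2904
  chor  384         2.342   0.4702
  mamm   72         2.440   0.8721
Spearman rank correlation: r = -0.1846, p = 6.779e-31, n = 3853 (t approximation)
Group comparison (anova): p = 5.594e-36
```

The median turnover rises monotonically from the oldest (`u_org`) to the
youngest (`mamm`) group — old genes make slow-turnover proteins — and the
within-group variance rises alongside: turnover is most uniform for the
oldest genes. The Spearman correlation of age rank with turnover is negative
(here −0.18; the generator's population value is −0.20) and the ANOVA
confirms the group differences.

```r
hom <- generate_homolog_pairs(genes, cfg)
pair_turnover_comparison(hom)
```

```
Ortholog turnover comparison (2107 pairs)
  mean human = 2.194, mean mouse = 2.016, mean ratio = 1.113
  fraction human > mouse = 0.742 (ties 0.000), Mann-Whitney p = 1.88e-34
```

About 74% of ortholog pairs have the larger turnover value in human, as
planted through the mouse/human species factor of 0.91 with lognormal ratio
noise.

The whole path (simulate → stratify → peptide variance → GO ranking →
orthologs → PTMs → report bundle) runs as one call:

```r
res <- run_full_analysis(run_config(output_dir = "run1", seed = 1))
print(res)
```

A thin command-line dispatcher with the same stages (`simulate`,
`age-correlate`, `peptide-variance`, `go-rank`, `interspecies`, `ptm`,
`run-all`) ships in `inst/scripts/agestrat.R`.

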