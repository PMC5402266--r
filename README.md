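# tsnetwork

Tissue-specific coexpression networks from multi-tissue expression data.

Organ development depends on genes whose expression is restricted to the
developing tissue, and disruptions of their co-regulation underlie
developmental disorders such as congenital heart disease/defect (CHD).
`tsnetwork` implements the complete analysis path for finding such genes and
their co-regulation structure from a gene × sample expression matrix
spanning many tissues (e.g. summarized microarray intensities of fetal
tissues), and for asking two follow-up questions: are disease candidate
genes overrepresented among them, and do they evolve under different
selective constraint?

## The statistics at the core

**Tissue-specificity index (TSI / tau).** For a gene with per-tissue mean
expression `exp_i` over `n` tissues and maximum `exp_max`,

```
TSI = Σ_{i=1..n} (1 − exp_i / exp_max) / (n − 1)
```

TSI is 0 for a uniformly expressed (housekeeping) gene and 1 for a gene
expressed in a single tissue, and is invariant under rescaling of the
profile. Genes maximal in a chosen target tissue group are ranked by TSI
and the top quantile (default 20%) is selected as tissue-specific.

**Coexpression network + MCL.** Pearson correlations between the selected
genes (log2 intensities, over target-tissue samples by default) define a
graph with edges at `r ≥ 0.80`. The graph is partitioned by a from-scratch
Markov Cluster (MCL) implementation: alternate *expansion* (matrix power of
the column-stochastic flow matrix) and *inflation* (elementwise power +
column renormalization, default 2.0) until the flow stabilizes; clusters
are the connected components of the limiting flow's support.

**Enrichment.** Overrepresentation of user-supplied gene sets (GMT) in the
selected set is tested with the hypergeometric upper tail
`P(X ≥ k)` for `X ~ Hypergeom(N, K, s)` against the preprocessing universe,
with Benjamini–Hochberg adjustment (and a permutation alternative).

**Selective constraint.** Mean derived allele frequency (DAF) of SNPs in
the selected genes is compared with a background set using bootstrap
percentile confidence intervals (default 500 replicates, 95% level);
persistently low DAF indicates purifying selection.

A seeded synthetic-data module generates all inputs with ground truth:
tissue panels with replicate arrays, planted co-regulated modules boosted
in the target tissues (a one-factor log-normal model with closed-form
within-module correlation), and variant tables with set-specific Beta DAF
distributions.

## Worked example

```r
library(tsnetwork)

dir <- file.path(tempdir(), "demo")
paths <- write_fixture_bundle(dir, expression_gen_config(seed = 17),
                              variant_gen_config(seed = 17))
cfg <- pipeline_config(
  expression = paths[["expression"]], samples = paths[["samples"]],
  target_tissues = paste0("heart_", 1:10), outdir = file.path(dir, "out"),
  gene_sets_gmt = paths[["gene_sets"]], variants = paths[["variants"]],
  seed = 17)
manifest <- run_pipeline(cfg)
```

prints (stage log):

```
[preprocess] 3476 genes x 40 samples -> 20 tissues (0.60s)
[specificity] 1536 target-maximal genes, 307 selected (0.10s)
[network] 307 nodes, 39147 edges, 4 clusters (0.54s)
[enrichment] 2 sets tested (0.01s)
[constraint] significant = TRUE (6.96s)
```

Reading: of 3476 genes, 1536 have their expression maximum in the 10-tissue
heart group; the top 20% by TSI (307 genes, nearly all of the 316 planted
module genes) form a network whose MCL partition recovers the 4 planted
modules. The planted `constrained` gene set is enriched in the selection,
and the DAF comparison finds the tissue-specific genes under detectably
different constraint:

```r
v <- read_variants(paths[["variants"]])
sets <- read_gmt(paths[["gene_sets"]])
compare_daf(v, sets$constrained, sets$background, n_reps = 500,
            level = 0.95, seed = 17, names_ab = c("heart_specific", "background"))
#> heart_specific: n = 1580 SNPs, mean DAF = 0.0923, 95% CI [0.0853, 0.0994]
#> background: n = 15800 SNPs, mean DAF = 0.1427, 95% CI [0.1401, 0.1451]
#> difference = -0.0504, bootstrap p = 0.003992, significant (disjoint CIs)
#>   (heart_specific lower; 500 reps)
```

The lower mean DAF in the specific set (disjoint CIs) reproduces the
planted direction: Beta(0.3, 3) SNPs (mean 0.091) against a Beta(0.5, 3)
background (mean 0.143).

All stage outputs (`specificity.tsv`, `network_edges.tsv`,
`network.graphml`, `clusters.tsv`, `enrichment.tsv`,
`daf_comparison.tsv/json`) land in `cfg$outdir` together with a
`manifest.json` of parameters and checksums; identical config + seed gives
identical checksums. A 20-member CHD candidate gene set ships as
`inst/extdata/chd_candidates.gmt`. A thin CLI lives in
`inst/scripts/tsnetwork.R`.

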