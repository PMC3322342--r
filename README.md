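# gscatlas

Cross-dataset filtering of germline stem cell (GSC) niche expression
profiles, with a fully seeded synthetic-data generator for validating
every stage against planted ground truth.

## The problem

Dissected gonadal tissues are cell mixtures. A two-color microarray
comparison of the Drosophila germarium against the apex of the testis
finds sex-biased genes, but cannot say whether a gene is expressed in
germline stem cells, their differentiating daughters, or the somatic
niche. The classic resolution is integrative: combine the tissue
comparison with independent experiments that are genetically or
physically enriched for stem cells (FACS-purified female GSC-like cells
vs Kc cells; *Os*-overexpressing *bgcn*-mutant testes vs *bgcn*-mutant
testes) and intersect significance/direction calls across datasets.
This package implements that pipeline — simulation, normalization,
testing, filtering, ranking, enrichment, and evaluation — for anyone who
wants to run the analysis on simulated or user-supplied expression
tables, or to study how reliably such conjunctive filters recover known
cell-type expression classes.

## The method

For each gene on a two-color array, **M** = log2(germarium/testis) after
undoing dye flips and **A** = mean log2 intensity. Robust loess of M on A
removes intensity-dependent dye bias; single-channel matrices are
quantile-normalized on the log2 scale.

Per-gene inference uses the empirical-Bayes **moderated t-test**: with
gene-wise variance s² on d degrees of freedom and a moment-matched
scaled-inverse-chi-square prior (d₀, s₀²),

    s̃² = (d₀·s₀² + d·s²) / (d₀ + d),     t = M / sqrt(s̃² / n_eff),

with two-sided p from the t distribution on d₀ + d df and
Benjamini–Hochberg FDR adjustment; significance is strict
adjusted p < 0.01.

Three conjunctive filters then produce ranked candidate lists:
genes enriched in **both** female and male stem-cell comparisons (plus a
baseline-intensity gate, intensity > 64 in both tissues), genes enriched
in the **germarium but not in female GSCs**, and genes enriched in the
**testis apex but not in male GSCs/gonialblasts**. Lists are ordered by
sums of per-dataset ranks (average ties; lexicographic final
tie-break). Term over-representation of each list is the exact
hypergeometric upper tail against the all-genes background. Recovery of
each list against its planted truth class is scored as
precision/recall.

## Worked example

The `analysis/` directory holds the numbered stage drivers
(`01_simulate.R` … `06_recovery.R`); each writes its tables under
`results/`. The same computation in one call:

```r
library(gscatlas)
manifest <- run_all(run_config(seed = 1), outdir = "results/run1")
```

which logs, for the default study shape (5,000 genes; 4 two-color
replicates, 2 dye-flipped, noise sd 0.35; 3 samples per single-channel
group, noise sd 0.15; planted effect 1.5 log2):

```
[normalize] replicate concordance: germarium R=0.957 (0.956-0.958), testis R=0.957 (0.956-0.957)
[de] significant genes at FDR<0.01: tissue 701, female GSC 457, male GSC 598
[integrate] filter shared_gsc: 293 genes
[integrate] filter germarium_not_gsc: 305 genes
[integrate] filter testis_not_gsc: 346 genes
[enrich] filter shared_gsc: top term planted_shared_gsc (p_adj=5.89e-47)
[evaluate] filter shared_gsc: precision 1.000, recall 0.977 (list 293, truth 300)
[evaluate] filter germarium_not_gsc: precision 0.977, recall 0.993 (list 305, truth 300)
[evaluate] filter testis_not_gsc: precision 0.853, recall 0.983 (list 346, truth 300)
```

Reading: replicate reproducibility sits where a careful two-color tissue
study lands (mean pairwise R ≈ 0.9–0.96); each filter list recovers its
planted expression class at ≥ 0.85 precision and ≥ 0.97 recall; and the
annotation term planted on each class tops its enrichment ranking. The
testis filter's lower precision is structural: genes expressed across
the whole male germ lineage barely differ between the two germ-cell-rich
testis genotypes, so the exclusion arm cannot remove them — the same
misclassification mode the integrative design has on real data. The
methods vignette (`vignettes/gsc-niche-filtering.Rmd`) documents the
model, parameter defaults, degenerate-limit guards, and limitations.

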