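---
title: "Models and methods behind xenoGerm"
author: "xenoGerm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xenoGerm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoGerm)
```

# The problem

When rat spermatogonial stem cells (SSCs) are transplanted into
germ-cell-depleted mouse testes and the regenerated tissue is profiled by
droplet single-cell RNA-seq, every droplet may contain a rat cell, a
residual mouse germ cell, or ambient RNA from both. Before any biology can
be read off, each barcode must be assigned to a species; the surviving rat
cells must then be staged along spermatogenesis and compared across
cryopreservation treatments (fresh, short-frozen, long-frozen, each before
and after transplantation). xenoGerm implements that full analysis as a
reusable, tested pipeline, together with a synthetic dual-species data
generator so that every stage can be exercised, end to end, without any
external data.

# The lineage model

`lineageModel()` encodes the idealised clonal arithmetic of rat
spermatogenesis: one SSC undergoes 9 mitotic doublings through progenitor
(3 of them, by default) and differentiating spermatogonia to type B
(2^9 = 512 cells, the ~500-fold premeiotic expansion), one further
doubling into preleptotene spermatocytes (1,024), and meiosis converts
each spermatocyte into 4 spermatids — 4,096 per founding stem cell.
`idealLineageCounts()` propagates these counts per stage; the split of
the nine doublings between the progenitor and differentiating phases
only positions the intermediate stage counts and does not affect the
terminal yield.

```{r lineage}
idealLineageCounts(lineageModel())
```

# The synthetic data generator

`simulateExperiment()` draws UMI counts from a hierarchical model chosen
to match what is known about droplet data rather than any particular
dataset:

* **Counts** are gamma-Poisson (negative binomial) per gene with a shared
  dispersion (default 0.3), the standard overdispersion model for UMI
  counts.
* **Library sizes** are lognormal with mean 3,000 UMIs (sd 0.35 on the
  log scale). Sequencing depth quoted in reads per cell is several-fold
  larger than the UMI yield after deduplication, hence a few thousand
  UMIs as the realistic default.
* **Stages.** Each of the seven germ-cell states has an expression
  profile built from a shared lognormal baseline modulated by a per-gene
  random walk along the stage order (step sd 0.35). The walk gives
  adjacent stages broad, correlated transcriptomic signatures — which is
  what makes unsupervised clustering and a largely linear pseudotime
  work on real spermatogenesis data — while marker genes are additionally
  boosted 50-fold in their own stage. Transition-protein and protamine
  genes (Tnp1/2, Prm1/2) are already elevated 10-fold in round spermatids
  before peaking in elongating spermatids, so treatment effects planted
  on them in round spermatids are measurable there and absent in
  elongating spermatids.
* **Stage sampling.** Unselected samples are late-stage heavy
  (2/3/7/12/21/30/25% across the stage order), qualitatively matching the
  amplifying divisions of the lineage; no quantitative stage census of
  the rat testis exists, so these weights are configuration, not claims.
  EpCAM-style selection multiplies the weights of the three premeiotic
  stages by 10. Replicate-to-replicate compositional variability is
  Dirichlet with concentration 225, i.e. about 2 percentage points of
  standard deviation on a 10% stage — the scale a sample-level ANOVA on
  proportions has to overcome.
* **Contamination and QC structure.** Each cell devotes an expected 1%
  of its library (configurable) to the other species' mean expression
  profile; per-cell mitochondrial load is Beta(2, 38) (mean 5%), spent on
  13 mitochondrial genes per species.
* **Planted effects.** Treatment arms modify the profiles relative to
  fresh: a 20-gene stress program is induced in SSCs of frozen arms
  (1.5-fold short, 2.25-fold long — the direction and ordering are the
  established finding; only the 1.5 magnitude convention is fixed);
  transplanted arms suppress Prm1/Tnp1/Tnp2 in round spermatids with the
  printed fold ratios (2.8/2.3/1.6-fold down in transplanted long-frozen
  versus fresh, intermediate in the other transplanted arms, Prm2
  untouched); transplanted long-frozen shifts composition (+0.10 SSC,
  −0.10 elongating spermatid); and a per-arm fraction of cells is
  apoptotic, with the 38-gene proapoptotic program tripled.

Planted DE folds are **exact on the CPM scale**: naive scaling plus
renormalisation attenuates a planted fold by the change in the library
total, so the generator solves for the gene scaling that makes the
normalised proportion ratio equal the planted fold. The apoptosis
induction, whose contract is only a higher module score, uses plain
scaling. The shipped gene programs (apoptosis, stress) are kept
stage-flat so that planted arm effects are their only systematic signal.

What the generator does **not** emulate: somatic cell types (the real
analysis removes them before germ-cell work; the generator produces only
germ cells), doublets, cell-cycle structure, batch effects requiring
anchor integration, barcode errors, or read-level artefacts. Passing
tests therefore demonstrate the correctness of the statistical machinery
under a faithful noise model, not robustness to every artefact of real
droplet data.

# Species assignment

A barcode is called rat iff its rat-aligned UMI total exceeds
`(1 + margin)` times its mouse-aligned total (default margin 0.05 — "more
than 5% higher"), mouse symmetrically, otherwise unknown. The comparison
is strict, so exact ties — including 105 vs 100 at the default margin,
and 0 vs 0 — are unknown. Totals sum over all genes of each reference,
mitochondrial genes included. Downstream stages keep only rat calls.
Accuracy against ground truth counts unknowns as errors.

# QC, normalisation, typing, pseudotime

Cells are dropped when mitochondrial reads exceed 20% of the library
(strictly: exactly 20% is kept), or fall below floors of 200 detected
genes / 500 UMIs. The floors quantify "low-quality cells", which the
margin rule's source leaves otherwise unspecified; an all-zero cell has
`pct_mito` defined as 0 and is caught by the UMI floor. Normalisation is
counts-per-million followed by log1p — the CPM convention matches the
"1 normalized count per million" display threshold — and preserves the
zero pattern exactly.

Typing runs k-means (25 restarts, seeded) on the top 10 principal
components, with **k = 14 by default: two centroids per expected state,
merged afterwards by marker-panel labelling**. With k equal to the seven
panels, k-means prefers splitting the abundant postmeiotic states over
isolating the rare premeiotic ones and annotation accuracy collapses;
mild overclustering followed by label merging is the field-standard
remedy and restores >90% accuracy on both selection streams. Each cluster
is labelled with the panel (mean log-normalised expression of the panel
genes) of highest mean score over its cells; ties break toward the
earlier stage. Because the premeiotic stages are rare in unselected
tissue, typing-critical analyses are best run on the EpCAM-selected
stream, exactly as the underlying experimental design does.

Pseudotime is a deliberate simplification of graph-based trajectory
inference: the first principal component rescaled to [0, 1], oriented so
the top decile of Etv5 expression (undifferentiated spermatogonia)
averages below 0.5. It is adequate for a single unbranched lineage and
nothing else.

# Pseudobulk, PCA, PERMANOVA

Sample-level inference treats each biological replicate as one
observation: `pseudobulk()` averages log-CPM over a replicate's cells of
one type (SSCs, for the freezing comparisons). PCA is row-centred;
distances are Euclidean on the log-CPM pseudobulk (the choice is a
documented assumption — no metric is canonical here — and configurable).

`permanova()` is implemented from its definition: with squared distances
d², SS_total = Σ_{i<j} d²_ij / N, SS_within sums within-group pairs
scaled by group size, and pseudo-F = ((SS_total − SS_within)/(a − 1)) /
(SS_within/(N − a)). The null distribution comes from random relabelings;
p = (1 + #{F_perm ≥ F_obs}) / (1 + n_permutations), so p is never 0, with
ties counted (the vegan convention). An `exhaustive` mode enumerates all
permutations for small N.

One numerical consequence deserves emphasis: with 3+3 samples there are
only 10 distinct relabelings, and the observed partition recurs among
random permutations with probability 0.1, so the add-one p-value cannot
drop much below ~0.1 regardless of effect size. Power and type-I
behaviour are therefore assessed at 4+4 and 5+5 in the test suite, where
p = 0.05 is resolvable; at 3+3 the test is exact but very conservative.
The default comparison pools the short- and long-frozen arms against
fresh (3 vs 6 replicates), which has tie probability ~0.012 and can
resolve p below 0.05.

# Differential expression

Within a cell type, cells are pooled across replicates and each gene gets
a two-sided Wilcoxon rank-sum test (normal approximation with continuity
and tie correction; exact when the smaller group has fewer than 8 cells).
The fold change is log2((mean_A + 1)/(mean_B + 1)) on CPM-scale means —
the +1 pseudocount stabilises low-expression genes and is the package's
convention, as no formula is canonical. FDR control is Benjamini–Hochberg
(the specific FDR procedure is unstated in common practice descriptions;
BH is the default everywhere and configurable here). A gene is
significant iff |log2FC| ≥ log2(1.5) ≈ 0.585 — inclusive, "minimum
1.5-fold" — and adjusted p ≤ 0.05, also inclusive. `overlapSets()` counts
every exclusive region of the Venn/Euler partition of several DEG sets.
Pooling cells across replicates follows the "on all cells" convention of
the original analyses; it is powerful but pseudoreplicated, which is why
the sample-level PERMANOVA complements it.

# Module scores, apoptosis, proportions

`moduleScore()` follows the published binned-control definition: genes
are cut into 25 equal-frequency bins of average expression, each program
gene draws up to 100 controls from the non-program genes of its own bin,
and the score is mean(program) − mean(controls) per cell. Excluding
program genes from the control pool matters whenever a program dominates
its expression bins (38 apoptosis genes at a common baseline do); when a
program spans its entire bin the pool falls back to the bin itself, which
keeps the whole-universe score identically zero. Control sampling is the
score's only stochasticity and is fixed by the seed. A cell is apoptotic
iff its score strictly exceeds 0.1 (a deliberately arbitrary published
cutoff; exactly 0.1 is not flagged).

`celltypeProportions()` row-normalises per-replicate type counts (rows
sum to 1 within 1e-9), and `anovaPerCelltype()` runs a fixed-effects
one-way ANOVA per cell type on untransformed proportions, matching the
direct use of proportions in the source analyses; an arcsine-sqrt
transform is deliberately not the default. Treatments with fewer than
two replicates are an error; a zero-variance response returns F = 0,
p = 1 by convention.

# The pipeline and its I/O

`runPipeline()` chains the stages — simulate (or accept counts), assign
species, QC, normalise, cluster, type, pseudotime, SSC pseudobulk
PCA + PERMANOVA (pooling frozen arms against the rest when both exist),
per-cell-type DE versus the first arm, apoptosis scoring, proportions and
ANOVA — deterministically under the configuration seed, and writes
annotations/proportions/DEG tables as TSV plus a JSON report. Counts
travel as 10x-style MatrixMarket triplets (genes x cells, 1-based
indices); the reader validates dimensions against the sidecar TSVs,
rejects non-integer entries, and refuses silently truncated coordinate
files. A thin command-line wrapper over these functions ships in
`inst/scripts/xenogerm.R`.

# Scales used by the shipped checks

The test suite and acceptance script size their simulations to be
decisive yet quick: the species-assignment validation uses 10,000 +
10,000 cells with the default 1,000-gene universes; typing accuracy uses
the default 9,000-cell EpCAM-selected design; parameter recovery uses
~550 round spermatids per group; type-I checks use 500 (PERMANOVA) and
100 (ANOVA) simulations; the directional end-to-end check uses two
transplanted arms of 3 x 600 cells and a 300-gene universe. These sizes
are the package's chosen operating points for its own verification.

# Known limitations

The generator's realism bounds what green tests mean (see above). The
margin rule is applied to UMI totals — whether the original protocol
applied it before or after UMI collapse is unknowable from the published
description; UMI totals match the count-matrix entry point. Clustering
quality, and hence typing, degrades for stages rarer than ~1% of cells;
EpCAM-selected input is the supported route to premeiotic resolution.
Wilcoxon DE pools cells and so inherits pseudoreplication; PERMANOVA at
very small replicate counts is granular, as discussed. The pipeline does
not integrate batches, detect doublets, or infer branched trajectories.
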