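---
title: "Assessing cold-storage stability of tissues in droplet scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cold-storage stability of tissues in droplet scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldstab)
```

## The problem

Human tissue for single-cell RNA-seq is rarely dissociated at the bedside.
A practical alternative is to hold the intact tissue piece at 4 °C in a
hypothermic preservation solution and process it later — hours to days of
*cold ischemic time*. The question this package addresses is: how do you
tell, from the sequencing data alone, whether that storage degraded the
sample, and where the degradation shows up first?

Degradation leaves several distinct fingerprints in droplet data:

* **Ambient RNA and debris.** Dying cells leak transcripts; droplets that
  captured no cell still capture that free-floating mRNA ("soup"), and
  droplets with intermediate RNA content capture cell fragments.
* **Mitochondrial enrichment.** Stressed and dying cells retain
  mitochondrial transcripts while losing cytoplasmic ones, raising the
  per-cell mitochondrial UMI percentage.
* **Intron/exon skew.** Unspliced (intron-containing) transcripts appear
  relatively more stable to degradation, so the exonic fraction of
  confidently mapped reads falls while the intronic fraction rises.
* **Composition and expression drift.** Vulnerable cell types drop out of
  the captured population, and stress signatures appear in the
  per-cell-type expression profiles.

`coldstab` implements one coherent pipeline for all of these, plus a
synthetic droplet-experiment generator that provides exact ground truth
for every statistic the pipeline computes.

## The droplet statistic

The central droplet-level quantity is the read-depth-normalized UMI count

$$\tilde u_b = u_b \times \frac{10^6}{\sum_{b'} u_{b'}}$$

where $u_b$ is the UMI count of barcode $b$ and the sum runs over all
barcodes of the run. By construction $\sum_b \tilde u_b = 10^6$ for every
run, which makes droplet populations comparable across sequencing depths.
Droplets are then classified by fixed intervals:

| class | interval |
|---|---|
| ambient RNA | $0 < \tilde u \le 0.25$ |
| debris | $0.25 < \tilde u \le 5$ |
| cellular material | $\tilde u > 5$ |

Upper bounds are inclusive, matching the defining inequality chain
exactly; a barcode with zero UMIs falls in no interval and is reported
`unclassified` rather than silently dropped. Classification is invariant
to uniform depth scaling, and `class_means()` summarises each class per
sample; per-donor class means at different storage times are compared with
Student t tests (`compare_time_points()`), paired where the same donors
contribute both time points and unpaired otherwise, because not every
donor has every time point. `ambient_profile()` ranks genes by their share
of ambient-droplet UMIs — the soup profile.

## Cell-level quality control

`filter_cells()` applies the standard filters: cells with fewer than 300
or more than 5,000 detected genes (8,000 in esophagus, whose keratinocytes
are larger and more complex), more than 20,000 UMIs, or more than 10%
mitochondrial reads are removed. The wording is strict ("fewer
than"/"more than"), so boundary cells — exactly 300 genes, exactly 20,000
UMIs, exactly 10% MT — are **kept**; this off-by-one matters for cell
counts and is pinned by tests. The removal log records the first rule that
fired per cell, in the order min-genes, max-genes, max-UMI, max-MT, so
cell-count reconciliation is exact. `filter_genes()` keeps genes detected
in at least three cells of the tissue-pooled matrix and is idempotent.

Read categories (exonic / intronic / intergenic counts of confidently
mapped reads per barcode) arrive as a separate TSV; the pipeline never
parses alignments itself. The companion extraction that produces this TSV
should select reads with the aligner's confident-mapping quality value
(255 by convention). `quartile_extremes()` ranks cells by an alignment
fraction and averages the top and bottom `ceiling(n/4)` cells — the
extremes respond to degradation earlier than the mean. Ties are broken by
barcode order so the quartile membership is deterministic.

## Reassigning high-mitochondrial cells

Cells above 10% MT are excluded from clustering, but discarding them would
bias exactly the statistic of interest (the per-cell-type MT fold change).
They are therefore projected onto the annotated reference: centroids are
per-gene **medians of log-normalized expression** (counts scaled to a
common total of 10,000, then `log1p`) per cell type, on features selected
by a dropout-vs-expression criterion (genes with the largest positive
residuals of dropout rate regressed on log mean expression; top-variance
fallback when few genes exist). Queries are assigned to the nearest
centroid by cosine similarity, with a 0.7 abstention threshold. The
projection tool this emulates does not publish its parameter choices, so
the feature count (500) and threshold (0.7) here are package defaults, not
reproduced facts. Raising the threshold can only move cells to
`unassigned`, never flip a label (monotone abstention), and the similarity
is computed on depth-normalized profiles, so assignment is invariant to
per-cell depth.

## Degradation statistics

* `mito_fold_change()` — for every (tissue, cell type, time) stratum,
  FC = mean MT% at time *t* over mean MT% at baseline, pooling low- and
  reassigned high-MT cells. Significance is a two-sided Wilcoxon rank-sum
  test of the per-cell MT percentages against baseline, BH-corrected
  within tissue. The display test is unnamed in the source material; the
  rank-sum choice here is deliberate — MT% distributions are strongly
  skewed, and a rank test is robust to that. Strata with fewer than 5
  cells on either side are masked `too_few_cells` (no FC, no p);
  (tissue, time) combinations without any sample are `missing_sample`.
  `significance_bins()` maps adjusted p to the reporting bins
  `*` < 0.01, `**` < 1e-5, `***` < 1e-8.
* `composition_proportions()` / `composition_time_tests()` — per-sample
  cell-type proportions (absent types count as 0 so rows sum to 1), with
  unpaired t tests for each baseline-vs-later contrast and for the
  combined early-times-vs-last contrast, BH across cell types and
  contrasts within tissue.
* `composition_donor_anova()` — one-way ANOVA of proportion on donor per
  (tissue, cell type), BH within tissue, reporting how many combinations
  differ significantly between donors. ("One-way" is the reading taken of
  an ambiguous "one-sided ANOVA": the F test is inherently one-tailed.)
  Zero-variance strata are flagged `degenerate` rather than producing 0/0.
* `variance_explained()` — gene-wise marginal R², each factor fitted
  **alone** (group means for categorical factors, linear fit for
  continuous depth or time), since the global partition asks how much each
  factor explains by itself. For the per-cell-type time analysis the donor
  and depth effects can first be residualized out (`residualize=`), but
  time and MT% never are — residualizing the variable under study would
  erase the signal.
* `crossorgan_dendrogram()` — deterministic subsample of up to 10 cells
  per (cell type, tissue, time, donor) stratum, 1,000 most variable genes
  by mean-binned normalized dispersion, average-linkage clustering on
  correlation distance; exported as newick with a leaf-metadata sidecar.

## Expression comparison

`make_pseudobulk()` sums raw counts per sample (sum, not mean — the
conventional construction; recorded in the provenance attribute).
`wilcoxon_de()` normalizes both matrices to counts per million, applies
the paired Wilcoxon signed-rank test across samples (zero-difference pairs
dropped per the test's convention; the unpaired rank-sum variant is
available), BH-corrects across genes, and reports the median over samples
of $\log_2((a+1)/(b+1))$ — pseudocount of one normalized count, so fold
changes stay finite. The upstream normalization is not documented in the
source material; CPM was chosen and is recorded in output metadata.
`storage_signature()` extracts per-cell-type time signatures (rank-sum,
adjusted p < 0.01) and their Jaccard similarity matrix;
`signature_overlap_fisher()` tests overrepresentation of a signature in a
reference set (for instance the dissociation-related immediate-early genes
FOS, FOSB, JUN, JUNB shipped by `dissociation_genes()`) with a one-sided
exact hypergeometric test — one-sided because the question is enrichment,
never depletion.

## The synthetic generator

`sim_config()` + `generate_experiment()` produce a complete multi-donor,
multi-tissue, multi-time-point droplet experiment with per-droplet truth:

* **Droplet totals** are log-normal around the class mean (cells, debris,
  ambient separately) — the simplest model that reproduces the heavy-tailed
  UMI-rank curve of real runs. Per-gene counts are multinomial on the
  appropriate profile: the cell's type profile, a reduced-depth type
  profile for debris, and the proportion-weighted mixture of all type
  profiles for ambient droplets (optionally up-weighting high-secretion
  types via `ambient_soup_weights`, mimicking plasma-cell-dominated soup).
* **Mitochondrial content** is drawn as a binomial split of each droplet's
  total at the target MT fraction (baseline × configured fold change),
  with MT counts then spread over the MT gene block. This keeps depth and
  MT% orthogonal by construction and makes stratum truth means exact:
  baseline 0.05 with fold 2 gives an expected MT% of exactly 10.
* **Read categories** are generated per barcode independently of the gene
  counts: a beta-distributed exonic fraction parameterized by mean and
  *fixed standard deviation* (so a mean shift translates the whole
  distribution and quartile means move one-for-one with the injected
  intron shift), a constant-mean intergenic fraction, remainder intronic.
* **Degradation dials** (`degradation_params()`): MT fold change per
  (tissue, cell type, time); intron shift per (tissue, time); target
  ambient share of total run UMIs per (tissue, time), implemented by
  scaling total ambient depth to $f/(1-f)$ times the cell+debris UMIs so
  the truth fraction is $f$ in expectation; and storage-signature genes
  whose profile mass scales with time. At time 0 all factors are 1 and all
  shifts 0, enforced at construction. `degradation_params()` with no
  arguments is the **null mode** used for calibration.
* **Determinism.** One global seed; each sample draws from a substream
  derived from (seed, donor, tissue, time), so an identical config yields
  a bit-identical experiment and adding a sample never perturbs others.

The default configuration emulates the study design this package grew out
of: 5 donors × three tissues (lung, esophagus, spleen) × storage times 0,
12, 24, 72 h, with spleen-only degradation at 72 h (MT fold 2, intron
shift 0.10) — the tissue and time point where real degradation was
observed. Sizes are desk-scale: 2,000 cells, 1,000 debris and 8,000
ambient droplets per sample at depth means of 20,000 / 60 / 3 UMIs. Those
depth means are one decade apart and, at these droplet counts, place the
three classes inside the fixed normalized-UMI intervals with ~99.7%
accuracy; the debris band is taken as the defining property of debris and
the generator targets it directly, since no empirical depth distribution
for debris is available. The bands are *absolute* thresholds: shrinking a
run (fewer cells or lower depth) shifts where raw counts land in
normalized units, so tests that exercise the classifier keep the default
scale, while tests of depth-free statistics run much smaller.

What the generator does **not** emulate: doublets, batch/chemistry
effects, gene-length or GC bias, bursty transcription beyond the
log-normal × multinomial hierarchy, and spatial tissue heterogeneity
(glands, vessels) that drives real between-sample composition variance.
Passing calibration on synthetic nulls therefore shows the *statistics*
are sound, not that real tissues are free of those additional variance
sources.

## Numerical choices and degenerate inputs

* Benjamini–Hochberg correction has a single implementation
  (`bh_adjust()`), verified in the test suite against a brute-force
  step-up oracle on all permutations of small p-value families.
* Exactly-zero-UMI barcodes are `unclassified`; all-zero runs error
  ("empty run") rather than returning NaN.
* Paired t tests with zero-variance differences error as degenerate;
  unpaired t tests on two identical constant groups return p = 1.
* Genes all-zero in both DE groups are `untested`; genes whose pairs all
  tie get p = 1 (no evidence) rather than being dropped.
* Odds ratios use the Haldane 0.5 correction only when a margin cell is 0.
* Quartile and subsampling operations break ties by barcode order /
  derive from the run seed, so every table is reproducible byte-for-byte.

## Problem sizes used by the test suite

The calibration properties run 200 null-mode experiments (6 donors, one
tissue, four time points, 60 cells/sample, 40 genes) for the composition,
bulk-DE and metric-trend false-positive rates; parameter-recovery
properties use ~500 cells per stratum for the MT fold change, 100 runs of
3-donor two-time-point experiments for ambient-shift detection, and a
10,000-cell planted matrix for filter fidelity. These sizes were chosen as
the smallest designs in which each property is statistically identified
(binomial 2-SE bounds on the rates; 3-SE bands on recovered shifts).

## Running the pipeline

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)                 # default study-design emulation
exp <- generate_experiment(cfg)
write_fixture(exp, "experiment/")

pc <- pipeline_config("experiment/", "report/")
report <- run_pipeline(pc)
report$fold_change        # per-stratum MT fold changes with masking
report$composition_tests  # time contrasts per tissue and cell type
```

The pipeline stages run in dependency order (droplets → cells → assign →
stats, plus de when a bulk table is supplied), write every table as TSV,
log each masking/skip decision, and embed a config hash in the manifest so
identical re-runs are verifiably identical.

## Known limitations

Cell calling is out of scope: the pipeline takes the cellular-material
class as its cell set (or an upstream caller's output via the fixture
layout). Doublet detection, de-novo clustering and manual annotation are
likewise upstream concerns — cell-type labels are inputs. The Wilcoxon
test choice for the MT fold-change display and the CPM normalization for
DE are package decisions where the source material is silent; both are
recorded here and in output metadata so downstream users can account for
them.
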