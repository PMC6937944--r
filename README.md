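# coldstab

Quality control and degradation statistics for droplet single-cell RNA-seq
of tissues held in cold hypothermic preservation before dissociation.

When an intact tissue piece sits at 4 °C for hours or days before
dissociation (cold ischemic time), degradation shows up in the sequencing
data as free-floating "ambient" RNA, debris from damaged cells, rising
mitochondrial read percentages, and a skew from exonic toward intronic
reads. `coldstab` quantifies all of these from standard 10x-style count
matrices, for people running tissue-stability pilots or auditing archived
scRNA-seq cohorts for storage artifacts.

## What it computes

The droplet-level statistic is the read-depth-normalized UMI count,

```
normalized UMI = UMI per droplet x 1,000,000 / UMI in all droplets per run
```

with fixed intervals classifying every barcode: ambient RNA
(0 < u ≤ 0.25), debris (0.25 < u ≤ 5) and cellular material (u > 5).
On top of that sit:

* per-barcode exonic/intronic/intergenic read fractions with top/bottom
  quartile trend analysis;
* the standard cell filters (300–5,000 detected genes, 8,000 in
  esophagus; ≤ 20,000 UMIs; ≤ 10% mitochondrial reads — boundaries kept)
  with an exact removal log, and the ≥ 3-cells-per-gene filter;
* cosine-similarity reassignment of high-mitochondrial cells to their
  nearest annotated cell type, so MT statistics include the cells most
  affected by stress;
* per-cell-type mitochondrial fold-change tables (Wilcoxon rank-sum,
  BH-corrected per tissue, strata under 5 cells masked);
* cell-type composition tests over time and one-way ANOVA across donors;
* gene-wise marginal R² variance partitioning by donor, tissue, cell
  type, depth and time;
* cross-organ hierarchical clustering of up to 10 cells per stratum on
  the 1,000 most variable genes;
* bulk vs single-cell pseudo-bulk differential expression (paired
  Wilcoxon signed-rank, BH, median log2 fold change) and Fisher's exact
  overrepresentation of storage signatures among dissociation-related
  genes (FOS, FOSB, JUN, JUNB, ...).

A synthetic droplet-experiment generator (`sim_config()`,
`generate_experiment()`) produces multi-donor, multi-tissue,
multi-time-point experiments with per-droplet ground truth and injectable
degradation (MT fold change, intron shift, ambient UMI fraction, storage
signature genes), so every statistic in the pipeline can be validated
against known truth. See the vignette in `vignettes/` for the model and
its assumptions.

## Worked example

Simulate a two-time-point spleen experiment for three donors with the
default degradation (mitochondrial fraction doubled at 72 h), write it as
a 10x-style fixture, and run the full pipeline:

```r
library(coldstab)

cfg <- sim_config(n_donors = 3, tissues = "spleen", time_points_h = c(0, 72),
                  n_genes = 60,
                  cell_type_profiles = make_cell_type_profiles(
                    n_genes = 60, cell_types = c("T_cell", "B_cell", "Plasma"),
                    n_mt_genes = 6, markers_per_type = 8),
                  seed = 1)
exp <- generate_experiment(cfg)
write_fixture(exp, "experiment/")

pc <- pipeline_config("experiment/", "report/",
                      thresholds = cell_qc_thresholds(min_genes = 20,
                                                      max_umi = 1e6))
rep <- run_pipeline(pc)

head(rep$droplet_class_summary, 3)
#>       sample_id    class n_droplets mean_norm_umi
#>  D1_spleen_T00h  ambient       7976       0.07361
#>  D1_spleen_T00h   debris       1015       1.45103
#>  D1_spleen_T00h cellular       2005     497.72573

fc <- rep$fold_change
fc[fc$time_h == 72, c("cell_type", "n_cells", "fc", "p_adj", "status", "bin")]
#>  cell_type n_cells fc p_adj status bin
#>     B_cell    1961  2     0     ok ***
#>     Plasma    2026  2     0     ok ***
#>     T_cell    2022  2     0     ok ***

rep$high_mt_rate
#>       sample_id n_cells high_mt_rate
#>  D1_spleen_T00h    2005        0.000
#>  D1_spleen_T72h    2001        0.495
#>  ...
```

Reading the output: the droplet classes land in their normalized-UMI
bands (ambient mean 0.074, debris 1.45, cellular 498); the injected
72-hour mitochondrial fold change of 2 is recovered exactly in every cell
type with vanishing adjusted p (`***` bin); and roughly half the 72-hour
cells exceed the 10% MT threshold while baseline samples have essentially
none. The gene-count thresholds are rescaled in `cell_qc_thresholds()`
because the synthetic universe has 60 genes; on real data the defaults
apply unchanged.

The same flow works from the shell via the thin CLI wrapper:

```sh
Rscript inst/scripts/coldstab-cli.R simulate --out experiment --seed 1
Rscript inst/scripts/coldstab-cli.R run --in experiment --out report
```

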