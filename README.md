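# methrestore

Integrative DNA-methylation / gene-expression analysis for
three-condition designs (control, disease, treatment), built around the
idea of a **restoration pattern**: a molecular change induced by disease
that is reversed by treatment. The package identifies genomic regions
whose methylation follows a hyper/hypo or hypo/hyper trajectory across
the two contrasts, genes whose expression follows the mirrored down/up or
up/down trajectory, and pairs the two layers through an inverse Spearman
correlation into **Pattern A** (hyper/hypo methylation + down/up
expression) and **Pattern B** (hypo/hyper + up/down) epigenetically
regulated genes.

It is aimed at bulk bisulfite-capture (Methyl-seq) + RNA-seq experiments
in small-n animal-model studies, starting from per-CpG count tables and a
transcript count matrix — alignment and quantification are upstream of
this package.

## Method

**Windowed DMR calling.** Chromosomes are tiled into 1000-bp windows
advanced by 500 bp. CpGs with read depth ≥ 20 in every sample of the
compared groups are pooled per window and sample; windows with ≥ 2 CpGs
are tested. Writing $m_{ij}, d_{ij}$ for the pooled methylated counts and
depths of window $i$ in sample $j$, the test is the logistic-regression
likelihood-ratio test of $m_{ij}/d_{ij}$ on group membership
($\chi^2_1$), with the statistic scaled by a Pearson overdispersion
factor pooled across all windows of the contrast. Group methylation is
the pooled ratio $\beta_g = \sum m / \sum d$ and the effect size is
$\Delta\beta = 100(\beta_b - \beta_a)$ percentage points. After
Benjamini–Hochberg adjustment over all tested windows, a window is a DMR
iff $|\Delta\beta| \ge 10$ and $q < 0.01$.

**Differential expression.** Counts are scaled to a common library size
(CPM); each transcript is tested by a Wald test on the log mean ratio
under a negative-binomial variance model with moment-estimated,
common-shrunk dispersion. Fold changes are reported in the signed linear
convention ($+r$ for up, $-1/r$ for down); the conventional screen is
$|\log_2 FC| \ge 1$ and $p < 0.05$.

**Integration.** A DMR links to transcripts whose promoter (TSS ± 1 kb)
or body it overlaps. For each link, the methylation pattern across the
ordered contrasts (disease vs control, treatment vs disease) and the
expression pattern are classified; concordant pairs with a negative
Spearman correlation between per-sample window methylation and min-max
scaled expression (all samples jointly) become Pattern A/B genes.

## Worked example

A complete synthetic study at the package defaults (3/3/4 samples, 2 × 2
Mb genome, 30-pp planted methylation shifts, 4-fold planted expression
changes, 20 + 5 planted pattern genes):

```r
library(methrestore)
d <- simulate_dataset(sim_config(seed = 7))
report <- run_pipeline(d$samples, d$sample_sheet, d$counts, d$models)
report
#> Restoration-pattern pipeline report
#>   contrasts: control -> disease; disease -> treatment
#>   windows tested: 7982 / 7980
#>   contrast 1 DMRs: 59 hyper (0.74%), 16 hypo (0.2%)
#>   contrast 2 DMRs: 15 hyper (0.19%), 59 hypo (0.74%)
#>   restoration DMRs: 58 hyper/hypo + 15 hypo/hyper = 73
#>   integrated: 73 DMRs, 25 genes (20 Pattern A, 5 Pattern B)
```

All 25 planted genes are recovered with their true patterns (the 73
integrated DMRs include the tiling neighbours that share each planted
window's CpGs — overlapping windows are deliberately reported
independently). The 59/16 hyper/hypo split under "disease" and its
mirror image under "treatment" show the planted induction-then-restoration
structure; the percentages are fractions of all tested windows.

The packaged candidate-gene table (27 DMR–transcript rows from a
published three-condition asthma study) is the deterministic worked
example for the classifiers:

```r
str(table1_report()[1:5])
#> List of 5
#>  $ n_rows_classified: int 27
#>  $ n_dmrs_unique    : int 25
#>  $ n_genes          : int 18
#>  $ n_pattern_a      : int 17
#>  $ n_pattern_b      : int 1
```

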