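---
title: "Restoration-pattern analysis of methylation and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoration-pattern analysis of methylation and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrestore)
```

## The design and the question

The package targets a three-condition bulk design — control, disease,
treatment — profiled in the same animals with bisulfite capture
sequencing (per-CpG methylated/unmethylated counts) and RNA-seq (a
transcript count matrix). The scientific object is the *restoration
pattern*: a change induced by disease (contrast 1, disease vs control)
that is reversed by treatment (contrast 2, treatment vs disease). In the
methylation layer this is hyper/hypo or hypo/hyper; in the expression
layer, down/up or up/down. Genes where a methylation restoration and the
mirrored expression restoration co-occur at a linked locus, with an
inverse methylation–expression correlation across samples, are reported
as Pattern A (hyper/hypo + down/up) or Pattern B (hypo/hyper + up/down).

## Windowed differential methylation

Chromosomes are tiled into overlapping windows (1000 bp, step 500 bp by
default), so interior bases belong to exactly two windows. Overlapping
windows are tested and reported independently: when a signal straddles
the grid, both members of a pair fire, and we keep both rather than
merging — the region identity (`chr$start$end`, 1-based inclusive) stays
interpretable and downstream gene-level rollups deduplicate anyway.

The depth filter (`min_depth = 20`) is applied per sample over all
samples of the two compared groups: a CpG enters a contrast only if it
is covered ≥ 20× in every one of those samples. This is the strictest
reading of a minimum-coverage rule; it guarantees pooled window counts
never mix covered and uncovered replicates, and it makes the testable
window set contrast-specific (the two contrasts legitimately report
different bin totals). Strands are kept as reported — CpG dyads are not
collapsed by default (`destrand = FALSE` in `build_cpg_set()`), since
collapsing assumes symmetric dyad methylation; a flag enables it.

Windows with ≥ 2 retained CpGs are tested by the logistic-regression
likelihood-ratio test of the pooled per-sample binomial counts on group
membership. With a single two-level covariate the group model's MLE is
the pooled proportion per group, so the deviance difference has a closed
form and the whole genome is tested vectorised, without iterative
fitting; the test suite verifies the closed form against `glm()`.

### Overdispersion

Replicate-to-replicate variation in methylation exceeds binomial
sampling noise, and an uncorrected binomial LRT is anti-conservative on
such data. The default (`method = "qlrt"`) therefore scales the LRT by a
McCullagh–Nelder-type dispersion factor — the Pearson chi-square of the
group fit divided by its residual degrees of freedom, floored at 1 —
and refers the scaled statistic to $\chi^2_1$. Two numerical choices
matter here:

* The dispersion is **pooled across all windows of a contrast**
  ($\hat\phi = \sum_w X^2_w / \sum_w \mathrm{df}_w$). A per-window
  estimate has only $n-2$ residual df (4 in a 3-vs-3 design), and the
  ratio of a $\chi^2_1$ statistic to so noisy a denominator is
  F-distributed rather than chi-square — referring it to $\chi^2_1$
  stays anti-conservative. The pooled estimate is effectively noiseless,
  restoring calibration while still adapting to the data's actual
  overdispersion.
* The **chi-square reference** (not an F reference) is kept so that
  extreme windows can reach arbitrarily small p-values; an F test with 4
  denominator df saturates near 10^-5 even under complete separation,
  which would make genome-wide q < 0.01 calls impossible for clean
  strong signals.

When either group has a single replicate the dispersion is not
estimable and `method = "auto"` falls back to Fisher's exact test on the
pooled 2×2 table. Degenerate windows (identical pooled proportions,
including both groups all-0 or all-1) give a zero LRT and p = 1 exactly.

Multiple testing uses Benjamini–Hochberg over all tested windows of the
contrast: deterministic, monotone in the p-values, and standard. A
window is a DMR iff $|\Delta\beta| \ge$ `min_diff` (10 pp) and
$q <$ `max_q` (0.01), with $\Delta\beta$ the difference of group-pooled
betas in percentage points — ratio-of-sums pooling, not mean-of-ratios,
so deep CpGs weigh more and the statistic matches the tested counts.

## Feature annotation

Each window receives exactly one of six classes by fixed precedence:
promoter > 5′ UTR > 3′ UTR > CDS > intron > intergenic, any ≥ 1-bp
overlap counting. The promoter is TSS ± 1000 bp (strand-aware TSS), the
common tiling-annotation convention; both the span and the precedence
are configuration knobs since neither has a universal definition.
UTRs are derived as exonic sequence outside the CDS span on the
respective side; exons of non-coding transcripts rank at the 3′-UTR
level (they are real transcribed sequence but have no reading frame, so
they should not outrank true 5′ UTRs or CDS). DMR→transcript links are
overlap-first (promoter or gene body, distance 0), then nearest TSS
within `max_distance`, keeping all equidistant ties in lexicographic
order. Annotations load from BED12 or GTF via `rtracklayer`.

## Differential expression

The paper-scale design (3 vs 3) calls for a negative-binomial test, and
the package implements a deliberately compact one rather than wrapping a
full DE framework: counts are scaled to a common library size (CPM-style;
TMM-type composition correction is out of scope and a documented
deviation), per-transcript dispersion is estimated by the method of
moments within groups, left unfloored, shrunk halfway toward the trimmed
common dispersion and then floored at zero — flooring before pooling
would bias the null dispersion upward and make the test conservative.
The Wald statistic for the log mean ratio uses the delta-method variance
$(1/\mu + \phi)/n$ per group and a standard normal reference. Fold
changes use a 0.5 pseudocount on group means and the signed linear
convention ($+r$ up, $-1/r$ down), so the two-fold screen
$|\mathrm{fc}| \ge 2$ coincides with $|\log_2 FC| \ge 1$. Significance
for the DEG screen is that magnitude screen plus raw $p <$ 0.05 — raw by
design, matching practice in small-n designs where the downstream
integration provides the real specificity; `alpha` and `lfc` are
configurable. The suite checks type-I calibration on Poisson data
(within [0.03, 0.07] at nominal 0.05), ≥ 80% power for 4-fold changes at
these settings, and rank agreement with edgeR where available.

## Pattern classification and integration

`classify_meth_pattern()` demands $\Delta\beta_1 \ge$ 10 pp with
$q_1 <$ 0.01 and the opposite-signed, equally strong change in contrast
2 (mirrored for hypo/hyper). `classify_expr_pattern()` demands
significant ($p <$ 0.05) opposite-signed fold changes in the two
contrasts. Its default magnitude threshold is `min_fc = 1` — direction
plus significance, with no fold-change floor. This is intentional: in
published candidate tables of this design, several accepted restoration
genes carry |fc| below 2 in one contrast, so the two-fold DEG screen is
evidently a genome-wide screening device, not part of the pattern
definition; passing `min_fc = 2` restores the stricter behaviour.

Integration operates at (DMR, transcript)-link granularity — the same
granularity as a published candidate table, where one gene may appear
with several overlapping windows or transcript isoforms. For each link
with a valid A/B pairing, the per-sample window beta (pooled ratio per
sample, no depth filter) is correlated with the transcript's per-sample
CPM, min-max scaled to [0, 1], across **all** samples of all three
groups jointly — using every sample maximises rank resolution with only
10 observations. The correlation is Spearman's rank correlation
(average ranks for ties), and records require $\rho < 0$ strictly; a
configurable `rho_max` allows stricter cutoffs. A constant vector
min-max scales to all 0.5, keeping it rank-degenerate: its correlation
is undefined and the pair is excluded rather than fabricated. Gene-level
rollups count a gene as Pattern A if any of its links is Pattern A, over
unique symbols.

## The synthetic-data generator

`simulate_methylome()` / `simulate_counts()` emulate the statistical
structure the pipeline assumes: background per-CpG methylation drawn
from a bimodal mixture (modes near 0.1 and 0.9, as bulk methylomes
show), Poisson read depth (mean 30), beta-binomial methylated counts
with precision 30 (variance roughly double binomial at 30× depth —
moderate, typical replicate overdispersion), and log-normal baseline
expression with NB dispersion 0.1, a standard bulk RNA-seq value.
Planted windows sit on the tiling grid, 10 kb apart, with a window-level
30-pp shift under disease restored under treatment; planted genes' TSS
sit at their window centres and their group means move by a 4-fold
factor opposite in sign to the methylation shift, which couples the
layers and induces the negative cross-sample correlation. The default
scene is 2 chromosomes × 2 Mb at 10 CpGs/kb with 20 Pattern A + 5
Pattern B genes over 500 nulls — about 8000 testable windows per
contrast, sized so the full simulate-and-analyse cycle runs in seconds;
the test suite uses a 2 × 0.3 Mb variant for most unit tests and a 1-Mb
single-chromosome null scene (~2000 windows) for calibration checks.
Everything derives from one integer seed and is bit-reproducible.

What the generator does **not** emulate: read-level artefacts (bisulfite
conversion error, mapping bias, PCR duplicates), CpG clustering into
islands, distance-decaying correlation between neighbouring CpGs,
transcript-length and GC effects on counts, and composition bias between
libraries. Passing the planted-truth recovery tests therefore shows the
pipeline's statistics and bookkeeping are correct under its own model,
not that real tissue data will be as clean; on real data the thresholds
carry the inferential weight.

## Degenerate inputs and tie rules

* A CpG missing from one sample has depth 0 there — it simply fails the
  depth filter; windows whose group depth is zero are skipped with a
  warning.
* `delta_beta = 0` windows have direction `NA`; they can never be DMRs.
* `signed_fold_change()` maps an exact ratio of 1 to +1 (the boundary is
  arbitrary; +1 keeps the magnitude invariant $|fc| \ge 1$).
* Equidistant transcript links are all retained, ordered by id.
* An empty DMR set propagates as empty tables and an empty (header-only)
  BED, never as an error.

## Known limitations

The DE test is a desk-scale NB Wald test, not a reimplementation of a
quantile-adjusted conditional-ML framework; numerical parity with such
tools is a non-goal (rank agreement is tested instead). The window test
models overdispersion with a single pooled factor per contrast, which
under-corrects windows far more variable than average. Enhancer-level
annotation, CpG-island context, q-value methods other than BH, and
covariates beyond group are out of scope.
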