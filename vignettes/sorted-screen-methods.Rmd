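---
title: "Models and methods behind sortscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sortscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
```

`sortscreen` implements the statistical core of a reporter-sorted pooled
CRISPR screening study and its companion assays: gene-level RSA statistics
on guide enrichments, BioID label-free differential abundance with
missingness-aware imputation, per-patient signature-activity scoring with
survival stratification, and genomic interval association statistics.
Every analysis can be exercised end to end on synthetic data with known
ground truth; this vignette explains the models, the parameters that
matter, the numerical conventions, and what the simulations do and do not
demonstrate about real data.

## The sorted-screen generative model

A FACS-sorted screen couples a fluorescent reporter of a transcriptional
activity to genome-wide knockout. The simulator
(`simulate_sort_screen()`) uses the minimal model that supports tail
sorting:

* **Library representation.** Each of the `N` guides infects
  `cells_per_guide` cells on average (default 200, a standard library
  redundancy); cells are assigned to guides by multinomial sampling with
  uniform abundance. An optional log-normal abundance jitter
  (`abundance_sd_log`) is available but off by default, reflecting a
  library verified to be evenly represented.
* **Reporter.** Each cell draws a reporter value
  `Normal(effect(gene), reporter_sd)`. Effects are expressed in
  reporter-SD units, so `reporter_sd` (default 1) is purely a scale
  choice. The reporter's true dynamic range and the sorter's gating noise
  are not modelled — neither is quantitatively known — so sorting is exact
  rank truncation: the bottom and top `sort_fraction` (default 1%) of
  cells by reporter value become the "low" and "high" gates.
* **Sequencing.** Each sample (unsorted, low, high) is an independent
  multinomial draw of `sequencing_depth` reads (default $10^6$) over its
  guide composition, so counts are conserved exactly per sample.
* **Controls.** Guides targeting the reporter construct itself share a
  reserved gene id (`control_gene_id()`) and default to a &minus;5 SD
  effect: silencing the reporter sends those cells to the low gate, which
  is the expected positive-control behaviour.

What this model omits, deliberately: infection dynamics and multiplicity
of infection, PCR amplification bias, sorter spillover, and any
correlation between guides beyond their shared gene effect. Passing
recovery tests therefore demonstrates the statistical machinery, not
robustness to those artefacts.

## Normalization, enrichment, and the RSA statistic

Counts are normalized per sample as $(c_{gs} + 1)/T_s$, with $T_s$ the sum
of raw counts; the pseudocount keeps ratios finite for guides absent from
a gate. The denominator is the raw total (not the pseudocounted one) —
the two differ by a constant factor per sample that cancels in enrichment
ratios. Guide enrichment is the normalized ratio of a sorted gate to the
unsorted pool.

Gene scores use the redundant sgRNA activity (RSA) statistic: rank all $N$
guides by enrichment, most-enriched first, ties assigned the worst
(largest) rank so that pseudocount-induced ties cannot inflate
significance. For a gene whose $n$ guides sit at ranks
$r_1 < \dots < r_n$,

$$p_i = P(X \ge i), \quad X \sim \mathrm{Hypergeom}(N, n, r_i), \qquad
p_{\min} = \min_i p_i .$$

Both directions are computed against the unsorted sample, each from its
own gate's enrichment vector, so a "low-direction hit" is a gene whose
guides are jointly over-represented in the low gate. Optional activity
bounds of the original RSA script are not applied. Hits are called at a
strict `p_min < alpha` with `alpha = 0.01` by default, optionally followed
by `expression_filter()`, which drops hits below 1 RPKM in the screened
line (a loss-of-function hit requires the gene to be expressed).

**A calibration caveat that is easy to miss:** $p_{\min}$ is the minimum
over up to $n$ dependent tail probabilities and carries no correction for
that minimization — this is the classical definition, and it is
anti-conservative. Under pure-permutation null ranks with 1000 genes of 6
guides, the fraction of genes with $p_{\min} < 0.01$ is about 0.04, not
0.01, and the full simulator reproduces this (~0.044 measured by the
acceptance suite over 10 seeds). Screens using RSA at a fixed
$\alpha = 0.01$ implicitly tolerate this inflation; the package reports
the statistic as defined rather than recalibrating it, and the null rate
is surfaced by the test suite so the property is visible rather than
hidden.

## BioID differential abundance

The label-free pipeline (`bioid_differential()`) mirrors standard
proteomics practice for a 3 + 3 comparison of a bait line against a
control line, on log2 LFQ intensities:

1. **Filter** (`filter_protein_groups()`): drop proteins with fewer than
   two observed values in *both* groups.
2. **Missingness labels** (`classify_missingness()`): a missing cell is
   MNAR when its group is missing 2 or 3 of 3 replicates while the other
   group is complete — the signature of intensity-dependent dropout of a
   condition-specific protein. Every other missing cell of a kept protein
   is MAR. Ambiguous patterns such as (2 missing, 1 missing) default to
   MAR; this is the conservative choice because the MNAR imputation
   injects extreme values.
3. **Imputation** (`impute_lfq()`): MNAR cells take the minimum observed
   value of their sample column (MinDet — a left-censored value sits at
   the detection floor); MAR cells take the mean of the `k = 10` nearest
   proteins (Euclidean distance on mutually observed entries, ties broken
   by row order) observed at that sample. `k` is exposed; 10 is the
   conventional default for this family of imputations.
4. **Quantile normalization** (`quantile_normalize()`): columns are forced
   to the vector of row-wise means of sorted columns, with ties resolved
   by row order so that the defining property — identical sorted columns —
   holds to machine precision even after MinDet creates within-column
   ties.
5. **Moderated t** (`moderated_t_test()`): per-protein pooled variance
   $s_g^2$ ($d_g = 4$ df) is shrunk towards an empirical-Bayes prior
   $(d_0, s_0^2)$ fitted by the method of moments on $\log s_g^2$ (the
   classical derivation; `fit_variance_prior()` is exported and its
   `d_0 = \infty` branch uses the arithmetic mean of variances as the
   prior scale). $d_0 = 0$ recovers the ordinary pooled t-test; the
   moderated statistic has $d_0 + d_g$ degrees of freedom.
6. **FDR** (`adjust_fdr()`): Benjamini–Hochberg by default. The original
   analysis chain used a density-based FDR estimator whose exact flavour
   is under-specified; BH is the deterministic standard and other
   `p.adjust` methods are accepted.

Known limitations, all visible in the test suite: MinDet imputation
admits false discoveries on null proteins whose missingness pattern
mimics MNAR (minimum-value imputation fabricates large fold changes with
tiny within-group variance), and the power of a 3 + 3 comparison at a
4-fold effect with replicate SD 1 is intrinsically low — the expected
moderated t is $2/\sqrt{2/3} \approx 2.45$, so only a small minority of
such proteins survive BH at 5% regardless of estimator. Detection becomes
reliable only for stronger effects or when condition-specific censoring
carries the signal.

The LFQ simulator (`simulate_lfq_experiment()`) draws per-protein
baselines `Normal(25, 3)` on the log2 scale with replicate SD 1 (typical
LFQ magnitudes), applies the bait-group shift to a chosen fraction of
proteins, then censors: cells below a chosen quantile of the true
intensities drop out with probability 0.9 (MNAR), and surviving cells
drop out uniformly at `mar_rate` (MAR). Applying the mechanisms in that
order guarantees each missing cell has exactly one generating label,
which is what makes label-recovery tests well-posed.

## Signature activity and survival

`signature_scores()` implements single-sample scoring in the GSEA family:
each gene is z-scored across the cohort, genes are ranked within the
sample by descending z (ties by gene order), and the signed
Kolmogorov–Smirnov statistic of the set's ranks against uniformity is
returned,

$$D^+ = \max_i\left(\tfrac{i}{m} - \tfrac{r_i - 1}{N}\right), \quad
  D^- = \max_i\left(\tfrac{r_i}{N} - \tfrac{i-1}{m}\right), \quad
  D = \begin{cases} D^+ & D^+ \ge D^- \\ -D^- & \text{else.} \end{cases}$$

The z-scoring step makes the score invariant under per-gene affine
rescaling — the invariance that matters across expression platforms — but
*not* under arbitrary monotone transforms of a single sample, because
z-scores mix per-gene location and scale. Setting `zscore = FALSE` ranks
raw values and restores exact monotone-transform invariance at the cost
of letting absolute expression magnitude dominate the ranking. The
activity convention follows the biology: a repressor's activity is the
*negated* score of its repressed gene set, a coactivator's activity is
the score of its induced set (`activity_scores()`).

One practical subtlety the simulations exposed: when the two signature
sets occupy a large fraction of the measured transcriptome, their genes
perturb each other's background rank distribution and the recovered
activity correlation attenuates (at 20% signature density the recovered
Spearman for a planted &minus;0.85 was about &minus;0.76; at a realistic
2.5–5% density, about &minus;0.82, which also reflects that the Spearman
of a bivariate normal with Pearson $\rho$ is $(6/\pi)\arcsin(\rho/2)$,
i.e. &minus;0.84 for $\rho = -0.85$). The cohort fixtures therefore use
signature sets sized at a few percent of the transcriptome, matching the
proportions of a ~500-gene signature in a ~20,000-gene expression matrix.

Survival comparisons stratify a score at the third quartile
(linear-interpolation quantile, type 7; "high" is strictly above Q3) and
compare Kaplan–Meier curves with the log-rank test — the 1-df chi-square
that "chi-square test" denotes for survival curves — via the `survival`
package. The cohort simulator uses exponential survival with per-patient
hazard `baseline_hazard * hazard_ratio_per_sd^activity` and independent
uniform censoring (a censored patient reports a uniform time before their
event); this is the simplest model that supports log-rank power analyses,
and it ignores real-world features such as non-proportional hazards and
informative censoring.

`wilcoxon_rank_sum()` uses exact enumeration when the smaller sample has
at most 8 observations and no ties, and the normal approximation with tie
and continuity corrections otherwise; the two paths agree to within 0.02
at the boundary.

## Genomic interval statistics

All coordinates are 0-based, half-open, throughout. A peak's summit is an
explicit offset when provided and the floored midpoint otherwise. Summit
classification against promoter and enhancer sets uses point containment
with promoter precedence on overlaps. Overlap significance is the
hypergeometric upper tail $P(X \ge k)$ for $k$ of $n$ peaks falling in
$K$ bound regions out of a universe of $N$ — the universe is an explicit
argument because overlap p-values are meaningless without one.
Peak-to-gene assignment takes every gene with a summit within 50 kb of
its TSS, inclusive at the boundary and strand-agnostic. ATAC-style
fragments are partitioned at the 146-bp mononucleosome length (sizes
strictly below are sub-nucleosomal). The interval simulator plants an
exact overlap count by construction, which turns these statistics into
fixtures with known truth.

## Problem sizes and determinism

Every simulator is a pure function of its arguments including `seed`
(verified bit-identical on repeat calls). The test and acceptance runs
use desk-scale versions of the study design: screens of 1000 genes × 6
guides + 3 controls at depth $10^6$ with 200 cells per guide and 1%
gates (single-digit seconds per replicate); LFQ matrices of 2000–2500
proteins; cohorts of 500 patients × 8000 genes with two 200-gene
signatures, plus 100 small cohorts for log-rank power. These sizes keep
the whole suite in a few minutes while leaving every statistic in the
regime where its asymptotics already hold.
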