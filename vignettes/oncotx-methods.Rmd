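---
title: "Methods and design notes for oncotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for oncotx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotx)
```

This vignette explains the statistical procedures oncotx implements, the
assumptions behind them, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical conventions and
design choices made where the methods literature leaves the details open.

## Differential transcript calling

For each transcript, expression values in the case (treatment) and control
groups are compared with Welch's unequal-variances t-test:
$t = (\bar x - \bar y) / \sqrt{s_x^2/n + s_y^2/m}$ with Welch–Satterthwaite
degrees of freedom and a two-sided Student-t p-value; sample variances use
the $n-1$ denominator. The test assumes approximately normal group means;
with 5–6 replicates per arm it is robust but, like any t-test at this size,
not exact (see the calibration note below).

Zeros in transcript-level quantification are meaningful observations, not
missing data: a transcript quantified at zero in every sample of exactly
one group is categorically different from one that is merely low. The
caller therefore partitions transcripts before testing:

* all values zero in both groups → `excluded`;
* all case values zero, some control signal → `switched_off`;
* all control values zero, some case signal → `switched_on`;
* otherwise → `tested`, with Welch results attached.

"Measurable expression in both groups" is interpreted at group level
(group mean > 0, equivalently not all-zero), consistent with the group-zero
convention of the switched labels. A tested transcript is a DET when its
nominal p-value is below α (default 0.05, no multiple-testing correction by
default — the workflow this implements filters on nominal p; Benjamini–
Hochberg adjustment is available via `p_adjust = "BH"`). Up/down calls use
the sign of `mean_case − mean_control`; the reported log2 fold change uses
a pseudo-count (default 0.01) on both group means because zeros are common
on the TPM scale.

Degenerate transcripts (zero variance in both groups) follow a fixed
convention instead of being dropped: equal means give $(t=0,\ p=1)$,
unequal means give $(t=\pm\infty,\ p=0)$ with a `degenerate` flag.

### Type-I calibration

Welch's test is slightly conservative at these group sizes: on a Gaussian
null with $n = 6$ vs $m = 5$ its measured two-sided size is ≈ 0.046 rather
than 0.050, and skewed multiplicative (log-normal) noise lowers the null
rejection rate further, to ≈ 0.041 under the generator's default dispersion
of 0.3. The package's calibration checks therefore pool several independent
simulations (200,000 tested null transcripts in total) so that the measured
rate reflects this true calibration rather than Monte-Carlo noise.

## Sample correlation and classical MDS

`sample_correlation_matrix()` computes Pearson or Spearman correlations
between sample columns, optionally restricted to transcripts with Welch
p ≤ α between two design groups — the "correlation structure of the
significant transcripts" view. Pearson correlations default to the
log2(v+1) scale; Spearman is rank-based and unaffected by monotone
transforms. `classical_mds()` embeds samples by Torgerson MDS
(eigendecomposition of the double-centred squared-distance matrix) on
Euclidean distances over log2(v+1) values. Because eigenvectors are
sign-ambiguous, each axis is oriented so its largest-magnitude coordinate
is positive, making embeddings reproducible across platforms; coordinates
are centred per axis. Both the log transform and the orientation rule are
package conventions (configurable), chosen because raw-scale distances on
heavy-tailed expression data are dominated by a few highly expressed
transcripts.

## Stage-profile correlation with p-value weights

Given a staged reference compendium — per-stage mean expression profiles
(stages I–IV plus adjacent normal) and, for each stage-vs-normal pair,
per-transcript discrimination p-values $p_i \in (0, 1]$ — each group's
average expression profile is scored against every stage and against the
adjacent normal with a weighted Pearson correlation. Weights are

$$w_i = \frac{|\log_{10} p_i|}{\sum_i |\log_{10} p_i|},$$

so transcripts that discriminate a stage from normal dominate and
uninformative transcripts ($p_i$ near 1) contribute almost nothing. Weights
are computed per stage pair, since each pair has its own p-values. They are
scale-free in the sense that replacing all $p_i$ by $p_i^k$ leaves them
unchanged. p-values are clamped below at 1e-300 before the log so weights
stay finite; if all $p_i = 1$ the weights are undefined and the function
errors (or falls back to uniform weights when explicitly requested).

The weighted Pearson correlation is the standard one:
$\mu_w(v) = \sum w_i v_i$,
$\mathrm{cov}_w(x,y) = \sum w_i (x_i - \mu_w(x))(y_i - \mu_w(y))$,
$r = \mathrm{cov}_w(x,y)/\sqrt{\mathrm{cov}_w(x,x)\,\mathrm{cov}_w(y,y)}$.
With uniform weights it reduces exactly to plain Pearson.

The report contains, per metric and stage pair, r(case, stage),
r(control, stage), r(case, normal), r(control, normal), their case-minus-
control deltas, and summary means over stage pairs — both as absolute
differences and as percent of the control correlation. The percent form is
only meaningful when the control correlations are well away from zero.

**Scale choice.** Profiles and reference are correlated on the log2(v+1)
scale by default. This is a deliberate design decision: on the raw
expression scale, the weighted covariance of heavy-tailed profiles is
dominated by the few highest-abundance transcripts, and in simulation the
case-vs-control delta readout then collapses to ≈ 0 in roughly one
realization in ten even when a true shift toward normal was planted. On the
log scale the same readout is positive in every simulated realization with
a wide margin. Log-scale correlation is also the usual convention for
expression-profile comparison. The raw scale remains available via
`log2_transform = FALSE`.

## Pathway activation strength

For a pathway $p$ with genes $n$,
$\mathrm{PAS}_p = \sum_n \mathrm{ARR}_{np}\cdot \mathrm{BTIF}_n\cdot
\lg(\mathrm{CNR}_n)$, with lg = log10 (the OncoFinder convention). The
ingredients:

* **CNR** (case-to-normal ratio): $(\bar x_{case} + \varepsilon)/
  (\bar x_{ctrl} + \varepsilon)$ with pseudo-count ε = 1 on the expression
  scale guarding zero means (configurable).
* **BTIF** (beyond-tolerance-interval flag): 1 when CNR > θ or CNR < 1/θ
  (default θ = 1.5). The tolerance interval is symmetric on the ratio
  scale, so BTIF is invariant under ratio inversion — which in turn makes
  PAS exactly antisymmetric under a case/control swap. The originating
  method describes the flag only as "beyond a tolerance interval"; the
  symmetric fold-change rule is this package's concrete construction.
* **ARR** (activator/repressor role): −1, −0.5, 0, 0.5, 1 from the pathway
  role table.

Pathway genes absent from the expression matrix contribute zero and are
counted per pathway (`n_missing`), so partial coverage is visible rather
than silent. PAS is additive over any partition of a pathway's genes, and
increasing a flagged activator's case mean can never decrease PAS.

An optional permutation test (off by default, as significance procedures
for PAS vary between publications) shuffles sample labels B times and
reports $p = (\#\{|PAS^\ast| \ge |PAS|\} + 1)/(B + 1)$.

## The synthetic-data generator

`simulate_expression()` emulates the statistical shape of a small
treatment/control transcript-level experiment at desk scale (defaults:
2000 transcripts, 6 case vs 5 control samples):

* log-normal baseline abundances (meanlog 2, sdlog 1.5) shared by both
  groups — the skewed, non-negative shape of TPM data;
* a minority of truly shifted transcripts (`frac_de` = 0.05, half up, half
  down, ±1.5 log2 units);
* group-specific structural zeros (`frac_switched` = 0.01, half
  switched-on, half switched-off); the expressed group is guaranteed
  non-zero so planted labels are recoverable by definition;
* multiplicative log-normal noise (sdlog `dispersion` = 0.3 natural-log
  units);
* abundance-dependent dropout, P(zero) = exp(−v/0.5) on the baseline
  scale, giving a zero-inflated low-expression tail;
* TPM rescaling so every column sums to 1e6.

A counts mode Poisson-samples the same cell means at simulated library
depths and emits transcript lengths, for exercising RPKM/TPM normalization.

`simulate_stage_reference()` builds the staged compendium: a normal
profile, stage profiles whose informative transcripts (default 200) shift
progressively (stage index × `sep` log2 units, direction random per
transcript, stage IV farthest), and discrimination p-values from Welch
tests on simulated per-stage replicates (8 per arm, sdlog 0.12). These
replicate parameters were chosen so that informative transcripts get small
enough p-values that the weight vector concentrates most of its mass on
them — the regime the weighting scheme is designed for. With `sep = 0` the
construction is null and p-values are near-uniform. Optionally the normal
profile can be derived from an existing matrix's baseline (`baseline`
argument), modelling the realistic situation where a compendium of the
same tissue shares the global abundance structure of the assayed samples;
the pipeline's a549 preset uses this.

`simulate_case_blend()` creates the "treatment moves expression toward
normal" scenario by replacing case columns with a convex combination
(default blend 0.3) of their values and the reference normal profile. Note
that blending overwrites case-group structural zeros, so it should be
viewed as defining a new scenario rather than augmenting an existing one.

`simulate_pathways()` plants known pathway activation: disjoint gene sets
with mixed roles; in an activated pathway, activator genes are up-shifted
and repressor genes down-shifted in the case group (default 1.5 log2
units), and conversely for repressed pathways — so the true PAS sign is
forced by construction.

**What the generator does not emulate:** read-level artifacts (alignment
ambiguity, positional bias), transcript-length effects in TPM mode,
between-transcript correlation beyond the shared per-sample scaling,
isoform structure within genes, batch effects, and real compendium
heterogeneity (mixed source datasets and metrics). Passing tests on this
generator therefore validate the algebra, conventions and statistical
behaviour of the procedures, not their performance on any real dataset.

## Determinism and problem sizes

Every stochastic function takes an explicit integer seed; the pipeline
derives per-stage child seeds deterministically from one master seed, and
two runs with the same configuration produce byte-identical output files
(no timestamps are written). Validation problem sizes — 2000-transcript
simulations at the study-like 6 vs 5 design, 20 replicate seeds for
recovery/directional checks, and 200,000 pooled null transcripts for
calibration — were chosen as the smallest scales at which the measured
quantities are stable to well within the tolerances being checked.

## Known limitations

* The nominal-p DET filter makes no false-discovery guarantee; with ~2000
  tested transcripts it admits ~5% of nulls by design. Use `p_adjust="BH"`
  when an FDR-controlled list is wanted.
* Weighted correlation against a reference requires a shared transcript
  universe; the report refuses to run below 100 shared transcripts
  (configurable) rather than silently correlating a handful of values.
* The BTIF rule and the CNR pseudo-count are conventions; PAS magnitudes
  are comparable within one configuration, not across θ/ε choices.
* TPM values are not re-scaled after subsetting to a shared universe, so
  subsetted columns no longer sum to 1e6; correlation-based analyses are
  scale-free and unaffected.
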