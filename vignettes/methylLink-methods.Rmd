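---
title: "methylLink: models, parameters, and design choices"
author: "methylLink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylLink: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methylLink)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
their defaults, what the synthetic-data generators emulate (and what they
do not), and the numerical and design choices made where the methodology
left room. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Scales: β and M

Array methylation is quantified as β = M/(U+M), the methylated fraction
of signal, bounded in [0,1] and typically bimodal (most probes sit near
fully unmethylated ~0.1 or fully methylated ~0.85). β violates the
homoscedasticity assumptions of linear models near its boundaries, so all
testing is done on M-values, M = log2(β/(1−β)), which are unbounded and
approximately Gaussian per probe. `betaToM()` clamps β to
[ε, 1−ε] with ε = 1e−6 (default, configurable in (0, 0.01]) before the
logit: the transform is then finite everywhere, strictly increasing, and
`mToBeta()` inverts it to better than 1e−12 on the interior. The
methylation enrichment *score*, in contrast, is deliberately computed on
the β scale (Score = Σ wβ): it is a weighted mixture of bounded
fractions, which keeps the score comparable across cohorts.

## Preprocessing

`qcFilterSamples()` drops samples whose missing fraction strictly exceeds
0.8 — "more than 80%" is read as `>`, so a sample at exactly the
threshold is kept; the boundary is covered by a test. `imputeKNN()` is
probe-wise: a probe's missing cell is filled with the mean of the k = 10
nearest complete probes (squared distance averaged over shared observed
samples, so probes observed in few common samples are not spuriously
close), clipped to [0,1]. Probe-wise imputation keeps the operation
independent of sample count, matching common methylation practice; the
order QC-then-impute is fixed (the alternative order is not exposed), and
imputation is idempotent by construction. A probe missing in every sample
has no usable neighbours and is an error rather than a guess.

## The moderated paired test

For each probe, within-subject differences d (post − pre, on the M scale)
give a mean logFC and a sample variance s² on n−1 degrees of freedom.
With tens of pairs and hundreds of thousands of probes, per-probe
variances are noisy; we shrink them toward a common prior by the standard
empirical-Bayes device: s² is modelled as s₀²·F(df, d₀), and (d₀, s₀²)
are estimated by method of moments from the mean and variance of
log s² (the trigamma equation is inverted by Newton iteration). The
posterior variance (d₀s₀² + df·s²)/(d₀ + df) feeds a t statistic on
d₀ + df degrees of freedom. Zero-variance probes remain finite because
the prior contributes. The test suite cross-checks this implementation
against `limma::eBayes` — same moment method, agreement to numerical
precision — and a plain paired-t mode (`moderated = FALSE`) exists for
oracle testing.

Significance requires both p_adj < α (BH, default 0.05) and
|logFC| ≥ 0.1. The logFC threshold applies to the M-scale mean
difference, consistent with the convention of the array-analysis tools
this mirrors; the β-scale difference is reported alongside but never
thresholded. Direction is "hyper" when the post (weight-loss) group is
higher — the group2-minus-group1 convention with group2 = post.

Conservation between cohorts is the Jaccard index of significant probe
sets, computed after the gene-direction concordance filter (a gene with
simultaneous hyper- and hypomethylated significant probes drops all its
probes; intergenic probes always pass). Whether conservation should be
measured before or after that filter, and on probes or genes, is
genuinely ambiguous; we fixed probes-after-filtering and do not treat any
published conservation value as a benchmark.

## Probe reliability

`iccOneway()` is the one-way random-effects ICC(1): with balanced k
measurements per subject, ICC = (MSB − MSW)/(MSB + (k−1)·MSW). The
variant choice (subject as the random grouping factor, k = 2 for a
reference-tissue/other-tissue pair) matches the paired-tissue design the
filter is used in; negative estimates (down to −1/(k−1)) are reported as
computed, not clamped — the 0.4 pass threshold is unaffected.
`iccFilter()` requires ICC > 0.4 in *all* evaluated tissue pairs by
default (strict cross-tissue conservation); `minPassFraction` relaxes
this. Tissue pairs with fewer than two complete subjects are skipped with
a warning rather than silently.

Reliability is evaluated on the M scale in the package's own pipeline:
ICC is invariant to affine transforms but not to the nonlinear logit, so
the scale must simply be fixed and stated. The change rate
|β_c − β_r|/base × 100% uses the control as base by default
(`baseFrom`); it is deliberately asymmetric, a zero base leaves it
undefined (flagged NA — these are the unstable low-β probes), and ties in
the per-probe ranking break lexicographically by probe id so output is
deterministic.

## The elastic-net score

Weights minimise
½·Σᵢvᵢ(yᵢ − xᵢᵀw)² + λ₁‖w‖₁ + (λ₂/2)·wᵀLw,
with L a probe-graph Laplacian (D − A over probes sharing a gene, or
within 1 kb on the same chromosome). The Laplacian penalty is the reason
for the "generalized" elastic net: it pulls graph-adjacent probes toward
similar but not identical weights instead of pushing them independently
to zero, and for exactly duplicated features yields exactly equal weights
(a tested property).

Two modes exist because the training response for a published signature
of this kind is typically under-specified:

* **one-class** (default): squared loss against the all-ones target on
  the training class (the post-surgery samples). The fitted weights then
  describe that class's methylation profile, and scores rank new samples
  by resemblance to it.
* **regression**: an explicit per-sample response.

The choice is a configuration field, not a baked-in guess. Training
cohorts can be pooled with `cohortSampleWeights()`, which gives each
cohort equal total loss weight regardless of size. Scores are optionally
min-max normalised to [0,1] over the training set and clipped on new
data; the normalisation constants live in the `ScoreModel` and survive
serialization bit-exactly.

**Numerics.** The solver is cyclic coordinate descent with soft
thresholding, run in covariance (Gram) form so a sweep costs O(k²)
regardless of sample count. The objective is non-increasing by
construction (the per-sweep trace is attached to every fit and asserted
in tests). Convergence is declared when the exact KKT subgradient
violation falls below `kktTol` (default 1e−9) or the largest coordinate
update falls below `tol` (1e−10); non-convergence within 1e5 sweeps is an
error with diagnostics, never a silent partial result. `verifyKKT()`
re-checks any fitted model at tolerance 1e−6. Inside `runPipeline()` the
score fit uses `kktTol = 1e−6`: pipeline-scale probe matrices are highly
collinear (shared subject effects), first-order stagnation sets in well
below the verification tolerance, and 1e−6 is the level at which the
package itself certifies optimality. Defaults λ₁ = 0.01, λ₂ = 1 prefer
the L2/Laplacian side, which compresses weight quantiles rather than
inflating a sparse few; both are exposed everywhere.

## Genetic coupling

The CIN score is, per chromosome, Σ |log2 ratio| × segment length /
chromosome length, summed over chromosomes for the total. The exact
published recipes for CIN vary; length weighting was chosen because it
makes the score additive over disjoint segment sets and exactly invariant
to splitting a segment in two (tested to 1e−12), and alternative
weightings (`count`, `amplitude`) are one argument away rather than
hidden.

Covariate screens use Spearman correlation (tie-corrected, pairwise
deletion of missing covariates, BH across the screened covariates)
because scores, TMB and CIN are not plausibly Gaussian. Per-chromosome
regressions are ordinary least squares of score on each chromosome's CIN
within age subgroups; "over 65 / under 65" leaves 65 itself unassigned,
so the fixed rule is age ≥ 65 → older subgroup, and the boundary is
tested. Degenerate predictors are skipped with an explicit note, and
cohorts are always analysed separately, never pooled.

Mutations are binarized per (sample, gene) over the non-synonymous
variant classes; genes are tested only above 3% cohort mutation rate
(strict >). The rank-sum test enumerates all rank assignments exactly
when both groups have ≤ 8 samples — midranks make this valid under ties,
where the textbook exact distribution is not — and otherwise uses the
normal approximation with tie and continuity correction. A gene is a
"two-hit" gene when its mutation is score-associated (BH p < 0.05) *and*
it carries a significant differential probe.

## Co-methylated blocks

Blocks are grown by a left-to-right scan over position-sorted probes: the
chain extends while the next probe is within 1000 bp (inclusive — the
1001 bp boundary case is tested) *and* the adjacent pair's Spearman ρ
meets the threshold (0.4 and 0.6 are both run in the pipeline, reported
side by side). Chain adjacency — each consecutive pair must pass, not all
pairs — is the documented behaviour of the block-detection convention
this follows; an all-pairs strict mode is available behind `allPairs`.
Constant probes have undefined correlation and always break the chain.
Blocks need ≥ 5 probes. Because Spearman is rank-based, β and M inputs
give identical blocks (asserted by a test). The scan provably equals
brute-force enumeration of maximal satisfying runs, and the test suite
checks that equivalence on hundreds of random instances.

Amplification calls in a region: a gene's log2 ratio is the
overlap-length-weighted mean of the sample's covering segments; a sample
is amplified only if *every* region gene exceeds 0.2 (strict), and a
sample with an uncovered gene is "not callable", reported separately
rather than called negative.

## What the generators emulate — and what they do not

All noise is applied on the logit (M) scale, so β stays in (0,1) and
effects compose additively; planted differential shifts are specified on
the β scale (Δβ = 0.15 by default) and converted. Defaults: 2,000
probes, 16 pre/post pairs with subject effects (SD 1.0 M-units) and
within-pair noise (SD 0.5), 70% of planted DMPs hypermethylated before
surgery (hypo in post), 6 tissues × 20 subjects for the reliability
cohort, 3 control/replicate pairs, and 2 tumor cohorts × 100 samples.
Probe positions mix clustered ~300 bp gaps with occasional >1 kb jumps so
the position-gap boundary is actually exercised. Tumor samples carry a
latent instability level that drives both CNV amplitude (hence CIN) and,
with configurable strength, the signature probes — so score–CIN coupling
is plantable and removable. A 19q12-13.12-like region carries co-gained
genes and a 6-probe co-methylated chain in amplified samples. Replicated
paired cohorts can share a truth table, which is what makes cross-cohort
Jaccard meaningful in simulation.

Deliberately not emulated: EPIC probe-chemistry artifacts (type I/II
bias, dye effects), cell-type composition, batch structure, and realistic
linkage disequilibrium of mutations. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated on data with the
stated structure; they do not certify performance on real arrays, where
those artifacts dominate preprocessing.

Problem sizes in the test suite (500 null replicates at 20 probes × 10
pairs; ICC recovery at 100 subjects × 999 probes; 200 random block
instances; 100-sample tumor cohorts) were chosen as the smallest sizes at
which the Monte-Carlo error of each check is comfortably below its
assertion margin.

## Known limitations

* The ICC filter assumes a balanced paired-tissue design (k = 2);
  unbalanced groups are an error, not a fallback.
* One-class training with a squared loss against a constant target makes
  the weight *signs* meaningful only through the features' location
  relative to the implied reference; the sign-recovery property is
  therefore validated on generators where the planted association is a
  location shift.
* The CIN recipe is a principled reconstruction (length-weighted
  amplitude), not a reproduction of any single published pipeline;
  comparisons across CIN conventions should use the `weighting` options.
* Coordinates are hg19-style throughout; no liftover is performed.
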