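---
title: "Calling the CpG island methylator phenotype across cancers: models and methods"
author: "panCIMP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling the CpG island methylator phenotype across cancers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panCIMP)
```

## The problem

The CpG island methylator phenotype (CIMP) is the concerted hypermethylation
of many promoter CpG islands (CGIs) in a subset of tumors. It has been
described in colorectal, breast, bladder, lung, gastric and other cancers,
but studies differ in technology and in which CGIs they use to define it, so
whether CIMP is one phenomenon across tissues or many tissue-specific ones is
a live question. panCIMP implements one consistent workflow for asking it:
call CIMP per tissue from array-style methylation, compare the defining CGI
sets across tissues against a random-subset null, ask whether gene expression
alone can recover the CIMP classes (separately and jointly across tissues),
and test mutation, survival and clinical associations. A seeded synthetic
generator plants known CIMP structure so every stage can be validated against
ground truth.

## From probes to islands

Array methylation is measured per CpG probe as the beta value
$\beta = M/(M+U)$, the methylated fraction of total signal intensity;
`compute_beta()` implements exactly this ratio, with zero total intensity
yielding a missing value rather than an error. Probes are then averaged per
CGI. A CGI's profile includes, by default, its shore (0–2 kb) and shelf
(2–4 kb) probes alongside the island probes, because flanking-region
methylation tracks island methylation and roughly doubles the usable probe
count; open-sea probes never contribute. The aggregation statistic is the
arithmetic mean of non-missing probe betas — the standard region summary for
450K-style data; no offset constant is added to the denominator. Missingness
is handled at the CGI level by `filter_cgis()`: CGIs missing in more than 30 %
of samples (configurable) are dropped, and remaining holes are imputed with
the CGI's per-cohort mean so that clustering sees complete data. Annotation
coordinates are stored 1-based (manifest convention); BED exports convert to
0-based half-open intervals. Strand is ignored, since CpG methylation is
symmetric.

## Calling CIMP

Per tissue, the *CIMP signature* is the top 5 % most variant CGIs
(unbiased sample variance, $n-1$ denominator; ties at the cutoff are broken
lexicographically by CGI id so selection is deterministic). Samples are then
clustered on the signature CGIs with Ward linkage on Euclidean distances
(`hclust(method = "ward.D2")`, the Ward form consistent with plain Euclidean
input) and the tree is cut into two classes. The class with the higher mean
signature methylation is labelled CIMP-positive — this labelling rule is
asserted on every call, so "positive" always means hypermethylated.
Degenerate inputs fail loudly: a single sample (variance undefined), more
clusters than samples, or a matrix with no methylation variation are errors,
not silent results.

### How many classes?

Whether an intermediate methylation class exists is assessed by Monti-style
consensus clustering. For each candidate $K = 2,\dots,5$, samples are
subsampled without replacement (default 80 % of samples, 100 resamples, no
feature subsampling), clustered, and the consensus matrix records the
fraction of co-clusterings among co-samplings for each sample pair. The area
$A(K)$ under the empirical CDF of the off-diagonal consensus entries
summarizes how binary the consensus is, and
$$\Delta(2) = A(2), \qquad \Delta(K) = \frac{A(K) - A(K-1)}{A(K-1)}\ (K \ge 3)$$
is the relative-increase criterion whose maximum suggests the supported
number of clusters.

Two numerical choices matter here. First, $A(K)$ is computed as the exact
integral over $[0,1]$ of the right-continuous empirical CDF (a step
integral), not a fixed-grid quadrature: on ideal block-structured data the
consensus entries are exactly 0 or 1 and the step integral reproduces the
combinatorial closed form $A(2) = 1 - s$ (with $s$ the within-block pair
fraction) to machine precision, which the test suite asserts at `1e-12`. A
101-point CDF grid is still returned for plotting. Second, pairs never drawn
together are recorded as missing and excluded from the CDF rather than
imputed. Resamples too small to support $K$ clusters are skipped with a
warning; if all resamples are skipped the run errors.

Signature-size sensitivity is quantified by `signature_stability()`, which
re-derives the call for signature fractions 1–10 % and reports the adjusted
Rand index against the 5 % reference call.

## The cross-cancer signature

Per-tissue signatures are intersected exactly (`intersect_signatures()`),
with all pairwise overlap counts. The scale of the observed overlap is judged
against the independence null: if each of $T$ signatures were a uniform
random subset containing a fraction $p$ of $N$ CGIs, the expected full
intersection is $N p^T$ — for five 5 % signatures over 21,176 CGIs,
0.006 CGIs, i.e. essentially zero, so any sizable observed overlap is strong
evidence of a shared epigenetic program. `monte_carlo_overlap()` checks this
analytic value by simulation and additionally reports an exceedance
probability for an observed overlap count (an extension beyond the analytic
expectation; the expectation alone is the headline number).
`pan_cancer_call()` then pools all samples, restricts them to the common
CGIs, and re-runs the two-class call to ask whether CIMP status, not tissue
of origin, drives the pooled clustering.

## Predicting CIMP from expression

Expression features are $\log_2(\mathrm{RPKM}+1)$-transformed and
standardized to zero mean / unit variance per gene *within tissue* —
penalized fits need a common scale, and per-tissue standardization is what
makes pooling cohorts with different expression distributions meaningful.
Genes constant in any tissue are dropped so all tissues share one gene
universe. Three sparse logistic models are provided:

* **lasso** — one tissue at a time: mean logistic loss plus
  $\lambda\lVert\beta\rVert_1$, unpenalized intercept;
* **combined lasso** — one coefficient vector over the pooled samples with
  an unpenalized intercept *per tissue* (absorbing the different CIMP
  prevalences so cohort imbalance cannot masquerade as signal);
* **group lasso** — one coefficient vector per tissue, penalized by
  $\lambda\sqrt{T}\sum_g \lVert\beta_{g\cdot}\rVert_2$ over each gene's
  coefficients across the $T$ tissues, with each tissue's loss weighted
  $1/n_t$. Whole genes are selected or dropped jointly while coefficients
  stay tissue-specific; $\sqrt{T}$ is the standard group weight, and with
  $T=1$ the objective reduces exactly to the lasso.

All three are solved by one monotone FISTA engine (accelerated proximal
gradient with backtracking line search and restart on rejected steps, so the
objective is non-increasing by construction), to a relative objective
tolerance of `1e-7` within 5,000 iterations. The group proximal operator is a
row-wise group soft-threshold, which for singleton groups is exactly the
lasso soft-threshold — one code path backs all penalties. Non-convergence at
the iteration cap warns and flags the fit rather than erroring by default,
because the unpenalized separable case legitimately runs to the cap with
unbounded coefficients while its predictions are already exact; strict
erroring is available via `on_nonconvergence = "error"`. Solutions are
checked in the tests against glmnet on a shared objective scale (the
independent oracle; glmnet is never the implementation).

Accuracy is measured by stratified 3-fold cross-validation repeated 100 times
(`evaluate_cv()`), stratifying by class crossed with tissue for the joint
models. Within each training split the penalty is chosen by an inner 3-fold
CV over 50 log-spaced values from $\lambda_{\max}$ down to
$0.01\,\lambda_{\max}$, taking the minimum held-out deviance (no
one-standard-error rule for accuracy). Because cohorts are imbalanced, the
reference is the majority-class predictor, and significance is a one-sided
one-sample Student $t$ test of the per-repeat accuracies against that
constant baseline — the baseline has no sampling variance of its own, which
forces the one-sample form.

Gene signatures are defined by stability, not by a single fit:
`bootstrap_signature()` fixes the penalty by full-data inner CV, refits on
100 bootstrap resamples (drawn with replacement within tissue; resamples that
lose a class are redrawn, at most 10 times), and keeps genes selected in at
least 50 % of refits, ranked by frequency. For this purpose the penalty
policy defaults to the one-standard-error choice (`lambda_policy = "1se"`,
with a 5-fold inner CV so the standard-error estimate is usable): at the
CV-minimum penalty the lasso family is well known to drag in noise variables
whose spurious correlations survive mild shrinkage, which is harmless for
prediction accuracy but poisons support recovery. The sparser 1se penalty
plus the 50 % bootstrap-frequency filter is the customary stability-selection
remedy, and on planted-signal simulations it is what makes the recovered gene
set match the planted one (mean F1 above 0.8 across seeds, which the
acceptance suite measures); at the CV-minimum penalty the raw selected set
reaches F1 of only ~0.2–0.5 under the same conditions. `evaluate_cv()` keeps
the min-deviance policy, where the extra genes cost nothing.

## Mutations, survival, clinical covariates

Per-gene association with CIMP uses the hypergeometric tail (the one-sided
Fisher test of the 2×2 table). The genome-wide scan tests both directions —
$p = \min(1,\, 2\min(\text{upper},\text{lower}))$ — because depletion in the
positive class is as interpretable as enrichment, and reports the direction;
genes mutated in fewer than 3 samples are untestable and filtered
(configurable). Multiple testing is Benjamini–Hochberg (`p.adjust`, validated
in the tests against a brute-force step-up). Mutation burden per sample is
compared between classes by a two-sided Wilcoxon rank-sum test, chosen for
robustness to the heavy right tail of somatic mutation counts; the candidate
panel IDH1/IDH2/BRAF/KRAS/TET2 (genes with reported CIMP links) gets its own
per-tissue table with absent genes flagged rather than tested.

Survival uses the survival package throughout: Kaplan–Meier product-limit
curves, the log-rank test, and Cox proportional-hazards regression with Efron
tie handling (the better approximation under tied event times; the data do
not say which convention the field's tables used, so the default is the
accurate one). The Cox model defaults to CIMP plus age — which covariates
belong in the adjusted model is genuinely open, so the covariate list is an
argument. Monotone-likelihood degeneracies are detected (unbounded
coefficient) and error with diagnostics. Clinical associations use Welch's
$t$ for numeric covariates (the safer default under unequal variances, with a
pooled-variance toggle) and chi-squared without continuity correction for
categorical ones, flagging tables with expected counts below 1; missing
values are dropped per covariate and entirely missing covariates are reported
untestable.

## What the generator emulates — and what it does not

`simulation_config()` / `simulate_dataset()` generate per-tissue cohorts
with: CGI methylation drawn from a two-mode beta mixture (hypomethylated
Beta(1.5, 10) vs hypermethylated Beta(8, 2), 70 % low mode — the bimodality
characteristic of 450K beta values); a planted CGI set, forced into the low
mode, whose CIMP-positive samples are shifted on the logit scale; probe
values equal to the CGI value plus clipped Gaussian noise (sd 0.03);
expression Gaussian per gene on the log2 scale, exponentiated to RPKM-like
positives, with planted predictive genes shifted by a standardized effect in
CIMP-positive samples; Bernoulli mutations with an odds-ratio bump in
CIMP-positive samples for a planted gene set; and exponential survival
(median 1500 days) with uniform censoring whose horizon is solved numerically
to hit the target censoring fraction. The logit shift for planted CGIs is
likewise solved numerically so that the *expected* beta increase equals
`cimp_shift` exactly — the planted effect is calibrated, not approximate.
All randomness flows from one seed in a fixed stream order (annotation,
planted sets, gene means, then per tissue: labels, methylation, expression,
mutations, clinical), so a configuration reproduces its dataset bit for bit.

Defaults (chosen once as a realistic mid-size study): 3 tissues × 200
samples, CIMP prevalence 0.3, 500 CGIs with 3–8 probes each, 50 planted CGIs
of which 80 % are shared across tissues, `cimp_shift` 0.35, 200 genes with 10
predictive at effect 1.0 SD, background mutation rate 0.02 with 5 genes at
odds ratio 8, survival hazard ratio 1 (no planted survival effect) and 30 %
censoring. `simulate_methylation_clusters()` is the companion generator for
the cluster-number question: it plants $K$ sample groups differing in mean
methylation on a signature fraction of CGIs.

The generator deliberately does *not* model array chemistry (dye bias,
probe-type I/II differences, detection p-values), copy number, tumor purity,
gene–gene correlation, or methylation–expression coupling at the level of
individual gene pairs. Passing tests therefore demonstrate that the
algorithms recover planted structure of the assumed form; they do not
certify performance on real tumors, where effect sizes are smaller,
correlations are pervasive and class boundaries are fuzzier.

## Problem sizes and reproducibility

The test suite and acceptance checks run at deliberate desk scale: recovery
simulations use cohorts of 150–200 samples and feature universes of a few
hundred CGIs/genes, consensus uses 100 resamples, calibration checks use
1,000 null replicates, and the penalized-model recovery runs 10 seeds with
100 bootstraps each — sizes chosen so the full suite completes in a few
minutes while the binomial/Monte-Carlo error bands stay tight enough to be
meaningful. Every stochastic routine accepts a seed, and the pipeline
(`run_pipeline()`) writes a manifest of output files with MD5 hashes;
identical configuration and seed reproduce every hash.

## Known limitations

* The two-class call forces every sample into CIMP-positive or -negative;
  borderline samples get no confidence measure beyond the consensus matrix.
* The Δ(K) criterion compares only contiguous K starting at 2 and, like all
  consensus criteria, can be flattered by strong two-block structure.
* The group-lasso objective uses the standard $\sqrt{T}$ group weight and
  $1/n_t$ loss weighting; other weightings are defensible and would change
  selected-set sizes at a given penalty.
* Monte-Carlo overlap p-values are resolution-limited by the replicate count.
* The pipeline assumes one shared probe annotation across tissues (one array
  design), and survival times are taken as provided, not re-derived from
  dates.
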