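---
title: "methylBMI: model, design choices, and what the simulations do and do not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylBMI: model, design choices, and what the simulations do and do not show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The DM-BMI model

methylBMI predicts body mass index from CpG methylation beta values
(fractions in [0, 1]) measured on 450K-style arrays. Two ideas carry the
method.

**The trait transformation.** Raw BMI is right-skewed and its clinical
meaning is asymmetric around the healthy range, so BMI is mapped through
a piecewise transform anchored at `healthy_bmi` = 25 kg/m² (the
conventional upper limit of the healthy range): logarithmic below the
anchor, `log(bmi + 1) - log(healthy_bmi + 1)`, and linear above it,
`(bmi - healthy_bmi)/(healthy_bmi + 1)`. Both branches vanish at the
anchor and share the derivative `1/(healthy_bmi + 1)`, so the map is C¹
and strictly increasing; its exact inverse reports predictions back in
kg/m². "log" is the natural log throughout — any base would leave
monotone comparisons unchanged but rescale coefficients, so it is fixed
and documented. The anchor is configurable; 25 is the default and is
stored with the model.

Predicted scores exist on both scales. Comparisons against measured BMI
(Spearman, paired t) are made on the BMI scale, which is where a paired
t-test against observed BMI is meaningful; `predict()` exposes
`scale = "transformed"` for the linear-score scale.

**The sparse fit.** The transformed trait is regressed on probe betas
with a lasso penalty (glmnet, α = 1). The penalty path is built
explicitly: 100 log-spaced values from λ_max — the smallest penalty that
zeroes every coefficient, computed on features standardized with the 1/n
variance convention — down to 10⁻³·λ_max. Passing the grid explicitly
matters: the fitter's default path stops early once deviance gains are
tiny, and on near-noiseless data that truncation prevents the small-λ
end from ever being reached, leaving avoidable shrinkage bias. The
selected penalty minimises the mean 10-fold cross-validated squared
error (the `lambda.min` rule); exact ties resolve toward the larger,
sparser penalty. Fold assignment is drawn once from a recorded seed, so
a fit is bit-reproducible from (data, seed). The model is refit on the
full data at the selected penalty and only nonzero coefficients are
kept, on the original beta scale.

`lambda.min` is the accuracy-oriented rule; it is known to overfit a
minority of CV curves, so on data with no signal the selected support is
*mostly* but not *always* empty. The test suite asserts exactly that
(median support ≤ 2 over seeds), not a per-seed guarantee.

## Preprocessing

The QC chain mirrors the standard methylation workflow at the level of
rules, not of specific published algorithms:

- **Missingness filter**: a probe is removed when missing in strictly
  more than 50% of samples (`> 0.5`, so exactly half survives), plus all
  X/Y probes and SNP-flagged probes. The SNP flag is taken from the
  annotation input; no manifest version is assumed.
- **knn imputation** (`k = 10` default): neighbours are probes
  (row-space), distance is Euclidean over co-observed samples, ties
  break by probe order, and a missing entry becomes the mean of the k
  nearest probes observed at that sample. The methylation toolchain
  inherits this convention from expression imputation; neither k nor the
  neighbour space is standardized, so both are explicit, documented
  defaults. Observed entries are never altered.
- **Batch adjustment** is per-probe, per-batch mean-centring to the
  probe's grand mean, clipped to [0, 1]. This provably removes the
  additive batch shifts the simulator generates and is deliberately not
  an empirical-Bayes batch correction: variance shrinkage and
  probe-type (type I/II) normalization are published third-party
  algorithms, out of scope here, and the simulator does not emulate
  probe chemistry. On real data users should expect to substitute their
  preferred batch/probe-type correction upstream.

## Adipose deconvolution

Breast tissue is modelled as a two-component epithelial/adipose mixture.
Basis probes are those with |β_adipose − β_epithelial| strictly greater
than 0.7 between the two reference methylomes. With exactly two
references, the constrained least-squares mixture fraction has the 1-D
closed form `f* = Σ(β_s − β_e)(β_a − β_e) / Σ(β_a − β_e)²`, clipped to
[0, 1]; the closed form *is* the exact solution, so no iterative
machinery is used. Clipping (rather than rejecting out-of-simplex
solutions) matches the projection behaviour of constrained estimators
and keeps fractions biological. Residual RMSE is reported at the clipped
fraction. Label symmetry (swapping references maps f to 1 − f) and
basis-order invariance are tested properties.

## Characterization and scores

Predictor CpGs are summarised over chromosome, gene-region group and
CpG-island relation with zero-count categories reported explicitly.
Differential methylation between paired tumor/adjacent tissues uses an
exact paired t-test with Benjamini–Hochberg adjustment — a deliberate,
self-contained replacement for moderated-statistics DMP callers, chosen
because it is closed-form-testable. When a probe's paired differences
have zero variance, t is 0 with p = 1 if the mean difference is also
zero, and flagged undefined otherwise; the same convention applies in
`evaluate_predictions()`.

Correlation screens use Spearman correlation with average ranks and the
asymptotic p-value (clamped away from exact zero so p stays in (0, 1]).
The "correlated" flag is strict: |r| > 0.3. For methylation–expression
correlation the negative-association flag uses the raw p < 0.05
alongside r < 0, and BH q-values over the tested family are reported in
the same table so stricter readers can re-threshold; the flag-level
choice follows the per-probe contract rather than family-wise
adjustment, and the output carries both.

TMB is non-synonymous mutation count divided by 38 Mb of exome. The
IFN-γ signature (6 genes) and the antigen-presentation (APM) set
(18 genes) ship built in; both are scored as the unweighted mean of the
present signature genes — for APM the source defines only an
"expression status", so the mean was chosen and is labelled in the
score's attributes. The expanded IFN-γ hallmark set is cited-not-listed
upstream, so it is a user-supplied list by design. External tool scores
(immune/stromal estimates, immune-dysfunction and cell-type scores) are
ingested as columns, never recomputed.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is verified. Defaults emulate the
training cohort the method targets: 221 breast-tissue samples, BMI drawn
from a truncated log-normal with median 28.24 kg/m² on (6, 54) (matching
the reported median and range; sdlog 0.25 gives a realistic spread), two
acquisition batches, 42 causal CpGs. `n_probes` defaults to 5000 — large
enough for realistic sparsity, small enough that the full pipeline runs
in seconds; the array-scale 300k-probe problem differs only in size, not
structure.

Each sample's methylome is `f·β_adipose + (1 − f)·β_epithelial` with the
adipose fraction `f` coupled to BMI through correlated normal scores
(`adipose_coupling`, default 0.7; at 1.0 the rank correlation is exactly
1 by construction). Causal probes shift by `effect_scale` (default 0.15
beta-units per transformed-BMI-unit) times F(BMI), on the beta scale —
the model fits betas directly, so effects live there too, with clipping.
Causal probes are assigned *identical* values in both reference
profiles: their BMI signal is thereby orthogonal to tissue composition,
which is both a biologically sensible reading (BMI-associated CpGs
independent of the mixing fraction) and what makes the zero-noise slope
oracle exact — regressing a causal probe's beta on F(BMI) at zero noise
recovers `effect_scale` to machine precision. Batch effects are additive
per-(probe, batch) normal shifts (sd `batch_shift_sd`, default 0.02),
the structure mean-centring provably removes. Gaussian noise (sd 0.05
default) and uniform missingness (2% default) follow, with clipping to
[0, 1] and a guard that no probe or sample ends fully missing.

Expression is generated per annotated gene; genes of promoter probes
(TSS200/TSS1500) decrease linearly in their probe's beta plus noise,
others are independent — the promoter-silencing caricature, enough to
test the negative-correlation screen against ground truth. The built-in
immune-signature genes are appended with expression mildly increasing in
transformed BMI, and mutation counts are Poisson with a rate mildly
increasing in F(BMI), so immune-score associations have a planted
positive sign. Annotation categories are sampled from fixed,
450K-flavoured proportions (autosomes only by default; sex-chromosome
behaviour is tested with hand-built annotations).

**What the simulations do not show.** The generator emulates linear
structure with Gaussian noise — not probe-type chemistry, detection
p-values, spatially correlated CpG blocks, cell-type diversity beyond
two components, or the noise model of real tissues (which the source
material does not state; Gaussian-with-clipping is a configurable
stand-in). Passing tests therefore demonstrate algorithmic correctness
and statistical behaviour under the stated model, not performance on
real arrays.

## Numerical choices and degenerate inputs

- Strict inequalities wherever the rule is worded as "over"/"greater
  than": missingness > 0.5, basis |Δβ| > 0.7, flag |r| > 0.3.
- The inverse transform evaluates its linear branch for y ≥ 0 so the
  anchor returns exactly (the log branch's `exp(log(h+1)) − 1` would
  round); round-trips hold to < 1e-10 over (5, 60).
- knn distance ties break by probe order; a probe with no eligible
  neighbour at a sample falls back to its own observed mean.
- Constant features/probes yield NA statistics with explanatory notes,
  never silent drops; constant responses abort the fit with a
  degenerate-fit error.
- Fractions and betas are clipped, never renormalised.
- The pipeline derives per-stage seeds from the global seed
  (`seed·101 + stage index`, kept under 2³¹) so stages are individually
  reproducible, and writes MD5 checksums of every output into the run
  manifest; rerunning a config reproduces identical checksums.

## Problem sizes used by the test suite

Parameter-recovery suites run at n = 250 samples × 2000 probes with 20
causal CpGs (lasso; 200 train / 50 held out, a 3-point noise ladder
0.10/0.05/0.02), 100 mixtures × 300 probes for deconvolution recovery,
and a 120 × 3000 cohort for the end-to-end determinism run — sizes at
which the full suite completes in well under a minute while leaving the
sparse-recovery problem genuinely high-dimensional (p ≫ causal set).

## Known limitations

- The 42-probe coefficient table of the published model is not shipped;
  the package rebuilds predictors from data rather than applying a
  frozen clock.
- One CV curve with `lambda.min` stands in for ensembles of repeated
  lasso fits; with a fixed fold seed the two coincide in expectation,
  and the equivalence is an assumption, not a theorem.
- Batch handling assumes additive location shifts; dye/probe-type
  effects and variance heterogeneity need external correction.
- Deconvolution is strictly two-component; three or more tissues, or
  reference-free adjustment, are out of scope.
- External immune scores are ingested, never reimplemented, so their
  provenance and normalisation are the user's responsibility.
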