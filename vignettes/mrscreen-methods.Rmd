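---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Two-sample Mendelian randomization (MR) asks whether an exposure (here,
the motivating use case is a blood metabolite) causally affects an outcome
(a disease such as oral cancer), using only GWAS summary statistics from
two non-overlapping cohorts. Genetic variants serve as instrumental
variables: under the three IV assumptions — relevance (the variant is
associated with the exposure), exchangeability (no confounding of the
variant–outcome relation), and exclusion restriction (the variant affects
the outcome only through the exposure) — the ratio of the variant's
outcome effect to its exposure effect estimates the causal effect.
`mrscreen` implements the full screening workflow: instrument selection,
allele harmonization, six estimators, outlier and pleiotropy diagnostics,
directionality checking, and a multi-exposure screen, together with a
synthetic summary-statistic generator so every stage can be validated
against known ground truth without any external data.

## Instrument selection

For each exposure the pipeline applies, in order:

1. **Relevance filter.** Keep SNPs with exposure p-value strictly below
   `exposure_p_threshold` (default `1e-5`, the threshold widely used in
   metabolite MR screens where genome-wide significant hits are scarce;
   boundary values are excluded).
2. **Greedy LD clumping.** Sort by ascending p-value; accept the best SNP;
   remove unaccepted SNPs on the same chromosome within ±`clump_kb`
   (default 500 kb, inclusive) whose r² with an accepted SNP is at or above
   `clump_r2` (default 0.1); repeat. Ties in p-value break by chromosome,
   position, then rsid, so the result is independent of input order. LD
   comes from a user- or simulator-supplied pair table; absent pairs count
   as r² = 0 (no reference-panel computation is attempted, keeping the
   package download-free).
3. **Weak-instrument filter.** Per-SNP variance explained
   R² = 2β²·EAF(1−EAF) / [2β²·EAF(1−EAF) + 2·se(β)²·N·EAF(1−EAF)], which
   algebraically reduces to β²/(β² + se²N) — the EAF factor cancels, and
   the reduced form doubles as the fallback when EAF is missing. Then
   F = (N−k−1)/k · R²/(1−R²) with k = 1 per SNP; SNPs with F < 10 are
   discarded as weak.
4. **Exclusion-restriction screen.** Drop SNPs whose *outcome* p-value is
   below `outcome_p_threshold` (default `1e-5`); SNPs absent from the
   outcome dataset are dropped too (no proxy lookup) and counted
   separately in the audit trail.

An exposure is analyzable only with at least `min_snps` = 3 surviving
instruments. Every stage logs its removal count, so a screen's attrition
is fully auditable.

## Harmonization

Outcome effects are re-expressed per copy of the exposure's effect
allele. Identical allele pairs pass through; swapped pairs negate the
outcome beta and complement its EAF; strand flips (reverse-complement
pairs, possibly swapped) are resolved silently, which is standard
practice when the alleles identify the variant unambiguously. Palindromic
SNPs (A/T, C/G) are removed unconditionally — no allele-frequency rescue
window is applied, because frequency-based strand inference is fragile
exactly where it is needed — and irreconcilable allele sets are removed as
mismatches. Every removal is recorded with its reason.

## Estimators

All ratio-based methods use first-order weights (the Wald-ratio standard
error approximated by `se_y/|beta_x|`, ignoring exposure-side noise);
a second-order option exists for the heterogeneity statistic.

- **Wald ratio** (single SNP): `beta_y/beta_x`, se `|se_y/beta_x|`.
- **IVW**: inverse-variance-weighted mean of Wald ratios, identical to
  zero-intercept WLS of `beta_y` on `beta_x` with weights `1/se_y²` (the
  package tests both forms against each other). Default inference is
  multiplicative random effects: the fixed-effect se is scaled by
  `max(1, sqrt(Q/(k−1)))`, never narrower than fixed. Unbiased when no
  horizontal pleiotropy is present.
- **MR-Egger**: WLS with free intercept after orienting `beta_x ≥ 0`;
  the slope is the causal estimate under InSIDE (instrument strength
  independent of direct effects), the intercept the mean directional
  pleiotropy. Standard errors divide by `min(1, sigma)` so they are never
  narrower than the fixed-effect model; inference uses t with k−2 df.
- **Weighted median**: weighted 50th percentile of the ratios with linear
  interpolation; consistent while valid instruments hold >50% of weight.
- **Weighted / simple mode**: mode of the (weighted) Gaussian-kernel
  density of ratios; bandwidth is `phi` × 0.9 × MAD(r) × k^(−1/5) — a
  normal-reference rule on a robust scale — with `phi` defaulting to 1.
  The density is evaluated at the ratios and refined by golden-section
  search around the best grid point. If the MAD is zero (all ratios
  effectively identical) the estimate falls back to the weight-plurality
  ratio.
- Median and mode standard errors come from a seeded parametric bootstrap
  (default 1000 draws of `beta_x`, `beta_y` from normals at their reported
  SEs); results are bit-reproducible given the seed.

Estimates are reported on the log-odds scale and as odds ratios with 95%
CIs (`exp(beta ± 1.959964·se)`). `estimate_all()` additionally flags
whether all computed slope estimates share the IVW sign.

## Diagnostics

- **Cochran Q** with the same first-order weights the IVW uses (one source
  of truth: it is exactly the statistic that scales the random-effects
  se); p from the upper χ²(k−1) tail.
- **Egger intercept test**: t(k−2) test of the intercept against zero.
- **Leave-one-out**: IVW re-estimated omitting each SNP, flagging sign
  flips and nominal-significance changes at α = 0.05.
- **Funnel data**: ratio vs precision (|beta_x|/se_y) with IVW/Egger
  reference lines; asymmetry suggests directional pleiotropy.
- **MR-PRESSO**: observed residual sum of squares from leave-one-out IVW
  predictions, compared against a parametric null (`n_sim` simulations,
  default 1000); per-SNP outlier p-values are empirical with add-one
  smoothing and Bonferroni adjustment across instruments; a distortion
  test compares the outlier-removed IVW shift against random same-size
  removals. The corrected estimate is reported alongside, never silently
  substituted. The method presumes a majority of valid instruments.
- **Steiger directionality**: total instrument R² on the exposure side
  versus the outcome side; if the outcome side explains more, the assumed
  causal direction is suspect. The p-value is a two-sided z-test on the
  difference of Fisher-transformed correlation magnitudes using the two
  sample sizes; an exact tie reports direction `FALSE` with p = 1 rather
  than erroring.

## Candidate criteria

A screened exposure is a candidate when every enabled criterion passes:
nominal IVW significance (p < 0.05), direction consistency across
methods, Cochran Q p > 0.05, Egger intercept p > 0.05, forward Steiger
direction, and no leave-one-out sign flip. Each criterion records its
own pass/fail so alternative candidate definitions can be replayed from
saved tables. No multiplicity adjustment is applied by default — the
screen reports nominal significance across exposures, which is the
convention in metabolite-wide MR screens — but Benjamini–Hochberg and
Bonferroni columns are available and recommended when the goal is strict
error control rather than candidate generation.

## The synthetic-data generator

`simulate_pair()` draws, for instrument j: MAF `m_j ~ U(0.05, 0.5)`; true
effect `gamma_j` with random sign and magnitude scaled so the instruments
jointly explain `h2_exposure` of the exposure's variance (per-SNP shares
vary by a uniform factor); observed `beta_x ~ N(gamma, se_x²)` with
`se_x = 1/sqrt(2m(1−m)·n_exposure)` — the standard error of a per-allele
effect on a unit-variance trait — and `beta_y ~ N(theta·gamma + alpha,
se_y²)` analogously at the outcome sample size. Binary-outcome effects
are treated as log-odds with normal sampling, the continuous
approximation appropriate to linear-mixed-model GWAS of common disease in
large biobanks. Pleiotropy modes: `balanced` (zero-mean direct effects),
`directional` (mean `pleiotropy_mean` in the exposure-raising allele
frame — defined that way because with random instrument signs a
fixed-sign direct effect would cancel out of both the IVW bias and the
Egger intercept), and `inside_violated` (direct effects proportional to
instrument strength). LD proxies attenuate the parent signal by
`sqrt(proxy_r2)` within 500 kb and are emitted in the LD table;
palindromic and allele-swapped records exercise harmonization; background
null SNPs exercise the p-value filter. Everything is deterministic given
the seed, and panels derive per-exposure seeds from one panel seed.

Defaults are fixed at the motivating study's scale: exposure N = 7,824
(a metabolomics GWAS cohort), outcome N = 372,373 (a biobank
case-control GWAS), 50 instruments explaining 30% of exposure variance.
That heritability share puts mean per-SNP F near 47 — comfortably past
the F ≥ 10 filter and consistent with instruments that reach p < 1e-5 at
N ≈ 7,800 with margin (the p = 1e-5 boundary corresponds to F ≈ 19.5).
Simulated causal effects are kept small (θ ≈ 0.03–0.05 log-odds per SD,
odds ratios of 1.03–1.05) as in real metabolite screens; note that a
large θ combined with a huge outcome GWAS would make the instruments
genome-wide significant for the outcome and the exclusion-restriction
screen would — faithfully — discard them.

What the generator does *not* emulate: realistic LD blocks from reference
panels, population stratification, sample overlap between the two GWAS,
winner's curse in instrument discovery, and non-normal effect
distributions. Passing tests therefore validate the estimators and the
pipeline logic under the stated sampling model, not the full messiness of
real GWAS data.

## Numerical and design choices

- Strict inequalities at both p-value thresholds; boundary SNPs excluded.
- Per-SNP F uses k = 1; the whole-instrument form with k = retained count
  is available through `f_statistic()` directly.
- First-order ratio weights throughout (`se_r ≈ se_y/|beta_x|`); Egger
  uses t(k−2), other methods normal quantiles.
- Empirical p-values (MR-PRESSO global, per-SNP, distortion) use add-one
  smoothing, so they are strictly positive and bounded by 1.
- The IVW finite-sample attenuation from exposure-side noise (a
  regression-dilution factor of roughly F/(F+1), about 2% at the default
  instrument strength) is a property of the first-order estimator, not an
  implementation artifact; the parameter-recovery tests bound the relative
  bias at 5% and check 95% CI coverage within [0.92, 0.97].
- Degenerate inputs are handled explicitly: all-equal exposure effects
  make the Egger design singular (error), a single SNP falls back to the
  Wald ratio, MR-PRESSO below 4 SNPs reports not-computable, zero-MAD
  ratio sets collapse the mode to the plurality value.
- Simulation sizes in the test-suite (e.g. 1000 replicates for IVW type-I
  error, 500 for coverage, 300 for the pleiotropy robustness comparison,
  100/200 for MR-PRESSO detection and calibration, a 50-exposure screen)
  were chosen so binomial Monte-Carlo error is small relative to the
  asserted bands while the whole suite runs in about a minute.

## Known limitations

Single-exposure univariable MR only: no multivariable MR, no
correlated-instrument IVW, no CAUSE/contamination-mixture estimators, no
radial-MR model selection, and no proxy-SNP substitution. The LD table is
taken as given. Palindromic SNPs are always dropped; there is no
frequency-based rescue. These are deliberate scope boundaries, not
oversights.
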