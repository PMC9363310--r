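---
title: "Methods: longitudinal two-sample MR across age epochs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal two-sample MR across age epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epochmr)
```

## The design

`epochmr` estimates the causal effect of a time-varying exposure —
age-standardised childhood BMI, measured at twelve time points from birth
to eight years — on a binary outcome (multiple sclerosis) from GWAS
summary statistics alone. The two-sample design needs only per-SNP
(beta, SE, p) pairs: exposure associations from a longitudinal
child-cohort GWAS, outcome associations from an independent case-control
GWAS. Using all time points from a single cohort keeps the genetic
instruments on one standardised scale and avoids the subtle population
stratification that mixing cohorts across ages would invite.

The three instrumental-variable assumptions are the usual ones: each SNP
is (1) robustly associated with the exposure at its time point, (2)
independent of confounders of the exposure–outcome relation, and (3)
affects the outcome only through the exposure (no horizontal pleiotropy).
Assumption (1) is enforced by the genome-wide significance filter and
checked by F statistics; (3) is untestable but probed by the whole
sensitivity suite (Egger intercept, median/mode estimators, PRESSO,
leave-one-out, Steiger).

### Epochs

Adjacent time points share most of their BMI genetics, so the primary
analysis amalgamates them into four developmental epochs
(`epoch_definitions()`): birth–6 weeks, 3 months–1.5 years, 2–5 years,
7–8 years. Within an epoch a SNP significant at several time points
carries the statistics of its smallest-p time point; ties break by
smaller SE, then by the epoch's time-point order, so amalgamation is
deterministic. The per-time-point secondary analysis feeds the
Mann–Kendall trend test.

## Instrument construction

Per time point: retain associations with p strictly below 5e-8; excise
the MHC (chr6:25–35 Mb, hg19, both ends inclusive — its long-range LD and
dominant MS signals disqualify it); clump greedily against a
user-supplied LD matrix (r² > 0.001 within 10,000 kb of the index SNP,
smallest p wins; ties by smaller SE, then rsID). Clumping against a
reference panel is deliberately out of scope: the interface accepts a
precomputed LD matrix or pre-clumped input instead. SNPs missing from the
LD matrix are an error unless `allow_missing = TRUE`, because silently
treating them as unlinked would inflate the instrument. The packaged SNP
lists are post-selection, so the pipeline skips these stages for them
(`pre_selected = TRUE`).

## Harmonisation

Outcome records are aligned to the exposure effect allele: direct match,
swap (sign flip, EAF complement), strand-complement match, or
complement-and-swap; anything else is excluded as `allele_mismatch`
rather than guessed. Palindromic SNPs (A/T, C/G) cannot be
strand-resolved from alleles alone. The default policy is **strict**
(drop them all): it is the policy that reproduces the published
instrument counts of 7 and 4 from the 8 printed birth and 5 printed
later-childhood rows, whereas a MAF > 0.42 rule would retain the
later-childhood C/G SNP (exposure MAF 0.234). The `maf_threshold` policy
is kept as an option; under it a palindromic SNP with missing frequency
is dropped, since the ambiguity cannot be assessed. Every exclusion is
logged with a reason, and retained + excluded always equals the input
count.

## Estimators and conventions

All estimators act on the per-SNP pairs `(bx_i, by_i)` with outcome
weights `w_i = 1/sy_i^2`.

* **IVW.** Slope of the weighted through-origin regression. Fixed-effect
  SE `sqrt(1/sum(bx^2 w))`; the primary multiplicative-random-effects
  model inflates it by `max(1, sqrt(Q/(n-1)))` — the floor at 1 means
  homogeneous sets fall back to the fixed model rather than gaining
  spurious precision. p two-sided normal. These conventions (residual df
  n−1, normal p) are the ones that reproduce the published per-epoch
  estimates from the packaged records.
* **Egger.** Weighted least squares with intercept after orienting every
  SNP to a positive exposure effect; slope and intercept SEs carry the
  same `max(1, sigma)` inflation, p-values use t(n−2). A two-SNP Egger
  fit is exact; its SEs are reported as `NA` rather than zero.
* **Weighted median and modes.** Wald-ratio weights are inverse
  *second-order* delta-method variances
  `sy^2/bx^2 + by^2 sx^2 / bx^4`; the second-order term matters — with
  first-order weights the published weighted-median values are not
  recovered. The median interpolates the cumulative weight at 1/2; the
  modes maximise a normal-kernel density with the modified Silverman
  bandwidth `0.9 min(sd, mad) n^{-1/5}` scaled by `phi` (default 1). The
  bandwidth convention makes mode point estimates approximate by nature.
  SEs come from a parametric bootstrap (default `n_boot = 1000`,
  seed-controlled, weights held fixed across replicates).
* **MR-PRESSO.** Observed statistic: weighted RSS of each SNP about its
  leave-one-out IVW prediction; null distribution from `n_sim = 10000`
  parametric simulations, p-values with the +1 correction so they are
  never zero. Per-SNP outlier p-values are Bonferroni-adjusted, outliers
  called at adjusted p < 0.05. The outlier-corrected estimate follows the
  original PRESSO convention — plain weighted through-origin regression,
  SE scaled by the residual sigma with *no* floor, p from t(n−1) — which
  differs from the package's IVW convention and is what reproduces the
  published corrected birth-epoch p-value. The distortion test bootstraps
  outlier-free estimates.
* **Steiger.** Variance explained approximated as `z^2/(z^2+N)` per side,
  with the binary outcome's effective `N = 4/(1/cases + 1/controls)`. The
  exact variance-explained formula for a binary trait is not uniquely
  determined; this approximation reproduces the published null filtering
  result at the study sample sizes and is the convention used throughout
  (also by the synthetic generator).
* **Mann–Kendall.** Exact pair-sign score, ties contribute zero, variance
  `n(n-1)(2n+5)/18` without tie correction, continuity-corrected normal
  p. All-equal input returns tau 0, p 1.
* **Scales.** 95% CIs are fixed at ±1.96 SE and odds-ratio columns are
  elementwise exponentials; this reconstruction is what the abstract-level
  OR presentation uses.

### Multivariable MR

The residual method regresses `by` on the secondary-exposure betas first
(no intercept by default — the summary-data convention; an intercept
option exists because the original residual-method description is
ambiguous at summary level, and both are tested), then regresses the
residuals through the origin on `bx` with the IVW-style MRE inflation.
The joint method fits both exposures in one weighted regression. With all
secondary betas zero both collapse to univariable IVW exactly (machine
precision — a test pins this). A |correlation| above 0.95 between primary
and secondary betas attaches a multicollinearity warning; exact
collinearity is an error naming the columns. The instrument-restriction
sensitivity analysis retains SNPs whose secondary-exposure association
has p strictly greater than the cutoff (default 0.05); an empty result is
legitimate and reported, not fatal.

## The synthetic-data generator

`synth_scenario()` defaults encode the study's conditions: exposure GWAS
n = 28,681; outcome 14,802 cases / 26,703 controls; per-SNP exposure
effects N(0, 0.07) — matching the 0.05–0.14 magnitude range of the
published instruments — and EAF uniform on (0.1, 0.9). Standard errors
are analytic, `1/sqrt(2 maf (1-maf) N)`, with the effective case-control
N on the outcome side; observed betas are the true effects plus normal
noise at those SEs. Pleiotropy can be balanced (zero-mean) or directional;
the directional mean acts on the exposure-increasing-allele orientation,
the scale on which the Egger intercept is defined — an unoriented
constant would cancel across allele codings and no estimator could see
it. An `inside_violation` parameter correlates pleiotropic with exposure
effects. Longitudinal scenarios draw per-SNP effect vectors from a
multivariate normal with a user correlation matrix (PSD-checked), with an
optional secondary "adult" trait loading on the final time point, which
is how the mediation signature — univariable signal, null direct effect —
is constructed with known truth.

What the generator does *not* emulate: LD between instrument SNPs
(instruments are post-clumping by construction), individual-level
genotypes, selection effects in the source GWAS, and population
stratification. Passing tests therefore demonstrate correctness of the
estimators and pipeline under the stated sampling model, not robustness
to those real-data features.

## Numerical notes and degenerate inputs

* Single-SNP units fall back to the Wald ratio; two-SNP units support
  IVW only; median/modes need three SNPs, PRESSO four. Units left with no
  instruments are reported as empty ("no SNPs remained"), not errors.
* All stochastic components (bootstraps, PRESSO simulations, the
  generator) take explicit seeds, restore the caller's RNG state, and are
  bit-for-bit reproducible; the pipeline refuses a configuration with
  stochastic components enabled and no seed.
* The p-value/`|beta/se|` consistency check on input warns (never
  rejects) at a factor-of-2 disagreement, and only for p > 1e-12 —
  below that, print rounding of beta and SE alone moves the implied p by
  more than the factor. It is off for the packaged exposure records,
  whose p-values come from conditional-and-joint analysis and
  legitimately differ from marginal beta/SE.
* Greedy clumping and amalgamation tie-breaks (SE, then label order) make
  every selection deterministic; all order-dependence in the estimators
  is removed by sorting (median) or symmetric formulas, and tests pin
  permutation invariance.

## Test problem sizes

The suite exercises the estimators at the scales the design uses in
practice: fixture epochs of 4–18 SNPs; synthetic sets of 30–120 SNPs;
recovery studies of 200 replicates at 50 SNPs; PRESSO null-uniformity at
200 replicates of 1000 simulations; bootstraps of 100–1000 replicates.
These sizes give Monte-Carlo error small enough for the stated bands
while keeping the default run in the low minutes on one CPU.

## Known limitations

* The packaged per-SNP records are transcribed from a published table and
  are print-rounded (some outcome betas to three significant figures).
  Regression-based estimates recomputed from them can therefore differ
  from the originally computed values in roughly the fifth decimal place;
  the package's tests document agreement to ~2e-5 on the affected betas
  and exact agreement at two decimals on every odds-ratio presentation.
* The weighted median (and the modes) are median-consistent, not
  mean-unbiased: under study-scale noise their replicate mean sits
  slightly below a true effect of 0.2 (about −0.017 with balanced
  pleiotropy of SD 0.02, about −0.005 with none, at 50 SNPs). This is a
  property of the estimators under the second-order weighting convention,
  visible in the recovery tests, not an implementation artefact — the
  point estimates match an independent cumulative-scan oracle to 1e-10.
* Significance-based instrument selection induces winner's curse: the
  end-to-end synthetic pipeline test shows mild attenuation of the
  recovered causal effect, as expected for any threshold-selected MR
  design.
* Multivariable MR against real adult-BMI summary statistics requires an
  external GWAS; the package validates the MVMR machinery on synthetic
  data with known truth only. The residual method attenuates when the
  two exposures' genetic effects are strongly correlated — the joint
  method is the more reliable reference in that regime, and both warn or
  fail loudly near collinearity.
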