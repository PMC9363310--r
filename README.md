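# epochmr

Longitudinal two-sample Mendelian randomisation (MR) across age epochs,
built around the question of *when* in childhood body mass index (BMI)
begins to influence multiple sclerosis (MS) risk.

Observationally, higher childhood BMI is associated with later MS, but
confounding and reverse causation make the timing impossible to read off
cohort data. Two-sample MR sidesteps both by using genetic variants as
instruments: per-SNP effects on age-standardised childhood BMI (exposure
GWAS, n up to 28,681 children measured at 12 time points from birth to
8 years) are combined with the same SNPs' effects on MS susceptibility
(case-control GWAS, 14,802 cases / 26,703 controls). Time points are
amalgamated into four epochs — birth–6 weeks, 3 months–1.5 years,
2–5 years, 7–8 years — and a causal log-odds per SD of BMI is estimated
for each, so the age profile of the effect becomes visible.

`epochmr` is aimed at epidemiologists and statistical geneticists who want
this longitudinal design as a reusable, fully testable pipeline: every
stage from summary-statistic file to final report is an exported function,
and a synthetic-data generator with known causal structure makes the whole
pipeline verifiable without access to the source GWAS files.

## The statistics

For harmonised instrument SNPs with exposure effects `bx_i` (SE `sx_i`)
and outcome effects `by_i` (SE `sy_i`):

- **Wald ratio** (single SNP): `by/bx`, SE `sy/|bx|`.
- **IVW** (primary): weighted regression of `by` on `bx` through the
  origin, weights `1/sy^2`; the multiplicative-random-effects SE is the
  fixed-effect SE inflated by `max(1, sqrt(Q/(n-1)))`, where `Q` is
  Cochran's heterogeneity statistic, so over-dispersion widens intervals
  but never narrows them.
- **MR-Egger**: the same regression with a free intercept; a non-zero
  intercept flags directional horizontal pleiotropy, and the slope is a
  pleiotropy-adjusted estimate (p-values on t with n−2 df).
- **Weighted median / modes**: order-based and density-based estimates of
  the per-SNP Wald ratios, consistent under weaker validity assumptions;
  weights are inverse second-order delta-method Wald-ratio variances and
  SEs come from a parametric bootstrap.
- **MR-PRESSO**: a simulation-based residual test for pleiotropy (global
  over-dispersion, per-SNP outliers, outlier-corrected estimate and a
  distortion test).
- **Steiger filtering** removes SNPs explaining more variance in the
  outcome than the exposure (`r^2 = z^2/(z^2+N)` per side, effective
  case-control N); per-SNP instrument strength is `F = (bx/sx)^2`.
- **Multivariable MR**: residual-based and joint weighted-regression
  estimates of the *direct* effect of childhood BMI conditional on each
  SNP's effect on adult BMI — the mediation question.
- **Mann–Kendall trend test** across the per-time-point estimates:
  Kendall score `S`, `tau = S/(n(n-1)/2)`, normal approximation with
  continuity correction.

## Worked example

The 35 published instrument SNP records ship with the package. One epoch,
end to end:

```r
library(epochmr)
fx <- bmi_ms_instruments("infancy")        # 18 SNPs, 3 months-1.5 years
instr <- harmonise(fx$exposure, fx$outcome)
fit <- mr_fit(instr, seed = 1)
summary(fit)
```

```
Two-sample MR fit [infancy]: 18 SNPs
          method n_snp   beta      se    pval    ci_low ci_high    or or_low or_high
         ivw_mre    18 0.1622 0.06285 0.00986  0.039010  0.2854 1.176 1.0400   1.330
           egger    18 0.2593 0.22330 0.26250 -0.178300  0.6970 1.296 0.8367   2.008
 weighted_median    18 0.1794 0.08789 0.04120  0.007163  0.3517 1.197 1.0070   1.421
     simple_mode    18 0.1048 0.14880 0.48140 -0.186900  0.3964 1.110 0.8295   1.486
   weighted_mode    18 0.1964 0.11890 0.09857 -0.036640  0.4294 1.217 0.9640   1.536
Heterogeneity: Q = 14.24 on 17 df, p = 0.65
Egger intercept: -0.006838 (se 0.01508, p = 0.656)
Mean instrument F: 47.0
```

Read: one SD of genetically higher infancy BMI raises the odds of MS by a
factor 1.18 (95% CI 1.04–1.33, p = 0.01, IVW); the sensitivity estimators
point the same way, the Egger intercept shows no directional pleiotropy,
heterogeneity is unremarkable and the instruments are strong (mean F 47).
The full four-epoch run — instrument selection, harmonisation, Steiger
filtering, all estimators, leave-one-out, MR-PRESSO, trend test, report
files — is one call:

```r
fx <- bmi_ms_instruments("all")
report <- run_epoch_analysis(analysis_config(
  exposure = fx$exposure, outcome = fx$outcome, pre_selected = TRUE,
  steiger = list(n_exp = 28681, n_cases = 14802, n_controls = 26703),
  seed = 1, out_dir = "out"))
report
```

For the birth epoch this flags rs11187129 as a PRESSO outlier (global
p < 0.001) and corrects the estimate to −0.06 (p = 0.69) — the null birth
signal survives every sensitivity check, while all later epochs show
positive effects.

Synthetic data with known truth plugs into the same pipeline
(`synth_scenario()`, `simulate_two_sample()`, `simulate_longitudinal()`),
and `inst/scripts/epochmr-cli.R` wraps run/fixture/simulate for shell use.

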