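---
title: "Validating creatinine-based GFR equations in young adults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating creatinine-based GFR equations in young adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfryoung)
```

## The problem

Glomerular filtration rate (GFR) is routinely estimated from serum
creatinine, age and sex. In young adults (18–25 years) the commonly used
equations disagree: creatinine rises through adolescence as muscle mass
accrues while measured GFR stays roughly constant until about age 40, so
equations that model a monotone age decline (CKD-EPI) systematically
overestimate GFR in this age band, while equations built on *rescaled*
creatinine (EKFC, the re-expressed Lund–Malmö Revised) track the transition
smoothly. `gfryoung` implements the three equations, the rescaling (Q-value)
system behind two of them, the standard validation metrics, and a synthetic
cohort generator, so the whole comparison can be run and stress-tested
end-to-end without access to patient-level data.

## The Q-value system

The Q-value is the median serum creatinine of healthy persons of a given
age, sex and population; `SCr/Q` is dimensionless with healthy median 1.
Between ages 2 and 25 the European reference uses sex-specific polynomials

$$\ln Q = b_0 + b_1\,\mathrm{age} + b_2\ln(\mathrm{age}) +
b_3\,\mathrm{age}^2 + b_4\,\mathrm{age}^3 \qquad (Q\ \text{in µmol/L}),$$

which level off at the adult plateaus 0.70 mg/dL (female) / 0.90 mg/dL
(male). Two reading choices deserve note:

* **The log term is the natural logarithm.** Evaluated with base-10 logs the
  male polynomial gives ≈2.5 mg/dL at age 25 — wildly inconsistent with the
  stated plateau — while the natural log gives 0.915 mg/dL. The package uses
  the natural log and carries a regression test pinning this down.
* **Plateau rounding.** The polynomials evaluate to ≈0.706/0.915 mg/dL at
  25 against the rounded plateaus 0.70/0.90, so the built-in European spec
  is continuous at 25 only to within 0.02 mg/dL. That tolerance is asserted,
  not hidden.

For a population with known adult values but no pediatric curve (the
race-free US values, 0.73 F / 0.97 M mg/dL), `q_interpolated()` assumes all
healthy children share the European curve until age 12 and multiplies it by
a factor linear in age, from 1 at age 12 to the ratio
`plateau_new / Q_Europe(25)` at age 25. The denominator is the European
*polynomial value* at 25, not the rounded plateau: with the rounded value
the interpolated curve would miss the new population's plateau by the
rounding error and re-introduce exactly the kind of jump the construction is
meant to avoid. With this anchoring, `Q(12)` equals the European curve and
`Q(25)` equals the population plateau to machine precision. Ages below 2 are
rejected rather than extrapolated; above 25 the plateau applies with no
upper age bound.

## The equations

All three are implemented from their published closed forms and kept in one
auditable constants table:

* **EKFC**: $\mathrm{eGFR} = 107.3\,(SCr/Q)^{-\alpha}\cdot
  0.990^{\max(\mathrm{age}-40,\,0)}$ with $\alpha = 0.322$ for $SCr/Q<1$ and
  $1.132$ otherwise. Continuous at $SCr/Q = 1$, age factor exactly 1 in the
  18–25 band.
* **CKD-EPI 2021 (race-free)**: $142\cdot\min(SCr/\kappa,1)^{\alpha}
  \max(SCr/\kappa,1)^{-1.200}\cdot 0.9938^{\mathrm{age}}\cdot 1.012^{[F]}$,
  $\kappa = 0.7/0.9$, $\alpha = -0.241/-0.302$ (F/M). Ages below 18 are a
  hard error: the equation is adult-only.
* **r-LMR**: the Lund–Malmö Revised equation re-expressed on the rescaled
  scale. We derived the re-expression algebraically from the canonical LMR:
  $SCr/Q$ is mapped back to the native creatinine scale through the European
  adult reference values (61.88 F / 79.56 M µmol/L), giving
  $\mathrm{eGFR} = e^{X - 0.0158\,\mathrm{age} + 0.438\ln(\mathrm{age})}$
  with $X$ linear in creatinine below the native breakpoints (150 F / 180 M
  µmol/L) and log-linear (slope −0.926) above, continuous at the joint. For
  European adults this reproduces LMR exactly; for other populations the Q
  rescaling carries the adjustment. The transcription is frozen in
  regression tests (e.g. 93.554 mL/min/1.73 m² for a man of 22 at
  $SCr/Q = 1$).

`q_mode = "fixed"` replaces the age curve by the adult plateau at every age,
turning the polynomial-vs-fixed-Q contrast into a one-flag switch.

## Validation metrics

Performance against measured GFR (mGFR) is summarized per equation and
stratum by median bias (eGFR − mGFR), the interquartile range of the bias
(imprecision), and P30/P20 (percentage of estimates within ±30%/±20% of
mGFR, boundary inclusive). Method choices where the convention is not fixed:

* **Median-bias CI**: nonparametric bootstrap percentile interval, 2000
  resamples, seeded. No analytic CI for a median is standard; the bootstrap
  interval's coverage is itself property-tested (95% ± 3 points over 500
  simulation replicates at n = 100).
* **Proportion CI**: Wald interval $p \pm 1.96\sqrt{p(100-p)/n}$ clipped to
  [0, 100], which reproduces the printed interval widths of published
  validation tables at these sample sizes (e.g. 65.4% at n = 1892 →
  (63.3; 67.5)); Wilson is available behind a flag.
* **Quantiles**: linear interpolation (R type 7) throughout.
* **Comparison rule**: two equations differ on a metric only when their 95%
  CIs share no point; touching endpoints overlap. No p-values, no
  multiplicity adjustment — deliberately conservative.

## Age trends and agreement

The median bias across age is summarized by median (τ = 0.5) quantile
regression with a degree-4 polynomial. No quantile-regression package is
assumed: the fit minimizes the check loss by iteratively reweighted least
squares on a centred/scaled basis with a Nelder–Mead polish, and is tested
to land within 1e-6 of a fine grid search's best loss on small instances;
degree 0 reduces exactly to the sample median. P30 across age uses a
least-squares cubic B-spline with three free interior knots chosen by
coarse-to-fine search (decile grid, one halved-spacing refinement)
minimizing the residual sum of squares; fitted percentages are clipped to
[0, 100]. Curves store a fit range and a (possibly narrower) evaluation
range and refuse evaluation outside it — trends are typically fitted on a
wide age span but displayed on 18–25.

Bland–Altman summaries report the mean difference and mean ± 1.96·SD limits
of agreement, in absolute (mL/min/1.73 m²) or relative (% of mGFR) form.
Two conventions are decided, not inferred: the x-axis is measured GFR (the
classical mean-of-methods variant sits behind `x_axis = "mean"`), and the
relative difference is a percentage of mGFR (not of the pair mean).

## The synthetic cohort generator

Real validation cohorts of this kind are not publicly deposited, so the
generator emulates their printed profiles: Europe n = 1892 (age 20.7 ± 2.1,
mGFR 89.5 ± 28.9, all non-Black) and USA n = 474 (age 22.2 ± 2.2, mGFR
61.5 ± 35.3, 37 Black), with non-Black (437) and Black (37) sub-profiles.
Ages are truncated normal on [18, 25]; mGFR truncated normal on [5, 250];
age and mGFR are drawn independently; sex defaults to 50/50. Creatinine is
generated by inverting the EKFC closed form at the subject's mGFR and
multiplying by log-normal noise $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ with default σ = 0.15 — about the
creatinine-scale scatter needed to bring P30 into the published 80–95%
range. With σ = 0 the generating equation recovers mGFR exactly, a
known-truth mode used heavily in the tests.

**Calibration of the truncated marginals.** The printed mean/SD pairs
cannot all be read as parameters of the *untruncated* normal: for the US
mGFR profile the lower bound at 5 shifts the truncated mean up by
+4.1 mL/min/1.73 m², and on [18, 25] no truncated normal attains an age SD
of 2.1–2.2 at all (the uniform limit is ≈2.02). The generator therefore
*mean-matches*: it solves (by closed-form truncated-normal moments and root
finding) for the latent mean that makes the truncated distribution's mean
equal the printed mean, keeping the printed SD as the latent SD. Sample
means then converge to the profile means with ordinary CLT behaviour at any
n, while sample SDs run slightly below the printed values (e.g. ≈1.6 vs 2.1
for European age). Sampling is by inverse-CDF restricted to the bounds —
never by clipping, which would pile mass on the bounds and bias the moments.

What the generator does **not** emulate: the real joint distribution of
age, sex and mGFR; inter-cohort heterogeneity; US assay recalibration
error; any non-EKFC data-generating mechanism. Consequently the pipeline's
qualitative reproduction — CKD-EPI's median bias ranking far above EKFC's
and r-LMR's in the young band — is construction-dependent: EKFC is the
generating equation, so its near-zero bias is expected, and the published
effect magnitudes (e.g. a CKD-EPI bias of 17.4 in Europe) are not numeric
targets. What the synthetic runs do demonstrate is that every pipeline
stage — rescaling, equations, metrics, CIs, comparison rule, trends,
stratification — behaves correctly where truth is known, and that the
direction of the young-adult CKD-EPI overestimation follows from the age
structure of the equations themselves.

## Determinism, problem sizes, degenerate inputs

Every random step (cohort draws, creatinine noise, bootstrap) flows from an
explicit seed; the generator derives fixed per-column substreams from one
master seed so adding a column never perturbs the others, and identical
(profile, seed) pairs reproduce cohorts byte-identically. Reports are pure
functions of their config. The analysis scripts and tests run the study at
its printed sizes (1892/474) with 2000 bootstrap resamples; the
property-style suites use smaller sizes (simulation replicates 500,
bootstrap coverage at n = 100 with 800 resamples, spline truth-tracking at
n = 5000) chosen to keep the whole suite in the tens of seconds while
leaving the statistical assertions sharp. Degenerate inputs have defined
behaviour: constant bootstrap samples give a zero-width CI that still
brackets the point estimate; an all-identical P30 indicator returns the
constant curve; empty strata yield n = 0 rows with absent metrics rather
than vanishing; malformed cohort rows are routed to a rejects table with
one reason each.

## Known limitations

* The r-LMR coefficients come from our own re-expression of the canonical
  LMR rather than a published transcription table; the structural contract
  (breakpoint continuity, monotonicity, exact LMR agreement for European
  adults) is what the tests enforce.
* The bootstrap percentile CI for the median is a choice among several
  defensible CI methods; published tables built with rank-based or other
  resampling intervals will differ in the third digit.
* Cystatin C equations, pediatric-only equations (CKiD), race-coefficient
  variants and body-surface-area de-indexing are out of scope.
* BMI strata default to the WHO cut-offs (<18.5 / 18.5–25 / 25–30 / ≥30
  kg/m²); studies using different cut-offs need the strata supplied
  explicitly.
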