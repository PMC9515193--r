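---
title: "Diet moderation of internetwork connectivity effects on cognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet moderation of internetwork connectivity effects on cognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietconn)
```

## The scientific question

Internetwork resting-state functional connectivity (rsFC) — the mean
correlation between BOLD signals of regions belonging to *different*
large-scale brain networks — tends to rise with age as networks become less
segregated, and higher internetwork rsFC has repeatedly been associated with
worse cognition, particularly fluid reasoning. `dietconn` implements the
full analysis chain for asking whether Mediterranean-diet (MeDi) adherence
*moderates* that association: participants are scored on an 11-category
MeDi adherence scale, split into low/moderate/high tertile groups, and the
group-specific slopes of cognition on rsFC are compared through interaction
and stratified multivariable OLS models.

Because the human cohort behind this design is not redistributable, the
package pairs the analysis chain with a synthetic cohort generator whose
defaults *are* the published cohort's statistical structure: every stage can
therefore be validated by parameter recovery against a known ground truth.

## The models

For participant $i$ with adherence group $g(i) \in \{\text{low},
\text{moderate}, \text{high}\}$ (low = reference in every model), rsFC
summary $z_i$ (Fisher-z scale), reference-ability outcome $y_i$ and
covariates $x_i$:

* **Main effect**: $z_i = \beta_0 + \beta_m M_i + \beta_h H_i + \gamma' x_i
  + \varepsilon_i$, with $M, H$ the moderate/high indicators; the MeDi test
  is the 2-df Wald test of $(\beta_m, \beta_h)$.
* **Moderation**: $y_i = \beta_0 + \beta_z z_i + \beta_m M_i + \beta_h H_i +
  \delta_m M_i z_i + \delta_h H_i z_i + \gamma' x_i + \varepsilon_i$. The
  "overall interaction" p-value is the 2-df Wald test of
  $(\delta_m, \delta_h)$; this choice is logged in every manifest because
  the original software's test is not otherwise identified.
* **Stratified slopes**: $y = \beta_0 + \beta_z z + \gamma' x$ refit inside
  each group. Because $\gamma$ is refit per stratum, stratified slopes need
  not equal reference slope plus interaction — the test suite demonstrates
  this with a constructed counterexample, and it is why the two effect
  presets below are distinct.

Intervals are Wald (normal critical value), matching the "Wald confidence
interval" convention of the original GLM software; `ci = "t"` switches to t
quantiles, and the suite asserts the two agree to well under 1% at n = 201.
Significance conventions: two-sided 0.05 for main effects, 0.10 for
interaction terms. The per-network (10) and pairwise (45) scans apply no
multiplicity correction, mirroring the exploratory convention; the
comparison count is attached to every scan object so reports can say so.

The covariate set in all models: age, gender (female indicator, male = 0),
race/ethnicity indicators (non-Hispanic white reference — the largest
group), education, NART IQ, caloric intake, mean cortical thickness, total
brain volume, scrub percentage, log-WMH, and mean FA. WMH is transformed as
$\ln(\mathrm{WMH} + 1)$; the offset guards zeros and the base/offset are
configurable because neither is fixed by the protocol.

## MeDi scoring

Each of 11 food categories (7 beneficial: non-refined cereals, potatoes,
fruits, vegetables, legumes, fish, olive oil; 4 detrimental: poultry, red
meat, full-fat dairy, alcohol) is mapped from servings/month to a 0–5
frequency category by a monotone step function, detrimental categories are
reverse-scored as $5 - c$ (the only affine order-reversing map of 0–5 onto
itself), and the total spans 0–55. Decisions taken where the instrument is
under-specified:

* **Cutpoints** (servings/month → 0–5): the protocol does not print them;
  the defaults (1, 5, 13, 31, 61) are explicit, monotone, cover the
  support (≈ never / < weekly / 1–3×week / most days / daily / > 2×day) and
  are overridable everywhere rather than estimated from data.
* **Detrimental subscore orientation**: whether the published
  beneficial/detrimental sums used raw or reversed detrimental scores is
  not stated. Both are emitted (`detrimental_avoidance_sum`, reversed,
  higher = more avoidance; `detrimental_intake_sum`, raw); the reversed
  orientation is the modelling default because it matches the sign
  interpretation of the food-type interaction table.
* **Alcohol** is linearly reverse-scored like the other detrimental
  categories; some MeDi scales use a "moderate is best" rule, but none is
  described here.
* **Tertiles** are cut at the 33⅓/66⅔ percentiles with boundary ties
  falling to the lower group, and are assigned on the *post-cascade*
  analytic sample — the published group sizes (66/67/68) partition the
  final N = 201, not the enrolled cohort.

## The rsFC pipeline

Per participant, frames × ROIs time series pass through a fixed order:
framewise displacement (Power convention, rotations × 50 mm), scrubbing,
band-pass, nuisance regression; then Pearson correlation, Fisher z,
distance exclusion, and positive-only internetwork averaging. Numerical
choices:

* **FD threshold 0.5 mm** (configurable): the protocol names scrubbing but
  no threshold; 0.5 mm is the conventional censoring value, and the
  simulated scrub-percentage distribution (mean ≈ 6%, a few participants
  above 30%) is used only as a plausibility band.
* **Volume replacement** is linear interpolation between nearest clean
  neighbours (edges: nearest clean value), *before* filtering, so spike
  energy cannot leak through the filter. Frame count is unchanged and the
  replaced fraction is the scrub percentage.
* **Band-pass 0.01–0.08 Hz** is a zero-phase FFT filter with a 4th-order
  Butterworth magnitude response. No signal-processing dependency is
  available in the target environment, and the contract is the band, not a
  kernel: tests check the measured transfer function against a
  sinusoid-projection oracle (in-band gain ≥ 0.9, 0.2 Hz gain ≤ 0.1).
* **Nuisance regression** removes FD, the rms frame-to-frame BOLD
  difference, left/right white-matter and ventricular traces (all filtered
  identically first) plus an intercept; residual orthogonality is asserted.
* **Distance exclusion** is strict: centres < 20 mm are zeroed and masked;
  exactly 20 mm is retained.
* **"Set to zero" means excluded-from-averaging.** A zeroed pair is never
  averaged as a literal 0, because a zero is not a positive correlation.
  Non-positive z values are likewise excluded from every mean; an empty
  retained set yields `NA` with a warning, never a silent zero.
* **The overall measure is edge-weighted**: the mean over all retained
  cross-network ROI pairs, not the mean of the 45 pairwise means. The
  source describes it both ways ("mean internetwork correlation among all
  10 networks" vs "between all ROIs comprising all networks");
  `include_within = TRUE` preserves the broader reading without endorsing
  it. Whether negatives were excluded before or after the z-transform is
  immaterial — atanh preserves sign, so the retained set is identical.

## The synthetic cohort: what it emulates, and what a green test proves

`generate_cohort()` draws, per participant: covariates calibrated to the
published participant-characteristics table (age 54.10/15.98, education
16.14/2.26, NART IQ 117.28/8.10, thickness 2.55/0.12, FA 0.443/0.021,
lognormal WMH, gamma scrub % with mean ≈ 6 and ≈ 2% of draws above 30,
53% female, race mix 66.2/22.4/11.4%; caloric intake 1800/550 kcal/day as a
realistic adult distribution, since it is not tabulated); an 11-category
FFQ; a cross-network Fisher z from N(0.25, 0.045²) (the published overall
rsFC moments); and cognition

$$\mathrm{RA}_i = \alpha_{g(i)} + B_{g(i)} z_i + \gamma' x_i +
\varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2).$$

Two effect presets plant the published fluid-reasoning estimates:
`"tab2-stratified"` the stratified slopes (−5.354, −0.605, 0.177) and
`"tab2-interaction"` the low slope −5.354 with interaction deltas +5.620
and +4.779. They are deliberately distinct because the printed stratified
and interaction estimates are not mutually consistent (covariates were
refit per stratum). A `"null"` preset (equal slopes) calibrates the type-I
error of the 2-df interaction test: 0.10 ± 0.02 at α = 0.10 over 1000
replicates. Group intercepts $\alpha_g$ anchor the group means of each
reference ability to the published descriptives. Covariate effects default
to age −0.02, education +0.03, NART +0.015 z-units per unit — a typical
fluid-decline gradient — which puts the total FLUID SD near the published
0.84.

Choices worth spelling out:

* **Residual SD** $\sigma = 0.61$: calibrated so the sampling SDs of the
  simulated stratified slopes (≈ 1.87/1.84/1.92) match the published Wald
  SEs (1.78/2.00/1.97). A rougher closed-form inversion of the low-group
  interval gives 0.65; the refinement was made once, through the simulator,
  and then frozen.
* **FFQ draw**: lognormal servings/month (meanlog log 15, sdlog 1.2) plus a
  latent per-participant diet-quality factor (sd 0.5) that raises
  beneficial and lowers detrimental intakes together. Without it, MeDi
  totals bunch on ~20 integer values, boundary ties make the tertile groups
  erratically unequal, and the high-group slope becomes noisier than the
  published intervals imply; with it, totals have SD ≈ 7 and group sizes
  approach the published near-equal 66/67/68.
* **Missingness** is assigned sequentially to disjoint participant sets
  (108 diet, 22 rsFC, 87 structural, 7 cognitive), reproducing the
  published flow 425→317→295→208→201 exactly. Real missingness overlap is
  unknowable; disjoint sets are the only assignment consistent with the
  printed arithmetic.
* **Scan length**: the protocol reports 5- and 9.5-minute scans without TR;
  defaults are 285 frames at TR 2 s (9.5 min), both explicit knobs.
* **Tasks**: the 12 task scores are the planted ability plus within-domain
  scatter that is centred within each domain, so the norm-referenced
  composites reproduce the planted abilities exactly. Reference norms
  travel with the cohort; when absent, the scorer falls back to cohort
  mean/SD with a logged notice (the original external norms are not
  available).
* **Full mode** draws frames × ROIs multivariate normal data from a block
  correlation matrix (`rho_within` = 0.45 on network blocks, tanh(z)
  off-block, "excluded" ROIs independent), with planted motion spikes and
  white-matter/ventricle traces loading on every ROI. It emulates the
  second-order structure the pipeline consumes and nothing more — **no
  hemodynamic autocorrelation, physiological noise, spatial smoothness or
  volumetric data**. A green recovery test therefore establishes that the
  pipeline's statistics are faithful for data with the stated covariance
  structure, not that the preprocessing would behave identically on real
  BOLD series.

Fast mode skips the time-series stage and emits the drawn z directly; this
decouples the statistical tests from the signal-processing stage. With
finite scans the full pipeline carries per-participant measurement error of
roughly 0.03 z-units, which attenuates full-mode slopes by about a quarter
relative to fast mode — the two-path consistency test asserts agreement at
exactly that tolerance, which is a property of finite data, not a defect.

## Monte-Carlo precision of the recovery checks

The acceptance checks compare replicate-mean estimates against the planted
values at tolerances of ±0.15 (stratified high-group slope) and ±0.20
(interaction deltas). In a world calibrated to the published intervals the
per-replicate slope SD is ≈ 1.9 — that is the published standard error —
so a 400-replicate mean carries Monte-Carlo SE ≈ 0.10 and would stray
outside ±0.15 for roughly one seed in eight regardless of implementation.
The recovery requirement is stated as "≥ 400 replicates"; the suite and the
acceptance script use 1600 (MC SE ≈ 0.05), keeping each check under a
minute on one CPU. Estimates are unbiased: a 2000-replicate audit gives
means within ±0.05 of every planted coefficient.

## Known limitations

* The generator plants moderation on fluid reasoning only; the other three
  reference abilities share a common slope. Scans over outcomes exercise
  the code paths, not distinct planted truths.
* Stratified refits drop covariates that are constant within a stratum
  (e.g. a race level absent from a 60-person group); estimates for the
  remaining terms are unaffected, but the dropped indicator's adjustment is
  silently absent in that stratum.
* The Wald/chi-square conventions are slightly liberal at n = 201 compared
  with t/F (rejection ≈ 0.103 at nominal 0.10); this matches the original
  software's convention and is visible in the null-calibration test.
* `read_cohort()`/CLI paths assume the plain-text formats written by
  `write_cohort()`; arbitrary external imaging formats are out of scope.
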