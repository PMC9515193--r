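# dietconn

Does a healthy diet buffer cognition against unfavourable patterns of brain
connectivity? `dietconn` implements a complete, tested pipeline for a
moderation analysis at the intersection of nutritional epidemiology and
resting-state fMRI: Mediterranean-diet (MeDi) adherence scoring from
food-frequency questionnaires, reduction of ROI time series to internetwork
Fisher-z connectivity summaries, reference-ability cognitive composites,
sequential exclusion-cascade cohort assembly, and the interaction /
stratified regression family testing whether MeDi group changes the
rsFC→cognition association. It is written for biostatisticians and
cognitive-neuroscience researchers who want the whole chain reproducible
from plain-text inputs, and ships a synthetic cohort generator with planted
effects so every stage is validated by parameter recovery.

## The statistics in brief

* **MeDi score**: 11 food categories mapped from servings/month to 0–5
  frequency categories; the 4 detrimental categories (poultry, red meat,
  full-fat dairy, alcohol) reverse-scored as 5 − c; total 0–55; tertile
  groups low/moderate/high (boundary ties fall low).
* **Internetwork rsFC**: per ROI pair, Pearson r → atanh(r); pairs with
  centres < 20 mm apart excluded; only strictly positive cross-network
  values averaged — overall, per network (10), and per network pair (45).
  Time series are FD-scrubbed (volume replacement), band-pass filtered
  0.01–0.08 Hz (zero-phase), and residualized on FD, BOLD rms-difference,
  white-matter and ventricular traces.
* **Moderation**: for reference ability y, rsFC summary z and group
  indicators M, H (low = reference),
  `y ~ z + M + H + M:z + H:z + covariates`, with Wald 95% CIs, a 2-df Wald
  joint interaction test (two-sided α = 0.10 for interactions, 0.05
  otherwise), plus per-group stratified refits `y ~ z + covariates`.
* **Synthetic cohort**: covariates calibrated to the published cohort
  descriptives; cross-network z ~ N(0.25, 0.045²); cognition
  `RA = α_g + B_g·z + γ'x + ε`; effect presets plant the published
  stratified slopes (−5.354, −0.605, 0.177) or interaction deltas
  (+5.620, +4.779); sequential missingness (108/22/87/7 of 425) reproduces
  the exclusion flow 425→317→295→208→201.

## Worked example

Generate a synthetic cohort under the stratified-effects preset, assemble
the analytic sample, and fit the moderation models:

```r
library(dietconn)

cfg    <- sim_config(effect_preset = "tab2-stratified", seed = 2026)
cohort <- generate_cohort(cfg, fast = TRUE)   # fast = skip time-series stage
medi   <- score_medi(cohort$ffq)
ra     <- score_ra_table(cohort$tasks, cohort$norms)
asm    <- assemble_analytic(cohort$participants, medi, ra)
asm$flow
#>         enrolled       after_diet       after_rsfc after_structural  after_cognitive
#>              425              317              295              208              201

a <- asm$analytic
interaction_model(a, outcome = "FLUID")
#> <dc_model> FLUID ~ ... [interaction:overall_z], n = 201
#>                term        role      B       LL      UL         p
#>         (Intercept)   intercept  2.447  -0.9264  5.8206 0.1550976
#>                rsfc   rsfc_main -7.259 -11.2099 -3.3073 0.0003176
#>       medi_moderate group_dummy -1.791  -3.1342 -0.4476 0.0089733
#>           medi_high group_dummy -1.894  -3.2701 -0.5179 0.0069831
#>  rsfc:medi_moderate interaction  7.355   2.0205 12.6895 0.0068855
#>      rsfc:medi_high interaction  7.372   2.0079 12.7355 0.0070674
#> joint Wald test (2 df): chi2 = 9.559, p = 0.0084

for (g in c("low", "moderate", "high")) {
  t <- model_term(stratified_model(a, "FLUID", group = g), "rsfc")
  cat(sprintf("%-8s B = %6.3f [%.3f, %.3f], p = %.3f\n", g, t$B, t$LL, t$UL, t$p))
}
#> low      B = -6.539 [-11.132, -1.945], p = 0.005
#> moderate B =  1.251 [-2.614, 5.117], p = 0.526
#> high     B =  0.477 [-3.104, 4.059], p = 0.794
```

Reading the output: in this simulated cohort (one random draw, so estimates
scatter around the planted values) higher internetwork connectivity
predicts worse fluid reasoning only in the low-adherence group
(B = −6.5 per Fisher-z unit, p = 0.005), while the moderate- and high-group
slopes are near zero — the planted moderation pattern. The interaction
coefficients (≈ +7.4) say the rsFC slope is that much *less negative* in
the moderate/high groups than in the low group.

`run_pipeline(cfg, out_dir)` runs the whole chain end to end and writes the
analytic table, a long-format model table, Table-1–4 style CSVs, an
interaction figure, the exclusion-flow report and a run manifest (seed,
configuration hash, and every under-specified constant in force). A
command-line front end with subcommands
`simulate | score-medi | connectivity | assemble | analyze | run` is
installed at `inst/cli/dietconn.R`.

## Layout

| Path | Contents |
| --- | --- |
| `R/medi.R` | MeDi frequency categorisation, scoring, tertiles |
| `R/rsfc.R` | FD, scrubbing, band-pass, nuisance regression, Fisher-z matrices, internetwork summaries |
| `R/cognition.R` | task z-scoring and the four reference-ability composites |
| `R/cohort.R` | exclusion cascade, covariate preparation, analytic assembly |
| `R/models.R` | OLS with Wald intervals and the full moderation model family |
| `R/simulate.R`, `R/recovery.R` | synthetic cohort generator and replicated recovery studies |
| `R/pipeline.R`, `inst/cli/` | orchestration, tables/figure, manifest, CLI |
| `vignettes/diet-connectivity-moderation.Rmd` | methods notes: model, calibration, numerical choices, limitations |
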