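# Replicated simulation studies: parameter recovery and type-I error of the
# moderation tests under the effect presets.

#' Run a replicated fast-mode simulation study
#'
#' Generates `n_rep` independent synthetic cohorts under an effect preset
#' (fast mode, default no missingness so the analytic sample equals the
#' cohort), pushes each through the real analysis path (FFQ scoring,
#' reference-ability composites, cascade, tertiles, covariate preparation)
#' and fits the moderation models on the requested outcome. Per-replicate
#' seeds are fanned out from the master seed.
#'
#' @param preset Effect preset name, see [effect_presets()].
#' @param n_rep Number of replicate cohorts (default 400).
#' @param n Cohort size (default 201, the analytic sample size).
#' @param seed Master seed.
#' @param outcome Reference ability to model (default `"FLUID"`).
#' @param fit Which models to fit per replicate: `"both"` (default),
#'   `"interaction"` or `"stratified"`.
#' @param config_args Extra arguments passed to [sim_config()].
#' @return Data frame with one row per replicate: stratified slopes
#'   (`strat_low`, `strat_moderate`, `strat_high`), interaction coefficients
#'   (`int_moderate`, `int_high`) and the 2-df joint interaction p
#'   (`joint_p`); columns not requested are `NA`.
#' @export
replicate_study <- function(preset, n_rep = 400, n = 201, seed = 1L,
                            outcome = "FLUID",
                            fit = c("both", "interaction", "stratified"),
                            config_args = list()) {
  fit <- match.arg(fit)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_rep)
  out <- matrix(
    NA_real_, n_rep, 6,
    dimnames = list(NULL, c(
      "strat_low", "strat_moderate", "strat_high",
      "int_moderate", "int_high", "joint_p"
    ))
  )
  for (r in seq_len(n_rep)) {
    cfg <- do.call(sim_config, c(
      list(
        n_enrolled = n, effect_preset = preset,
        missingness_counts = c(diet = 0, rsfc = 0, structural = 0, cognitive = 0),
        seed = rep_seeds[r]
      ),
      config_args
    ))
    cohort <- generate_cohort(cfg, fast = TRUE)
    medi <- score_medi(cohort$ffq, cfg$cutpoints)
    ra <- score_ra_table(cohort$tasks, cohort$norms)
    analytic <- assemble_analytic(cohort$participants, medi, ra)$analytic
    if (fit != "stratified") {
      m <- interaction_model(analytic, outcome)
      out[r, "int_moderate"] <- model_term(m, "rsfc:medi_moderate")$B
      out[r, "int_high"] <- model_term(m, "rsfc:medi_high")$B
      out[r, "joint_p"] <- m$joint$p
    }
    if (fit != "interaction") {
      for (g in c("low", "moderate", "high")) {
        s <- stratified_model(analytic, outcome, group = g)
        out[r, paste0("strat_", g)] <- model_term(s, "rsfc")$B
      }
    }
  }
  as.data.frame(out)
}
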