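# Sequential exclusion cascade and analytic-table assembly.

MISSING_FLAGS <- c("miss_diet", "miss_rsfc", "miss_structural", "miss_cognitive")

#' Apply the sequential exclusion cascade
#'
#' Drops participants stage by stage in fixed order: missing diet data, then
#' missing rsFC data, then missing structural data, then missing in-scanner
#' cognitive tests. The flow report gives the count after each stage; with
#' disjoint missingness sets the stage decrements equal the flag counts
#' exactly, and in general the total number excluded equals the size of the
#' union of the flagged sets.
#'
#' @param records Data frame with logical columns `miss_diet`, `miss_rsfc`,
#'   `miss_structural`, `miss_cognitive`.
#' @return List with `analytic` (retained rows) and `flow` (named counts:
#'   enrolled and after each stage).
#' @export
exclusion_cascade <- function(records) {
  if (!all(MISSING_FLAGS %in% names(records))) {
    stop("records need flags ", paste(MISSING_FLAGS, collapse = ", "))
  }
  for (f in MISSING_FLAGS) {
    if (anyNA(records[[f]])) stop("missingness flag ", f, " contains NA")
  }
  flow <- c(enrolled = nrow(records))
  cur <- records
  for (f in MISSING_FLAGS) {
    cur <- cur[!cur[[f]], , drop = FALSE]
    flow[sub("miss_", "after_", f)] <- nrow(cur)
  }
  if (nrow(cur) == 0L) warning("exclusion cascade removed every participant")
  list(analytic = cur, flow = flow)
}

#' Model covariate column names
#'
#' The adjustment set used by every model: age, gender (female indicator,
#' male = 0), race/ethnicity indicators (non-Hispanic white reference),
#' education, NART IQ, caloric intake, mean cortical thickness, total brain
#' volume, scrub percentage, log-transformed white-matter-hyperintensity
#' volume, and mean fractional anisotropy.
#'
#' @return Character vector of covariate column names.
#' @export
dc_covariates <- function() {
  c(
    "age", "gender_female", "race_black", "race_other", "education",
    "nart_iq", "kcal", "cortical_thickness", "brain_volume", "scrub_pct",
    "log_wmh", "fa"
  )
}

#' Add model-ready covariate columns
#'
#' WMH volume is log transformed with a +`wmh_offset` guard against zeros
#' (`log_wmh = ln(wmh + 1)` by default); gender becomes a female indicator
#' (male = 0); race/ethnicity becomes two indicators with non-Hispanic white
#' (the largest group) as reference.
#'
#' @param df Data frame with raw columns `wmh`, `gender`, `race` plus the
#'   pass-through covariates.
#' @param wmh_offset Offset inside the log (default 1).
#' @return `df` with `log_wmh`, `gender_female`, `race_black`, `race_other`
#'   added; errors on non-finite covariates.
#' @export
prepare_covariates <- function(df, wmh_offset = 1) {
  need <- c("wmh", "gender", "race")
  if (!all(need %in% names(df))) {
    stop("need raw columns ", paste(need, collapse = ", "))
  }
  if (any(df$wmh < 0, na.rm = TRUE)) stop("WMH volume cannot be negative")
  df$log_wmh <- log(df$wmh + wmh_offset)
  df$gender_female <- as.numeric(df$gender == "female")
  df$race_black <- as.numeric(df$race == "non-Hispanic black")
  df$race_other <- as.numeric(df$race == "other")
  present <- intersect(dc_covariates(), names(df))
  for (v in present) {
    if (any(!is.finite(df[[v]]))) stop("non-finite covariate: ", v)
  }
  df
}

#' Drop high-motion participants (sensitivity analysis)
#'
#' Strict inequality: records with scrub percentage exactly at the cut are
#' retained.
#'
#' @param df Data frame with a `scrub_pct` column.
#' @param scrub_cut Threshold in percent (default 30).
#' @return Filtered data frame.
#' @export
sensitivity_filter <- function(df, scrub_cut = 30) {
  if (!"scrub_pct" %in% names(df)) stop("`df` needs a `scrub_pct` column")
  df[!(df$scrub_pct > scrub_cut), , drop = FALSE]
}

join_on_id <- function(base_ids, tab, cols) {
  tab[match(base_ids, tab$participant_id), cols, drop = FALSE]
}

#' Assemble the analytic table
#'
#' Joins participant covariates, MeDi scores, reference-ability composites
#' and (optionally) connectivity summaries; applies the exclusion cascade;
#' assigns MeDi tertile groups on the post-cascade analytic sample (matching
#' the convention that the printed group sizes partition the final sample);
#' and prepares model covariates.
#'
#' If the participant table lacks explicit `miss_*` flags they are derived
#' from the data: missing/incomplete FFQ, missing rsFC summary, any missing
#' structural covariate, missing cognition.
#'
#' @param participants Participant table (one row per enrolled participant).
#' @param medi Output of [score_medi()].
#' @param ra Output of [score_ra_table()].
#' @param rsfc Optional connectivity summary table
#'   ([summarize_cohort_connectivity()]); when supplied its `overall_z`,
#'   `net_*`, `pair_*` and `scrub_pct` columns override any same-named
#'   participant columns.
#' @return List with `analytic` (model-ready data frame with `medi_group`),
#'   `flow` (cascade report) and `tertile_cuts`.
#' @export
assemble_analytic <- function(participants, medi, ra, rsfc = NULL) {
  ids <- participants$participant_id
  d <- cbind(
    participants,
    join_on_id(ids, medi, c(
      "total", "beneficial_sum",
      "detrimental_avoidance_sum", "detrimental_intake_sum", "diet_missing"
    )),
    join_on_id(ids, ra, c("SPEED", "FLUID", "MEMORY", "VOCAB"))
  )
  if (!is.null(rsfc)) {
    cols <- setdiff(names(rsfc), "participant_id")
    d <- d[, setdiff(names(d), cols), drop = FALSE]
    d <- cbind(d, join_on_id(ids, rsfc, cols))
  }
  if (!all(MISSING_FLAGS %in% names(d))) {
    structural <- c("cortical_thickness", "brain_volume", "wmh", "fa")
    d$miss_diet <- is.na(d$diet_missing) | d$diet_missing
    d$miss_rsfc <- if ("overall_z" %in% names(d)) is.na(d$overall_z) else TRUE
    d$miss_structural <- Reduce(`|`, lapply(
      intersect(structural, names(d)),
      function(v) is.na(d[[v]])
    ))
    d$miss_cognitive <- is.na(d$FLUID) | is.na(d$MEMORY) |
      is.na(d$VOCAB) | is.na(d$SPEED)
  }
  casc <- exclusion_cascade(d)
  analytic <- casc$analytic
  if (nrow(analytic)) {
    analytic <- assign_tertiles(analytic)
    analytic <- prepare_covariates(analytic)
  }
  list(
    analytic = analytic, flow = casc$flow,
    tertile_cuts = attr(analytic, "tertile_cuts")
  )
}
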