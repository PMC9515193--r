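# Reference-ability composites: 12 in-scanner tasks, 3 per domain,
# z-scored against reference norms and averaged.

#' The 12-task reference-ability battery
#'
#' Four cognitive domains (perceptual speed, fluid reasoning, episodic
#' memory, vocabulary), each measured by three tasks.
#'
#' @return Data frame with columns `task` and `domain`
#'   (`SPEED`/`FLUID`/`MEMORY`/`VOCAB`).
#' @export
ra_task_battery <- function() {
  data.frame(
    task = c(
      "digit_symbol", "letter_comparison", "pattern_comparison",
      "paper_folding", "matrix_reasoning", "letter_sets",
      "logical_memory", "word_order", "paired_associates",
      "antonyms", "synonyms", "picture_naming"
    ),
    domain = rep(c("SPEED", "FLUID", "MEMORY", "VOCAB"), each = 3L),
    stringsAsFactors = FALSE
  )
}

#' Z-score a raw task score against reference norms
#'
#' @param raw Raw task score(s).
#' @param ref_mean,ref_sd Reference mean and standard deviation (SD must be
#'   positive).
#' @return `(raw - ref_mean) / ref_sd`.
#' @export
zscore_task <- function(raw, ref_mean, ref_sd) {
  if (any(ref_sd <= 0)) stop("reference SD must be positive")
  (raw - ref_mean) / ref_sd
}

#' Average three task z-scores into a reference-ability score
#'
#' @param z Numeric vector of exactly three task z-scores.
#' @return Their arithmetic mean, or `NA` if any component is missing.
#' @export
composite_ra <- function(z) {
  if (length(z) != 3L) {
    stop("a reference ability averages exactly three task z-scores")
  }
  if (anyNA(z)) return(NA_real_)
  mean(z)
}

#' Score the four reference abilities for a task table
#'
#' Z-scores every task against the supplied reference norms and averages
#' within domain. If no norms are supplied the cohort's own mean/SD per task
#' is used, with a logged notice: that preserves the formula when external
#' reference norms are unavailable, but the resulting composites are only
#' internally standardized.
#'
#' @param tasks Data frame with `participant_id` plus one column per task in
#'   [ra_task_battery()].
#' @param norms Optional data frame with columns `task`, `ref_mean`,
#'   `ref_sd`.
#' @return Data frame with `participant_id`, `SPEED`, `FLUID`, `MEMORY`,
#'   `VOCAB` and a `cognition_missing` flag (any task missing makes the
#'   affected composite, and the flag, missing).
#' @export
score_ra_table <- function(tasks, norms = NULL) {
  battery <- ra_task_battery()
  missing_cols <- setdiff(battery$task, names(tasks))
  if (length(missing_cols)) {
    stop("`tasks` is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- as.matrix(tasks[, battery$task])
  if (is.null(norms)) {
    message("no reference norms supplied; z-scoring against cohort mean/SD")
    norms <- data.frame(
      task = battery$task,
      ref_mean = colMeans(raw, na.rm = TRUE),
      ref_sd = apply(raw, 2, sd, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  i <- match(battery$task, norms$task)
  if (anyNA(i)) stop("`norms` must cover every task in the battery")
  z <- zscore_task(
    raw,
    matrix(norms$ref_mean[i], nrow(raw), 12, byrow = TRUE),
    matrix(norms$ref_sd[i], nrow(raw), 12, byrow = TRUE)
  )
  out <- data.frame(
    participant_id = tasks$participant_id,
    stringsAsFactors = FALSE
  )
  for (d in unique(battery$domain)) {
    out[[d]] <- rowMeans(z[, battery$task[battery$domain == d], drop = FALSE])
  }
  out$cognition_missing <- apply(is.na(raw), 1, any)
  out
}
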