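# MeDi adherence scoring: 11 food categories, 0-5 frequency categories,
# detrimental components reverse-scored, total on 0-55.

MEDI_BENEFICIAL <- c(
  "non-refined cereals", "potatoes", "fruits", "vegetables",
  "legumes", "fish", "olive oil"
)
MEDI_DETRIMENTAL <- c("poultry", "red meat", "full-fat dairy", "alcohol")

#' Fixed MeDi food categories
#'
#' The 11 food categories of the MeDi adherence scale, beneficial components
#' first (non-refined cereals, potatoes, fruits, vegetables, legumes, fish,
#' olive oil) followed by the detrimental components (poultry, red meat,
#' full-fat dairy, alcohol).
#'
#' @param which `"all"`, `"beneficial"` or `"detrimental"`.
#' @return Character vector of category names.
#' @export
medi_categories <- function(which = c("all", "beneficial", "detrimental")) {
  which <- match.arg(which)
  switch(which,
    all = c(MEDI_BENEFICIAL, MEDI_DETRIMENTAL),
    beneficial = MEDI_BENEFICIAL,
    detrimental = MEDI_DETRIMENTAL
  )
}

#' Default servings-per-month cutpoints
#'
#' Thresholds mapping monthly serving counts onto the six frequency
#' categories 0-5. The defaults (1, 5, 13, 31, 61) separate roughly
#' never / less than weekly / 1-3 times a week / most days / daily /
#' more than twice a day; the instrument itself does not fix the bands, so
#' they are explicit and overridable rather than data-dependent.
#'
#' @return Numeric vector of 5 strictly increasing thresholds.
#' @export
medi_default_cutpoints <- function() c(1, 5, 13, 31, 61)

check_cutpoints <- function(cutpoints) {
  if (length(cutpoints) != 5L || !is.numeric(cutpoints) ||
      any(!is.finite(cutpoints)) || any(diff(cutpoints) <= 0)) {
    stop("`cutpoints` must be 5 finite, strictly increasing thresholds")
  }
  invisible(cutpoints)
}

#' Map servings per month to a 0-5 frequency category
#'
#' Monotone step function: the category is the number of cutpoints less than
#' or equal to the intake, so zero intake scores 0 and anything at or above
#' the fifth cutpoint scores 5.
#'
#' @param servings_per_month Non-negative numeric vector.
#' @param cutpoints 5 strictly increasing thresholds
#'   (default [medi_default_cutpoints()]).
#' @return Integer vector of categories in 0-5.
#' @examples
#' categorize_frequency(c(0, 13, 100))
#' @export
categorize_frequency <- function(servings_per_month,
                                 cutpoints = medi_default_cutpoints()) {
  if (!is.numeric(servings_per_month) || any(!is.finite(servings_per_month))) {
    stop("`servings_per_month` must be finite numeric")
  }
  if (any(servings_per_month < 0)) stop("intake cannot be negative")
  check_cutpoints(cutpoints)
  findInterval(servings_per_month, cutpoints)
}

#' Score MeDi adherence from category-level FFQ intakes
#'
#' Converts a long food-frequency table (one record per participant and food
#' category, in servings per month) into per-participant MeDi scores. Each
#' category is mapped to a 0-5 frequency category; the 4 detrimental
#' categories are reverse-scored as `5 - category` so that higher always means
#' more adherent; the total is the sum over all 11 categories (0-55).
#' Beneficial (0-35) and detrimental (0-20) subscores are reported in both
#' orientations: `detrimental_avoidance_sum` uses the reversed scores (higher
#' = more avoidance, the default used downstream) and `detrimental_intake_sum`
#' the raw frequency categories.
#'
#' Participants missing any of the 11 categories are flagged
#' `diet_missing = TRUE` and receive no score (all score fields `NA`).
#'
#' @param ffq Data frame with columns `participant_id`, `category`,
#'   `servings_per_month`.
#' @param cutpoints Passed to [categorize_frequency()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `beneficial_sum`, `detrimental_avoidance_sum`, `detrimental_intake_sum`,
#'   `total`, `diet_missing`. The matrix of per-category 0-5 scores
#'   (detrimental already reversed) is attached as attribute
#'   `"category_scores"`.
#' @export
score_medi <- function(ffq, cutpoints = medi_default_cutpoints()) {
  need <- c("participant_id", "category", "servings_per_month")
  if (!all(need %in% names(ffq))) {
    stop("`ffq` needs columns ", paste(need, collapse = ", "))
  }
  cats <- medi_categories()
  unknown <- setdiff(unique(ffq$category), cats)
  if (length(unknown)) {
    stop("unknown food categories: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(ffq[c("participant_id", "category")])) {
    stop("duplicate participant x category records")
  }
  check_cutpoints(cutpoints)

  ids <- unique(ffq$participant_id)
  serv <- matrix(NA_real_, length(ids), length(cats),
    dimnames = list(NULL, cats)
  )
  serv[cbind(
    match(ffq$participant_id, ids),
    match(ffq$category, cats)
  )] <- ffq$servings_per_month
  complete <- rowSums(is.na(serv)) == 0L

  freq <- matrix(NA_integer_, nrow(serv), ncol(serv), dimnames = dimnames(serv))
  if (any(complete)) {
    freq[complete, ] <- categorize_frequency(serv[complete, ], cutpoints)
  }
  scored <- freq
  scored[, MEDI_DETRIMENTAL] <- 5L - freq[, MEDI_DETRIMENTAL]

  out <- data.frame(
    participant_id = ids,
    beneficial_sum = rowSums(scored[, MEDI_BENEFICIAL, drop = FALSE]),
    detrimental_avoidance_sum = rowSums(scored[, MEDI_DETRIMENTAL, drop = FALSE]),
    detrimental_intake_sum = rowSums(freq[, MEDI_DETRIMENTAL, drop = FALSE]),
    total = rowSums(scored),
    diet_missing = !complete,
    stringsAsFactors = FALSE
  )
  attr(out, "category_scores") <- scored
  out
}

medi_group_from_total <- function(total, cuts) {
  g <- ifelse(total <= cuts[1], "low",
    ifelse(total <= cuts[2], "moderate", "high")
  )
  factor(g, levels = c("low", "moderate", "high"))
}

#' Assign low/moderate/high adherence groups by tertiles
#'
#' Cuts the distribution of total MeDi scores at its 33 1/3 and 66 2/3
#' percentiles. Ties at a boundary fall to the lower group, so with discrete
#' totals the three groups need not be exactly equal in size.
#'
#' @param scores Data frame as returned by [score_medi()] (needs a `total`
#'   column; rows with `NA` totals get `NA` group).
#' @return `scores` with a `medi_group` factor (`low`/`moderate`/`high`)
#'   added; the cutpoints and group sizes are attached as attributes
#'   `"tertile_cuts"` and `"group_sizes"`.
#' @export
assign_tertiles <- function(scores) {
  if (!"total" %in% names(scores)) stop("`scores` needs a `total` column")
  tot <- scores$total
  usable <- !is.na(tot)
  if (sum(usable) < 3L) stop("need at least 3 scored participants")
  if (min(tot[usable]) == max(tot[usable])) {
    stop("degenerate score distribution: all totals identical")
  }
  cuts <- quantile(tot[usable], c(1, 2) / 3, names = FALSE, type = 7)
  scores$medi_group <- medi_group_from_total(tot, cuts)
  attr(scores, "tertile_cuts") <- cuts
  attr(scores, "group_sizes") <- table(scores$medi_group)
  scores
}
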