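# The moderation model family: multivariable OLS with Wald intervals,
# MeDi main effects on rsFC, MeDi-group x rsFC interactions on each
# reference ability, stratified slopes, per-network and pairwise scans,
# continuous food-type interactions, and three-way age/gender interactions.
#
# Significance conventions: two-sided alpha 0.05 for main effects, 0.10 for
# interaction terms. Low MeDi is the reference group in every model.

#' Ordinary least squares with Wald confidence intervals
#'
#' Least-squares fit of `y` on an explicit design matrix (intercept
#' included by the caller). Confidence intervals are Wald by default:
#' `B +/- z_{0.975} * SE` with the normal critical value, matching the GLM
#' convention of "Wald confidence intervals"; `ci = "t"` substitutes the
#' t critical value (the two coincide for all practical purposes at the
#' sample sizes used here). Two-sided p values come from the same statistic.
#'
#' @param y Numeric response.
#' @param X Numeric design matrix, full column rank, `nrow(X) == length(y)`.
#' @param ci `"wald"` (normal, default) or `"t"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `dc_ols` with elements `coefficients`, `se`,
#'   `vcov`, `lower`, `upper`, `p`, `sigma2`, `df_residual`, `n`, `fitted`,
#'   `residuals`, `rss`.
#' @export
fit_ols <- function(y, X, ci = c("wald", "t"), conf_level = 0.95) {
  ci <- match.arg(ci)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(X)) stop("missing values in model inputs")
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design matrix and response disagree on rows")
  if (n <= p) stop("not enough observations for ", p, " coefficients")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  b <- qr.coef(qx, y)
  fitted <- drop(X %*% b)
  res <- y - fitted
  df <- n - p
  rss <- sum(res^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  v <- sigma2 * xtx_inv
  dimnames(v) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(v), 0))
  crit <- if (ci == "wald") {
    qnorm(1 - (1 - conf_level) / 2)
  } else {
    qt(1 - (1 - conf_level) / 2, df)
  }
  stat <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
  pval <- if (ci == "wald") 2 * pnorm(-abs(stat)) else 2 * pt(-abs(stat), df)
  structure(
    list(
      coefficients = setNames(b, colnames(X)), se = setNames(se, colnames(X)),
      vcov = v, lower = b - crit * se, upper = b + crit * se,
      p = setNames(pval, colnames(X)), sigma2 = sigma2, df_residual = df,
      n = n, ci_type = ci, crit = crit, fitted = fitted, residuals = res,
      rss = rss
    ),
    class = "dc_ols"
  )
}

#' Joint Wald test of several coefficients
#'
#' `W = b' V^{-1} b` on the named subset, referred to a chi-squared
#' distribution with as many degrees of freedom as coefficients tested. This
#' is the "overall interaction" test used throughout: a 2-df Wald test of
#' both group-by-rsFC terms.
#'
#' @param fit A `dc_ols` fit.
#' @param terms Character vector of coefficient names.
#' @return List with `stat`, `df`, `p`.
#' @export
wald_joint <- function(fit, terms) {
  idx <- match(terms, names(fit$coefficients))
  if (anyNA(idx)) stop("unknown coefficients: ", paste(terms[is.na(idx)], collapse = ", "))
  b <- fit$coefficients[idx]
  v <- fit$vcov[idx, idx, drop = FALSE]
  w <- tryCatch(drop(t(b) %*% solve(v, b)), error = function(e) {
    # a noiseless fit has a zero covariance block: the test is degenerate
    if (all(abs(b) < 1e-12)) 0 else Inf
  })
  list(stat = w, df = length(idx), p = pchisq(w, length(idx), lower.tail = FALSE))
}

covariate_matrix <- function(analytic, covariates) {
  missing_cols <- setdiff(covariates, names(analytic))
  if (length(missing_cols)) {
    stop("analytic table lacks covariates: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(analytic[, covariates, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

group_dummies <- function(g, reference) {
  g <- factor(g, levels = levels(g))
  if (!reference %in% levels(g)) stop("unknown reference group: ", reference)
  others <- setdiff(levels(g), reference)
  counts <- table(g)
  if (any(counts == 0)) {
    stop("empty MeDi group: ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  list(
    others = others,
    d = vapply(others, function(o) as.numeric(g == o), numeric(length(g)))
  )
}

new_dc_model <- function(outcome, label, fit, roles, joint = NULL) {
  terms <- data.frame(
    term = names(fit$coefficients),
    role = unname(roles[names(fit$coefficients)]),
    B = unname(fit$coefficients),
    LL = unname(fit$lower), UL = unname(fit$upper),
    p = unname(fit$p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      outcome = outcome, label = label, terms = terms, joint = joint,
      n = fit$n, fit = fit
    ),
    class = "dc_model"
  )
}

#' @export
print.dc_model <- function(x, ...) {
  cat(sprintf("<dc_model> %s ~ ... [%s], n = %d\n", x$outcome, x$label, x$n))
  show <- x$terms[x$terms$role != "covariate", ]
  print(format(show, digits = 4), row.names = FALSE)
  if (!is.null(x$joint)) {
    cat(sprintf(
      "joint Wald test (%d df): chi2 = %.3f, p = %.4f\n",
      x$joint$df, x$joint$stat, x$joint$p
    ))
  }
  invisible(x)
}

#' Extract one term's estimate from a model
#'
#' @param model A `dc_model`.
#' @param term Term name, e.g. `"rsfc:medi_moderate"`.
#' @return One-row data frame with `B`, `LL`, `UL`, `p`.
#' @export
model_term <- function(model, term) {
  i <- match(term, model$terms$term)
  if (is.na(i)) stop("no term ", term, " in model")
  model$terms[i, c("B", "LL", "UL", "p")]
}

base_roles <- function(covariates) {
  setNames(rep("covariate", length(covariates)), covariates)
}

#' MeDi main effect on an rsFC summary
#'
#' Regresses the connectivity variable on the two MeDi group indicators
#' (low = reference) plus the full covariate set; the joint 2-df Wald test
#' of the group indicators is the test of any MeDi/rsFC association.
#'
#' @param analytic Analytic table from [assemble_analytic()].
#' @param rsfc_var Connectivity column (default `"overall_z"`).
#' @param covariates Adjustment set (default [dc_covariates()]).
#' @param reference Reference group (default `"low"`).
#' @param ci Interval flavour, see [fit_ols()].
#' @return A `dc_model` with the group-term estimates and joint test.
#' @export
medi_main_effect_on_rsfc <- function(analytic, rsfc_var = "overall_z",
                                     covariates = dc_covariates(),
                                     reference = "low", ci = "wald") {
  gd <- group_dummies(analytic$medi_group, reference)
  cm <- covariate_matrix(analytic, covariates)
  gnames <- paste0("medi_", gd$others)
  X <- cbind(1, gd$d, cm)
  colnames(X) <- c("(Intercept)", gnames, covariates)
  fit <- fit_ols(analytic[[rsfc_var]], X, ci)
  roles <- c(
    "(Intercept)" = "intercept",
    setNames(rep("group_dummy", 2), gnames), base_roles(covariates)
  )
  new_dc_model(rsfc_var, "medi-main", fit, roles, wald_joint(fit, gnames))
}

#' MeDi-group by rsFC interaction model
#'
#' The moderation model: reference ability on rsFC, two group indicators,
#' their products with rsFC, and the covariates. Reports each interaction
#' coefficient with its Wald interval and the 2-df joint interaction test
#' (interaction significance convention: two-sided 0.10).
#'
#' @inheritParams medi_main_effect_on_rsfc
#' @param outcome Reference-ability column (default `"FLUID"`).
#' @return A `dc_model`; the interaction terms are named
#'   `rsfc:medi_<group>`.
#' @export
interaction_model <- function(analytic, outcome = "FLUID",
                              rsfc_var = "overall_z",
                              covariates = dc_covariates(),
                              reference = "low", ci = "wald") {
  gd <- group_dummies(analytic$medi_group, reference)
  cm <- covariate_matrix(analytic, covariates)
  z <- analytic[[rsfc_var]]
  gnames <- paste0("medi_", gd$others)
  inames <- paste0("rsfc:medi_", gd$others)
  X <- cbind(1, z, gd$d, z * gd$d, cm)
  colnames(X) <- c("(Intercept)", "rsfc", gnames, inames, covariates)
  fit <- fit_ols(analytic[[outcome]], X, ci)
  roles <- c(
    "(Intercept)" = "intercept", rsfc = "rsfc_main",
    setNames(rep("group_dummy", 2), gnames),
    setNames(rep("interaction", 2), inames), base_roles(covariates)
  )
  new_dc_model(
    outcome, paste0("interaction:", rsfc_var), fit, roles,
    wald_joint(fit, inames)
  )
}

#' Within-group (stratified) rsFC slope
#'
#' Refits outcome ~ rsFC + covariates inside one MeDi group. Because the
#' covariates are refit per stratum, the stratified slopes need not equal
#' reference slope plus interaction from the pooled model.
#'
#' @inheritParams interaction_model
#' @param group Which MeDi group to fit within.
#' @return A `dc_model`; the slope of interest is term `"rsfc"`.
#' @export
stratified_model <- function(analytic, outcome = "FLUID",
                             rsfc_var = "overall_z", group = "low",
                             covariates = dc_covariates(), ci = "wald") {
  sub <- analytic[analytic$medi_group == group, , drop = FALSE]
  cm <- covariate_matrix(sub, covariates)
  # an indicator level can be absent from a stratum; constant columns are
  # dropped rather than failing the whole refit
  constant <- apply(cm, 2, function(x) length(unique(x)) == 1L)
  cm <- cm[, !constant, drop = FALSE]
  covariates <- covariates[!constant]
  if (nrow(sub) <= ncol(cm) + 2L) {
    stop("group ", group, " too small for the covariate set")
  }
  X <- cbind(1, sub[[rsfc_var]], cm)
  colnames(X) <- c("(Intercept)", "rsfc", covariates)
  fit <- fit_ols(sub[[outcome]], X, ci)
  roles <- c(
    "(Intercept)" = "intercept", rsfc = "rsfc_main",
    base_roles(covariates)
  )
  new_dc_model(outcome, paste0("stratified:", group), fit, roles)
}

#' Interaction and stratified models per network
#'
#' Applies [interaction_model()] and [stratified_model()] to the
#' per-network connectivity columns (`net_<name>`). No multiplicity
#' correction is applied across the 10 networks, mirroring the exploratory
#' convention; the comparison count is attached so reports can say so.
#'
#' @inheritParams interaction_model
#' @param networks Network labels (default [dc_networks()]).
#' @return List of per-network lists with elements `interaction` and
#'   `stratified` (one model per group), class `dc_scan`; attribute
#'   `n_comparisons`.
#' @export
network_level_scan <- function(analytic, outcome = "FLUID",
                               networks = dc_networks(),
                               covariates = dc_covariates(), ci = "wald") {
  vars <- paste0("net_", networks)
  missing_cols <- setdiff(vars, names(analytic))
  if (length(missing_cols)) {
    stop("analytic table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  res <- lapply(seq_along(networks), function(i) {
    list(
      network = networks[i],
      interaction = interaction_model(analytic, outcome, vars[i], covariates, ci = ci),
      stratified = lapply(
        setNames(nm = levels(analytic$medi_group)),
        function(g) stratified_model(analytic, outcome, vars[i], g, covariates, ci)
      )
    )
  })
  structure(res,
    names = networks, class = "dc_scan",
    n_comparisons = length(networks)
  )
}

#' Interaction models for every network pair
#'
#' Fits the moderation model for each unordered network pair's connectivity
#' column (`pair_<A>.<B>`) and summarizes the signs of the interaction
#' estimates (the qualitative claim of interest is that they are
#' consistently positive: weaker negative rsFC effects with higher
#' adherence). No multiplicity correction, as in the per-network scan.
#'
#' @inheritParams network_level_scan
#' @return Data frame with one row per pair: interaction estimates,
#'   intervals, p values and the joint p; attributes `n_comparisons` and
#'   `sign_summary`.
#' @export
pairwise_scan <- function(analytic, outcome = "FLUID",
                          networks = dc_networks(),
                          covariates = dc_covariates(), ci = "wald") {
  pairs <- combn(networks, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    v <- paste0("pair_", pairs[1, j], ".", pairs[2, j])
    if (!v %in% names(analytic)) stop("analytic table lacks column ", v)
    m <- interaction_model(analytic, outcome, v, covariates, ci = ci)
    tmod <- model_term(m, "rsfc:medi_moderate")
    thigh <- model_term(m, "rsfc:medi_high")
    rows[[j]] <- data.frame(
      pair = paste(pairs[1, j], pairs[2, j], sep = "."),
      B_moderate = tmod$B, LL_moderate = tmod$LL, UL_moderate = tmod$UL,
      p_moderate = tmod$p,
      B_high = thigh$B, LL_high = thigh$LL, UL_high = thigh$UL,
      p_high = thigh$p,
      joint_p = m$joint$p, n = m$n,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n_comparisons") <- nrow(out)
  attr(out, "sign_summary") <- c(
    positive = sum(out$B_moderate > 0) + sum(out$B_high > 0),
    total = 2L * nrow(out)
  )
  out
}

#' Continuous food-type subscore by rsFC interaction
#'
#' Tests whether the beneficial-intake subscore (0-35) or the
#' detrimental-avoidance subscore (0-20, reverse-scored so higher = more
#' avoidance) moderates the rsFC-cognition association, keeping the
#' subscore continuous: outcome ~ rsFC + subscore + rsFC x subscore +
#' covariates.
#'
#' @inheritParams interaction_model
#' @param subscore `"beneficial"` or `"detrimental"`.
#' @return A `dc_model`; the term of interest is `"rsfc:subscore"`.
#' @export
foodtype_interaction <- function(analytic, outcome = "FLUID",
                                 rsfc_var = "overall_z",
                                 subscore = c("beneficial", "detrimental"),
                                 covariates = dc_covariates(), ci = "wald") {
  subscore <- match.arg(subscore)
  svar <- if (subscore == "beneficial") {
    "beneficial_sum"
  } else {
    "detrimental_avoidance_sum"
  }
  s <- analytic[[svar]]
  z <- analytic[[rsfc_var]]
  cm <- covariate_matrix(analytic, covariates)
  X <- cbind(1, z, s, z * s, cm)
  colnames(X) <- c("(Intercept)", "rsfc", "subscore", "rsfc:subscore", covariates)
  fit <- fit_ols(analytic[[outcome]], X, ci)
  roles <- c(
    "(Intercept)" = "intercept", rsfc = "rsfc_main",
    subscore = "covariate", "rsfc:subscore" = "interaction",
    base_roles(covariates)
  )
  new_dc_model(outcome, paste0("foodtype:", subscore), fit, roles)
}

#' Three-way modifier x MeDi group x rsFC interaction
#'
#' Full factorial expansion of the moderation model with a continuous
#' (age) or binary (gender) modifier: all lower-order terms plus the two
#' three-way products, whose 2-df joint Wald test is reported. The modifier
#' is removed from the plain covariate set to avoid duplication.
#'
#' @inheritParams interaction_model
#' @param modifier `"age"` or `"gender"`.
#' @return A `dc_model` with joint test on the three-way terms
#'   (`rsfc:medi_<group>:mod`).
#' @export
threeway_interaction <- function(analytic, outcome = "FLUID",
                                 rsfc_var = "overall_z",
                                 modifier = c("age", "gender"),
                                 covariates = dc_covariates(), ci = "wald") {
  modifier <- match.arg(modifier)
  mvar <- if (modifier == "age") "age" else "gender_female"
  m <- analytic[[mvar]]
  covariates <- setdiff(covariates, mvar)
  gd <- group_dummies(analytic$medi_group, "low")
  cm <- covariate_matrix(analytic, covariates)
  z <- analytic[[rsfc_var]]
  gnames <- paste0("medi_", gd$others)
  X <- cbind(
    1, z, gd$d, m, z * gd$d, z * m, m * gd$d, z * m * gd$d, cm
  )
  colnames(X) <- c(
    "(Intercept)", "rsfc", gnames, "mod",
    paste0("rsfc:", gnames), "rsfc:mod", paste0("mod:", gnames),
    paste0("rsfc:", gnames, ":mod"), covariates
  )
  fit <- fit_ols(analytic[[outcome]], X, ci)
  three <- paste0("rsfc:", gnames, ":mod")
  roles <- c(
    "(Intercept)" = "intercept", rsfc = "rsfc_main",
    setNames(rep("group_dummy", 2), gnames), mod = "covariate",
    setNames(rep("interaction", 2), paste0("rsfc:", gnames)),
    "rsfc:mod" = "interaction",
    setNames(rep("interaction", 2), paste0("mod:", gnames)),
    setNames(rep("threeway", 2), three), base_roles(covariates)
  )
  new_dc_model(
    outcome, paste0("threeway:", modifier), fit, roles,
    wald_joint(fit, three)
  )
}

#' Group descriptive statistics
#'
#' Per-group mean (SD) with a one-way ANOVA F test for continuous
#' variables, per-group percentages with a Pearson chi-square test (no
#' continuity correction) for categorical ones.
#'
#' @param analytic Analytic table with `medi_group`.
#' @param continuous,categorical Variable names; defaults cover the usual
#'   participant-characteristics table.
#' @return Data frame with one row per variable (categorical variables get
#'   one row per level): per-group summaries, test statistic, p value and
#'   test name.
#' @export
group_descriptives <- function(analytic,
                               continuous = c(
                                 "age", "education", "nart_iq",
                                 "cortical_thickness", "brain_volume", "wmh",
                                 "fa", "scrub_pct", "overall_z", "FLUID",
                                 "MEMORY", "VOCAB", "SPEED"
                               ),
                               categorical = c("gender", "race")) {
  g <- analytic$medi_group
  levs <- levels(g)
  rows <- list()
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "N", t(vapply(levs, function(l) sprintf("%d", sum(g == l)), "")),
    stat = NA_real_, p = NA_real_, test = "",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (v in intersect(continuous, names(analytic))) {
    x <- analytic[[v]]
    cell <- vapply(levs, function(l) {
      sprintf("%.3f (%.3f)", mean(x[g == l]), sd(x[g == l]))
    }, "")
    k <- length(levs)
    n <- length(x)
    gm <- tapply(x, g, mean)
    ssb <- sum(tapply(x, g, length) * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, t(cell),
      stat = f, p = pf(f, k - 1, n - k, lower.tail = FALSE),
      test = "one-way ANOVA", stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  for (v in intersect(categorical, names(analytic))) {
    tab <- table(analytic[[v]], g)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    for (lev in rownames(tab)) {
      cell <- vapply(levs, function(l) {
        sprintf("%.1f%%", 100 * tab[lev, l] / sum(g == l))
      }, "")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = paste0(v, ": ", lev), t(cell),
        stat = if (lev == rownames(tab)[1]) unname(chi$statistic) else NA_real_,
        p = if (lev == rownames(tab)[1]) chi$p.value else NA_real_,
        test = if (lev == rownames(tab)[1]) "Pearson chi-square" else "",
        stringsAsFactors = FALSE, check.names = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(levs))] <- levs
  rownames(out) <- NULL
  out
}
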