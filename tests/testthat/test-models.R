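test_that("fit_ols matches the normal-equation oracle and is exact when noiseless", {
  set.seed(41)
  # noiseless line: exact coefficients, zero-width intervals
  x <- rnorm(30)
  X <- cbind(1, x)
  colnames(X) <- c("(Intercept)", "x")
  f <- fit_ols(2 + 3 * x, X)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-12)
  expect_equal(unname(f$upper - f$lower), c(0, 0), tolerance = 1e-10)

  # random toys vs solve(X'X) X'y
  for (i in 1:10) {
    n <- 20
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("a", "b", "c")
    y <- rnorm(n)
    f <- fit_ols(y, X)
    expect_equal(unname(f$coefficients), normal_equations(y, X), tolerance = 1e-8)
    # sanity of the interval arithmetic
    expect_true(all(f$lower <= f$coefficients & f$coefficients <= f$upper))
    # Wald consistency at matching levels: 0 outside the 95% CI iff p < 0.05
    expect_identical(unname(f$lower > 0 | f$upper < 0), unname(f$p < 0.05))
  }

  expect_error(fit_ols(rnorm(3), cbind(1, rnorm(3), rnorm(3))), "observations")
  Xd <- cbind(1, x, x)
  expect_error(fit_ols(rnorm(30), Xd), "rank deficient")
})

test_that("fit_ols null rejection rate is close to nominal", {
  set.seed(42)
  n <- 150
  hits <- vapply(1:400, function(i) {
    X <- cbind(1, rnorm(n))
    colnames(X) <- c("i", "x")
    fit_ols(rnorm(n), X)$p["x"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("Wald and t intervals converge at the analytic sample size", {
  set.seed(43)
  a <- make_analytic(n = 201)
  mw <- interaction_model(a, ci = "wald")
  mt <- interaction_model(a, ci = "t")
  ww <- mw$terms$UL - mw$terms$LL
  wt <- mt$terms$UL - mt$terms$LL
  expect_true(all(abs(wt / ww - 1) < 0.01))
  expect_equal(mw$terms$B, mt$terms$B)
})

test_that("interaction model recovers planted moderation and nulls", {
  # noiseless, no covariate effects: interaction coefficients are exact
  a <- make_analytic(n = 300, seed = 2, slopes = c(low = -5, moderate = 1, high = 2))
  a$FLUID <- c(-5, 1, 2)[as.integer(a$medi_group)] * a$overall_z
  m <- interaction_model(a)
  expect_equal(model_term(m, "rsfc")$B, -5, tolerance = 1e-8)
  expect_equal(model_term(m, "rsfc:medi_moderate")$B, 6, tolerance = 1e-8)
  expect_equal(model_term(m, "rsfc:medi_high")$B, 7, tolerance = 1e-8)

  # identical slopes -> interactions vanish
  a$FLUID <- -2 * a$overall_z
  m0 <- interaction_model(a)
  expect_equal(model_term(m0, "rsfc:medi_moderate")$B, 0, tolerance = 1e-8)
  expect_equal(model_term(m0, "rsfc:medi_high")$B, 0, tolerance = 1e-8)
})

test_that("reference-group choice changes contrasts, not the fit", {
  a <- make_analytic(n = 240, seed = 3)
  m_low <- interaction_model(a, reference = "low")
  m_high <- interaction_model(a, reference = "high")
  expect_equal(m_low$fit$fitted, m_high$fit$fitted, tolerance = 1e-10)
  expect_equal(m_low$fit$rss, m_high$fit$rss, tolerance = 1e-10)
  # contrast identity: (mod - low) - (high - low) = mod - high
  expect_equal(
    model_term(m_low, "rsfc:medi_moderate")$B - model_term(m_low, "rsfc:medi_high")$B,
    model_term(m_high, "rsfc:medi_moderate")$B,
    tolerance = 1e-10
  )
})

test_that("stratified slopes: exact noiseless recovery, covariate-driven gap", {
  a <- make_analytic(n = 300, seed = 4)
  a$FLUID <- c(-5, 0, 1)[as.integer(a$medi_group)] * a$overall_z
  for (g in c("low", "moderate", "high")) {
    s <- stratified_model(a, group = g)
    expect_equal(
      model_term(s, "rsfc")$B,
      c(low = -5, moderate = 0, high = 1)[[g]],
      tolerance = 1e-8
    )
    expect_identical(s$n, sum(a$medi_group == g))
  }

  # when a covariate effect differs by stratum, the stratified slope need
  # not equal reference slope + interaction from the pooled model
  b <- make_analytic(n = 300, seed = 5, noise_sd = 0)
  agec <- b$age - mean(b$age)
  slope_by_g <- c(-4, 0, 1)[as.integer(b$medi_group)]
  agec_by_g <- c(0.05, -0.05, 0)[as.integer(b$medi_group)]
  b$FLUID <- slope_by_g * b$overall_z + agec_by_g * agec
  pooled <- interaction_model(b)
  strat <- stratified_model(b, group = "moderate")
  implied <- model_term(pooled, "rsfc")$B + model_term(pooled, "rsfc:medi_moderate")$B
  expect_gt(abs(model_term(strat, "rsfc")$B - implied), 0.01)
  # while the stratified fit itself recovers its stratum exactly
  expect_equal(model_term(strat, "rsfc")$B, 0, tolerance = 1e-6)
})

test_that("MeDi main-effect model detects planted group shifts and respects the null", {
  a <- make_analytic(n = 270, seed = 6)
  z <- a$overall_z
  a$overall_z <- z + ifelse(a$medi_group == "high", 0.05, 0)
  m <- medi_main_effect_on_rsfc(a)
  # single-draw sampling error of the group contrast is about 0.007
  expect_lt(abs(model_term(m, "medi_high")$B - 0.05), 0.025)
  expect_lt(m$joint$p, 0.01)

  # permutation oracle: with labels permuted, the joint test p is uniform
  set.seed(7)
  a$overall_z <- z
  rate <- mean(vapply(1:150, function(i) {
    ap <- a
    ap$medi_group <- sample(ap$medi_group)
    medi_main_effect_on_rsfc(ap)$joint$p < 0.10
  }, logical(1)))
  expect_lt(abs(rate - 0.10), 0.07)
})

test_that("food-type interaction: planted recovery and affine equivariance", {
  a <- make_analytic(n = 300, seed = 8)
  det <- a$detrimental_avoidance_sum
  a$FLUID <- -4 * a$overall_z + 0.02 * det + 0.4 * a$overall_z * det +
    rnorm(300, 0, 0.05)
  m <- foodtype_interaction(a, subscore = "detrimental")
  # residual SD 0.05 puts the coefficient's sampling error near 0.01
  expect_lt(abs(model_term(m, "rsfc:subscore")$B - 0.4), 0.04)

  # rescaling the subscore by c rescales the interaction by 1/c
  a2 <- a
  a2$detrimental_avoidance_sum <- 2 * det
  m2 <- foodtype_interaction(a2, subscore = "detrimental")
  expect_equal(
    model_term(m2, "rsfc:subscore")$B,
    model_term(m, "rsfc:subscore")$B / 2,
    tolerance = 1e-8
  )

  # zero planted interaction
  a$FLUID <- -4 * a$overall_z + 0.02 * det
  m0 <- foodtype_interaction(a, subscore = "detrimental")
  expect_equal(model_term(m0, "rsfc:subscore")$B, 0, tolerance = 1e-8)
  b <- foodtype_interaction(a, subscore = "beneficial")
  expect_identical(b$label, "foodtype:beneficial")
})

test_that("three-way interaction recovers a planted modifier effect", {
  a <- make_analytic(n = 400, seed = 9)
  agec <- a$age - mean(a$age)
  dmod <- as.numeric(a$medi_group == "moderate")
  a$FLUID <- -2 * a$overall_z + 0.3 * a$overall_z * dmod * agec
  m <- threeway_interaction(a, modifier = "age")
  expect_equal(model_term(m, "rsfc:medi_moderate:mod")$B, 0.3, tolerance = 1e-6)
  expect_equal(model_term(m, "rsfc:medi_high:mod")$B, 0, tolerance = 1e-6)
  expect_lt(m$joint$p, 1e-6)

  mg <- threeway_interaction(a, modifier = "gender")
  expect_true(all(c("rsfc:medi_moderate:mod", "rsfc:medi_high:mod") %in% mg$terms$term))
  expect_false("gender_female" %in% mg$terms$term[mg$terms$role == "covariate"])
})

test_that("network and pairwise scans run over the expected columns", {
  a <- make_analytic(n = 220, seed = 10)
  nets <- c("A", "B", "C")
  for (k in nets) a[[paste0("net_", k)]] <- a$overall_z + rnorm(220, 0, 0.01)
  for (p in c("A.B", "A.C", "B.C")) {
    a[[paste0("pair_", p)]] <- a$overall_z + rnorm(220, 0, 0.01)
  }
  sc <- network_level_scan(a, networks = nets)
  expect_named(sc, nets)
  expect_identical(attr(sc, "n_comparisons"), 3L)
  expect_s3_class(sc[["A"]]$interaction, "dc_model")
  expect_named(sc[["A"]]$stratified, c("low", "moderate", "high"))

  pw <- pairwise_scan(a, networks = nets)
  expect_identical(nrow(pw), 3L)
  expect_identical(attr(pw, "n_comparisons"), 3L)
  ss <- attr(pw, "sign_summary")
  expect_identical(unname(ss["total"]), 6L)

  expect_error(network_level_scan(a, networks = c("A", "Z")), "net_Z")
})

test_that("group descriptives: ANOVA and chi-square against closed forms", {
  a <- make_analytic(n = 300, seed = 11)
  d <- group_descriptives(a)
  expect_true("N" %in% d$variable)

  # ANOVA oracle via lm-based decomposition
  frow <- d[d$variable == "age", ]
  an <- anova(lm(age ~ medi_group, data = a))
  expect_equal(frow$stat, an$`F value`[1], tolerance = 1e-8)
  expect_equal(frow$p, an$`Pr(>F)`[1], tolerance = 1e-8)

  # hand-computed 2x2 chi-square [[10,20],[20,10]] = 20/3
  b <- data.frame(
    medi_group = factor(rep(c("low", "moderate"), each = 30)),
    gender = c(rep("male", 10), rep("female", 20), rep("male", 20), rep("female", 10))
  )
  d2 <- group_descriptives(b, continuous = character(), categorical = "gender")
  chi_row <- d2[grepl("gender", d2$variable) & !is.na(d2$stat), ]
  expect_equal(chi_row$stat, 20 / 3, tolerance = 1e-8)

  # separation: one group shifted far away -> tiny p
  a2 <- a
  a2$age[a2$medi_group == "high"] <- a2$age[a2$medi_group == "high"] + 100
  d3 <- group_descriptives(a2, continuous = "age", categorical = character())
  expect_lt(d3$p[d3$variable == "age"], 1e-3)
})
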