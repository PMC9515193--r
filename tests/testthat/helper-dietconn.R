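# Shared fixture builders. Everything is generated in code; no stored data.

# Small parcellation with widely separated ROI centres (nothing inside the
# 20 mm exclusion radius unless a test plants a close pair on purpose).
make_parcellation <- function(n_per_net = 2, networks = c("A", "B"),
                              spacing = 40) {
  n <- n_per_net * length(networks)
  data.frame(
    roi_id = paste0("r", seq_len(n)),
    x_mm = spacing * seq_len(n),
    y_mm = 0, z_mm = 0,
    network = rep(networks, each = n_per_net),
    stringsAsFactors = FALSE
  )
}

# Long-format FFQ for one participant from named category -> servings.
make_ffq <- function(servings, id = "p1") {
  data.frame(
    participant_id = id,
    category = names(servings),
    servings_per_month = unname(servings),
    stringsAsFactors = FALSE
  )
}

# Servings value landing exactly in frequency category k under the default
# cutpoints (1, 5, 13, 31, 61).
servings_for_category <- function(k) c(0, 2, 6, 14, 32, 62)[k + 1]

# Analytic-style table built directly (no generator) for model unit tests.
# FLUID is generated with group-specific rsFC slopes plus a small education
# effect; remaining reference abilities are noise.
make_analytic <- function(n = 240, seed = 1,
                          slopes = c(low = -2, moderate = 0, high = 1),
                          noise_sd = 0.3, z = NULL) {
  set.seed(seed)
  g <- factor(rep(c("low", "moderate", "high"), length.out = n),
    levels = c("low", "moderate", "high")
  )
  if (is.null(z)) z <- rnorm(n, 0.25, 0.045)
  race <- sample(c("white", "black", "other"), n, TRUE, c(0.65, 0.25, 0.10))
  df <- data.frame(
    participant_id = sprintf("S%04d", seq_len(n)),
    medi_group = g, overall_z = z,
    age = rnorm(n, 54, 16),
    gender_female = as.numeric(runif(n) < 0.5),
    race_black = as.numeric(race == "black"),
    race_other = as.numeric(race == "other"),
    education = rnorm(n, 16, 2.3),
    nart_iq = rnorm(n, 117, 8),
    kcal = rnorm(n, 1800, 500),
    cortical_thickness = rnorm(n, 2.55, 0.12),
    brain_volume = rnorm(n, 0, 5e4),
    scrub_pct = rgamma(n, 1, scale = 5),
    log_wmh = rnorm(n, 6, 1),
    fa = rnorm(n, 0.44, 0.02),
    beneficial_sum = sample(0:35, n, TRUE),
    detrimental_avoidance_sum = sample(0:20, n, TRUE),
    stringsAsFactors = FALSE
  )
  df$FLUID <- slopes[as.integer(g)] * z +
    0.02 * (df$education - 16) + rnorm(n, 0, noise_sd)
  df$MEMORY <- rnorm(n, 0, 0.8)
  df$VOCAB <- rnorm(n, 0, 0.8)
  df$SPEED <- rnorm(n, 0, 0.8)
  df
}

# Brute-force least-squares oracle via the normal equations.
normal_equations <- function(y, X) {
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}
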