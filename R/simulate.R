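# Synthetic cohort generator: complete study inputs (FFQ, covariates, ROI
# time series, cognition, missingness) with known planted parameters so
# every downstream stage has a recovery-testable ground truth.

#' Default synthetic parcellation
#'
#' The 10 networks with their ROI counts (Hand 30, Vis 31, Mouth 5, Aud 13,
#' DMN 58, Sal 18, CO 14, FP 25, DAN 11, VAN 9 = 214 ROIs), optionally
#' padded with unlabelled `"excluded"` ROIs up to the 264 of the full
#' scheme. Centres are laid out deterministically on a 24 mm grid so that no
#' pair falls inside the default 20 mm distance-exclusion radius; tests
#' plant closer pairs explicitly when exercising that rule.
#'
#' @param n_excluded Number of additional `"excluded"` ROIs (0-50).
#' @param n_per_network Optional named vector overriding the ROI counts.
#' @return Parcellation data frame (`roi_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `network`).
#' @export
default_parcellation <- function(n_excluded = 0, n_per_network = NULL) {
  counts <- c(
    Hand = 30, Vis = 31, Mouth = 5, Aud = 13, DMN = 58,
    Sal = 18, CO = 14, FP = 25, DAN = 11, VAN = 9
  )
  if (!is.null(n_per_network)) counts <- n_per_network
  if (n_excluded > 0) counts <- c(counts, excluded = n_excluded)
  total <- sum(counts)
  grid <- as.matrix(expand.grid(
    x_mm = seq(-96, 96, by = 24),
    y_mm = seq(-120, 96, by = 24),
    z_mm = seq(-72, 96, by = 24)
  ))
  if (total > nrow(grid)) stop("too many ROIs for the coordinate grid")
  data.frame(
    roi_id = sprintf("roi%03d", seq_len(total)),
    x_mm = grid[seq_len(total), 1],
    y_mm = grid[seq_len(total), 2],
    z_mm = grid[seq_len(total), 3],
    network = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
}

#' Planted effect presets
#'
#' Two presets are defined from the printed moderation estimates, which are
#' not mutually consistent because the stratified fits refit covariates per
#' stratum: `"tab2-stratified"` plants the stratified fluid-reasoning slopes
#' (-5.354, -0.605, 0.177) for the low/moderate/high groups;
#' `"tab2-interaction"` plants the low-group slope -5.354 together with
#' interaction deltas +5.620 (moderate vs low) and +4.779 (high vs low).
#' `"null"` gives all three groups the same slope, for type-I-error
#' calibration.
#'
#' @return Named list of presets; each has a `fluid_slopes` vector with
#'   entries `low`, `moderate`, `high`.
#' @export
effect_presets <- function() {
  list(
    "tab2-stratified" = list(
      fluid_slopes = c(low = -5.354, moderate = -0.605, high = 0.177)
    ),
    "tab2-interaction" = list(
      fluid_slopes = c(
        low = -5.354, moderate = -5.354 + 5.620, high = -5.354 + 4.779
      )
    ),
    "null" = list(
      fluid_slopes = c(low = -1.7, moderate = -1.7, high = -1.7)
    )
  )
}

# Group-specific reference-ability means used to anchor intercepts
# (participant-characteristics calibration targets).
ra_group_means <- function() {
  rbind(
    FLUID = c(low = -0.032, moderate = 0.064, high = 0.085),
    MEMORY = c(low = 0.034, moderate = -0.033, high = -0.011),
    VOCAB = c(low = 0.231, moderate = 0.092, high = 0.094),
    SPEED = c(low = 0.034, moderate = 0.062, high = 0.084)
  )
}

#' Default covariate distribution parameters
#'
#' Means/SDs calibrated to the published participant characteristics (age
#' 54.10/15.98 years, education 16.14/2.26 years, NART IQ 117.28/8.10, mean
#' cortical thickness 2.55/0.12 mm, demeaned total brain volume SD 5e4, FA
#' 0.443/0.021, WMH lognormal with median ~ 400 mm^3 and heavy tail, scrub
#' percentage gamma with mean ~ 6% and a few percent of participants above
#' 30%, 53% female, race mix 66.2/22.4/11.4%). Caloric intake is not
#' tabulated; 1800/550 kcal/day is a realistic adult intake distribution.
#'
#' @return Named list of distribution parameters.
#' @export
default_covariate_params <- function() {
  list(
    age = c(54.10, 15.98), age_range = c(21, 80),
    education = c(16.14, 2.26), nart_iq = c(117.28, 8.10),
    kcal = c(1800, 550), cortical_thickness = c(2.55, 0.12),
    brain_volume = c(0, 50000), wmh_meanlog = 6.0, wmh_sdlog = 1.3,
    fa = c(0.443, 0.021), scrub_shape = 0.8, scrub_scale = 7.5,
    pct_female = 0.53, race_probs = c(0.662, 0.224, 0.114)
  )
}

#' Default covariate effects in the cognition model
#'
#' True coefficients applied to mean-centred covariates when generating
#' reference-ability scores: age -0.02 z-units/year (a typical fluid decline
#' gradient), education +0.03 z-units/year, NART IQ +0.015 z-units/point.
#' All other covariates have null effects.
#'
#' @return Named numeric vector.
#' @export
default_cognition_coefs <- function() {
  c(age = -0.02, education = 0.03, nart_iq = 0.015)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort: cohort size, scan length,
#' parcellation, block-correlation parameters (participant-varying
#' cross-network Fisher-z with population mean `rsfc_mean` and SD
#' `rsfc_sd`), the planted effect preset, covariate distributions, the
#' residual SD of the cognition model, the sequential missingness counts
#' and the master seed (which fans out to per-participant substreams).
#'
#' `noise_sd` defaults to 0.61, calibrated so that the sampling SDs of the
#' simulated stratified rsFC slopes match the published Wald intervals
#' (printed SEs 1.78-2.00 across the three adherence groups at group sizes
#' near 67 and rsFC SD 0.045).
#'
#' @param n_enrolled Enrolled cohort size (default 425).
#' @param n_frames Frames per resting scan (default 285, i.e. 9.5 min at
#'   `tr = 2`; the acquisition TR is not fixed by the protocol, so both are
#'   explicit knobs).
#' @param tr Repetition time, seconds (default 2.0).
#' @param parcellation Parcellation table (default
#'   [default_parcellation()]).
#' @param rho_within Within-network correlation in `[0, 1)` (default 0.45).
#' @param rsfc_mean,rsfc_sd Population mean and SD of the participant-level
#'   cross-network Fisher z (defaults 0.25, 0.045).
#' @param effect_preset Name of a preset in [effect_presets()].
#' @param covariate_params See [default_covariate_params()].
#' @param cognition_coefs See [default_cognition_coefs()].
#' @param noise_sd Residual SD of the cognition model (default 0.61).
#' @param missingness_counts Named counts `(diet, rsfc, structural,
#'   cognitive)` assigned sequentially to disjoint participant sets
#'   (defaults 108, 22, 87, 7); their sum must be below `n_enrolled`.
#' @param cutpoints FFQ cutpoints, see [medi_default_cutpoints()].
#' @param ffq_meanlog,ffq_sdlog Lognormal servings/month parameters
#'   (defaults give category frequencies spanning the full 0-5 range).
#' @param ffq_quality_sd SD of the latent per-participant diet-quality
#'   factor that correlates beneficial (positively) and detrimental
#'   (negatively) intakes; gives totals the spread and near-equal tertile
#'   group sizes observed in real cohorts.
#' @param n_spike_frames,spike_mm Motion spikes per scan and their size.
#' @param nuisance_loading Loading of the white-matter/ventricle traces onto
#'   every ROI's observed signal.
#' @param task_noise_sd SD of within-domain task scatter (centred within
#'   domain, so composites recover the planted ability exactly).
#' @param seed Master integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_enrolled = 425, n_frames = 285, tr = 2.0,
                       parcellation = default_parcellation(),
                       rho_within = 0.45, rsfc_mean = 0.25, rsfc_sd = 0.045,
                       effect_preset = "tab2-stratified",
                       covariate_params = default_covariate_params(),
                       cognition_coefs = default_cognition_coefs(),
                       noise_sd = 0.61,
                       missingness_counts = c(
                         diet = 108, rsfc = 22, structural = 87, cognitive = 7
                       ),
                       cutpoints = medi_default_cutpoints(),
                       ffq_meanlog = log(15), ffq_sdlog = 1.2,
                       ffq_quality_sd = 0.5,
                       n_spike_frames = 3, spike_mm = 1.0,
                       nuisance_loading = 0.3,
                       task_noise_sd = 0.3,
                       seed = 1L) {
  if (n_enrolled < 1 || n_frames < 2 || tr <= 0) {
    stop("counts must be positive")
  }
  if (!(rho_within >= 0 && rho_within < 1)) stop("rho_within must be in [0, 1)")
  if (abs(tanh(rsfc_mean)) >= 1) stop("tanh(rsfc_mean) must be in (-1, 1)")
  if (rsfc_sd < 0 || noise_sd < 0) stop("SDs cannot be negative")
  if (!effect_preset %in% names(effect_presets())) {
    stop(
      "unknown effect preset '", effect_preset, "'; available: ",
      paste(names(effect_presets()), collapse = ", ")
    )
  }
  missingness_counts <- as.integer(missingness_counts)
  names(missingness_counts) <- c("diet", "rsfc", "structural", "cognitive")
  if (any(missingness_counts < 0)) stop("missingness counts cannot be negative")
  if (sum(missingness_counts) >= n_enrolled) {
    stop("missingness counts must sum to less than n_enrolled")
  }
  check_parcellation(parcellation)
  check_cutpoints(cutpoints)
  structure(
    list(
      n_enrolled = as.integer(n_enrolled), n_frames = as.integer(n_frames),
      tr = tr, parcellation = parcellation, rho_within = rho_within,
      rsfc_mean = rsfc_mean, rsfc_sd = rsfc_sd,
      effect_preset = effect_preset, covariate_params = covariate_params,
      cognition_coefs = cognition_coefs, noise_sd = noise_sd,
      missingness_counts = missingness_counts, cutpoints = cutpoints,
      ffq_meanlog = ffq_meanlog, ffq_sdlog = ffq_sdlog,
      ffq_quality_sd = ffq_quality_sd,
      n_spike_frames = as.integer(n_spike_frames), spike_mm = spike_mm,
      nuisance_loading = nuisance_loading, task_noise_sd = task_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

draw_covariates <- function(n, cp) {
  data.frame(
    age = pmin(pmax(rnorm(n, cp$age[1], cp$age[2]), cp$age_range[1]), cp$age_range[2]),
    gender = ifelse(runif(n) < cp$pct_female, "female", "male"),
    race = sample(
      c("non-Hispanic white", "non-Hispanic black", "other"), n,
      replace = TRUE, prob = cp$race_probs
    ),
    education = pmax(rnorm(n, cp$education[1], cp$education[2]), 8),
    nart_iq = rnorm(n, cp$nart_iq[1], cp$nart_iq[2]),
    kcal = pmax(rnorm(n, cp$kcal[1], cp$kcal[2]), 500),
    cortical_thickness = rnorm(n, cp$cortical_thickness[1], cp$cortical_thickness[2]),
    brain_volume = rnorm(n, cp$brain_volume[1], cp$brain_volume[2]),
    wmh = rlnorm(n, cp$wmh_meanlog, cp$wmh_sdlog),
    fa = rnorm(n, cp$fa[1], cp$fa[2]),
    scrub_pct = pmin(rgamma(n, shape = cp$scrub_shape, scale = cp$scrub_scale), 100),
    stringsAsFactors = FALSE
  )
}

participant_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * i) %% 2147483647)
}

#' Generate one participant's ROI time series with motion and nuisance traces
#'
#' Draws `n_frames` multivariate-normal frames from a block correlation
#' matrix: `rho_within` on the diagonal (network) blocks, `tanh(true_z)`
#' everywhere off-block, `"excluded"` ROIs independent. Motion parameters
#' are small white noise with `n_spike_frames` planted translation spikes;
#' white-matter and ventricle traces load onto every ROI's observed signal
#' with weight `nuisance_loading`.
#'
#' @param true_z Participant-level cross-network Fisher z.
#' @param config A [sim_config()].
#' @return List with `signal` (frames x ROIs), `motion` (frames x 6) and
#'   `nuisance` (frames x 3: wm_left, wm_right, ventricles). Errors if the
#'   requested correlation structure is not positive definite.
#' @export
generate_roi_timeseries <- function(true_z, config) {
  parc <- config$parcellation
  net <- as.character(parc$network)
  n_roi <- nrow(parc)
  c_mat <- matrix(tanh(true_z), n_roi, n_roi)
  for (k in unique(net)) {
    i <- net == k
    c_mat[i, i] <- config$rho_within
  }
  exc <- net == "excluded"
  c_mat[exc, ] <- 0
  c_mat[, exc] <- 0
  diag(c_mat) <- 1
  ch <- tryCatch(chol(c_mat), error = function(e) {
    stop("requested block correlation structure is not positive definite")
  })
  nf <- config$n_frames
  signal <- matrix(rnorm(nf * n_roi), nf, n_roi) %*% ch
  motion <- cbind(
    matrix(rnorm(nf * 3, 0, 0.01), nf, 3),
    matrix(rnorm(nf * 3, 0, 1e-4), nf, 3)
  )
  if (config$n_spike_frames > 0) {
    sp <- unique(round(seq(2, nf - 1, length.out = config$n_spike_frames)))
    motion[sp, 1] <- motion[sp, 1] + config$spike_mm
  }
  nuis <- cbind(
    wm_left = rnorm(nf), wm_right = rnorm(nf), ventricles = rnorm(nf)
  )
  observed <- signal + config$nuisance_loading * rowMeans(nuis)
  colnames(observed) <- parc$roi_id
  list(signal = observed, motion = motion, nuisance = nuis)
}

#' Generate a complete synthetic cohort
#'
#' Produces every study input with known ground truth: covariates drawn
#' from the calibrated distributions; an 11-category FFQ whose MeDi tertiles
#' define the true adherence groups (tertile cuts computed on the
#' cascade-eligible participants so downstream grouping reproduces the
#' truth exactly); a participant-level cross-network Fisher z drawn from
#' `N(rsfc_mean, rsfc_sd)`; reference abilities generated as
#' `RA = alpha_g + B_g * z + gamma' x + eps`, `eps ~ N(0, noise_sd^2)`, with
#' group slopes from the effect preset (moderation planted on FLUID only);
#' 12 task scores whose norm-referenced composites recover the planted
#' abilities exactly; and sequential, disjoint missingness flags.
#'
#' In fast mode the participant table carries the drawn rsFC scalar
#' directly (`overall_z`); in full mode per-participant ROI time series,
#' motion and nuisance traces are generated instead (per-participant RNG
#' substreams keyed off the master seed), to be reduced by
#' [summarize_cohort_connectivity()].
#'
#' @param config A [sim_config()].
#' @param fast If `TRUE` (default) skip time-series generation.
#' @return Object of class `dc_cohort`: `participants`, `ffq`, `tasks`,
#'   `norms`, `parcellation`, `timeseries`/`motion`/`nuisance` (full mode),
#'   `ground_truth`, `config`, `fast`.
#' @export
generate_cohort <- function(config, fast = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_enrolled
  ids <- sprintf("P%04d", seq_len(n))
  cats <- medi_categories()

  covs <- draw_covariates(n, config$covariate_params)

  mc <- config$missingness_counts
  bounds <- cumsum(c(0, mc))
  flags <- sapply(seq_along(mc), function(j) {
    seq_len(n) > bounds[j] & seq_len(n) <= bounds[j + 1]
  })
  colnames(flags) <- paste0("miss_", names(mc))

  # a latent per-participant diet-quality factor raises beneficial and
  # lowers detrimental intakes together, giving MeDi totals the spread and
  # near-equal tertile sizes seen in real cohorts
  quality <- rnorm(n, 0, config$ffq_quality_sd)
  orient <- ifelse(cats %in% medi_categories("detrimental"), -1, 1)
  ffq <- data.frame(
    participant_id = rep(ids, each = length(cats)),
    category = rep(cats, n),
    servings_per_month = rlnorm(
      n * length(cats),
      config$ffq_meanlog + rep(quality, each = length(cats)) * rep(orient, n),
      config$ffq_sdlog
    ),
    stringsAsFactors = FALSE
  )
  scores <- score_medi(ffq, config$cutpoints)
  tot <- scores$total[match(ids, scores$participant_id)]
  eligible <- rowSums(flags) == 0
  cuts <- quantile(tot[eligible], c(1, 2) / 3, names = FALSE, type = 7)
  if (min(tot[eligible]) == max(tot[eligible])) {
    stop("degenerate FFQ draw: all totals identical")
  }
  group <- medi_group_from_total(tot, cuts)

  z <- rnorm(n, config$rsfc_mean, config$rsfc_sd)

  preset <- effect_presets()[[config$effect_preset]]
  means <- ra_group_means()
  slopes <- rbind(
    FLUID = preset$fluid_slopes,
    MEMORY = c(low = -1, moderate = -1, high = -1),
    VOCAB = c(low = -1, moderate = -1, high = -1),
    SPEED = c(low = -1, moderate = -1, high = -1)
  )
  gamma <- config$cognition_coefs
  cp <- config$covariate_params
  xc <- cbind(
    age = covs$age - cp$age[1],
    education = covs$education - cp$education[1],
    nart_iq = covs$nart_iq - cp$nart_iq[1]
  )
  lin <- drop(xc[, names(gamma), drop = FALSE] %*% gamma)
  gi <- as.integer(group)
  ra <- sapply(rownames(slopes), function(d) {
    alpha <- means[d, ] - slopes[d, ] * config$rsfc_mean
    alpha[gi] + slopes[d, gi] * z + lin + rnorm(n, 0, config$noise_sd)
  })

  battery <- ra_task_battery()
  norms <- data.frame(
    task = battery$task, ref_mean = 50, ref_sd = 10, stringsAsFactors = FALSE
  )
  tasks <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (d in unique(battery$domain)) {
    dn <- battery$task[battery$domain == d]
    delta <- matrix(rnorm(n * 3, 0, config$task_noise_sd), n, 3)
    delta <- delta - rowMeans(delta)
    for (j in 1:3) tasks[[dn[j]]] <- 50 + 10 * (ra[, d] + delta[, j])
  }

  participants <- cbind(
    data.frame(participant_id = ids, stringsAsFactors = FALSE),
    covs, as.data.frame(flags)
  )

  timeseries <- motion <- nuisance <- NULL
  if (!fast) {
    timeseries <- motion <- nuisance <- setNames(vector("list", n), ids)
    for (i in seq_len(n)) {
      set.seed(participant_seed(config$seed, i))
      p <- generate_roi_timeseries(z[i], config)
      timeseries[[i]] <- p$signal
      motion[[i]] <- p$motion
      nuisance[[i]] <- p$nuisance
    }
  } else {
    participants$overall_z <- z
  }

  ground_truth <- list(
    participant_id = ids, true_z = z, group = as.character(group),
    tertile_cuts = cuts, slopes = as.list(as.data.frame(t(slopes))),
    covariate_coefs = as.list(gamma), noise_sd = config$noise_sd,
    missing = lapply(
      setNames(seq_along(mc), names(mc)),
      function(j) ids[flags[, j]]
    ),
    effect_preset = config$effect_preset, seed = config$seed
  )

  structure(
    list(
      participants = participants, ffq = ffq, tasks = tasks, norms = norms,
      parcellation = config$parcellation, timeseries = timeseries,
      motion = motion, nuisance = nuisance, ground_truth = ground_truth,
      config = config, fast = fast
    ),
    class = "dc_cohort"
  )
}

#' Write a generated cohort to a directory of plain-text files
#'
#' Emits `participants.csv`, `ffq.csv`, `tasks.csv`, `norms.csv`,
#' `parcellation.tsv`, `ground_truth.json` and, for full-mode cohorts,
#' `timeseries/<id>.tsv`, `motion/<id>.tsv`, `nuisance/<id>.tsv`.
#'
#' @param cohort A `dc_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$participants, file.path(dir, "participants.csv"), row.names = FALSE)
  write.csv(cohort$ffq, file.path(dir, "ffq.csv"), row.names = FALSE)
  write.csv(cohort$tasks, file.path(dir, "tasks.csv"), row.names = FALSE)
  write.csv(cohort$norms, file.path(dir, "norms.csv"), row.names = FALSE)
  write.table(cohort$parcellation, file.path(dir, "parcellation.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(cohort$timeseries)) {
    for (sub in c("timeseries", "motion", "nuisance")) {
      dir.create(file.path(dir, sub), showWarnings = FALSE)
      for (id in names(cohort[[sub]])) {
        write.table(cohort[[sub]][[id]], file.path(dir, sub, paste0(id, ".tsv")),
          sep = "\t", row.names = FALSE, col.names = FALSE
        )
      }
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `dc_cohort`-like list (without config; `ground_truth` is the
#'   parsed JSON). Errors name any missing input file.
#' @export
read_cohort <- function(dir) {
  need <- c(
    "participants.csv", "ffq.csv", "tasks.csv", "norms.csv",
    "parcellation.tsv", "ground_truth.json"
  )
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing input file: ", file.path(dir, f))
    }
  }
  out <- list(
    participants = read.csv(file.path(dir, "participants.csv"), stringsAsFactors = FALSE),
    ffq = read.csv(file.path(dir, "ffq.csv"), stringsAsFactors = FALSE),
    tasks = read.csv(file.path(dir, "tasks.csv"), stringsAsFactors = FALSE),
    norms = read.csv(file.path(dir, "norms.csv"), stringsAsFactors = FALSE),
    parcellation = read.delim(file.path(dir, "parcellation.tsv"), stringsAsFactors = FALSE),
    ground_truth = jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  )
  ts_dir <- file.path(dir, "timeseries")
  if (dir.exists(ts_dir)) {
    ids <- sub("\\.tsv$", "", list.files(ts_dir))
    read_mats <- function(sub) {
      setNames(lapply(ids, function(id) {
        as.matrix(read.delim(file.path(dir, sub, paste0(id, ".tsv")), header = FALSE))
      }), ids)
    }
    out$timeseries <- read_mats("timeseries")
    out$motion <- read_mats("motion")
    out$nuisance <- read_mats("nuisance")
  }
  class(out) <- "dc_cohort"
  out
}
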