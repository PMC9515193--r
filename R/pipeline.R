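# End-to-end orchestration with a run manifest and publication-style
# table/figure outputs.

fnv1a_mulmod32 <- function(a, b) {
  a_hi <- a %/% 65536
  a_lo <- a %% 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

#' Hash a simulation configuration
#'
#' 32-bit FNV-1a over the deparsed configuration; used to make manifest
#' entries traceable to the exact configuration that produced them.
#'
#' @param config Any R object (normally a [sim_config()]).
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 256, b %% 256)
    h <- (h %/% 256) * 256 + lo
    h <- fnv1a_mulmod32(h, 16777619)
  }
  # h exceeds the integer range; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

model_rows <- function(m) {
  cbind(
    data.frame(
      label = m$label, outcome = m$outcome, stringsAsFactors = FALSE
    ),
    m$terms,
    data.frame(
      n = m$n, joint_p = if (is.null(m$joint)) NA_real_ else m$joint$p
    )
  )
}

#' Long-format table of model results
#'
#' @param models List of `dc_model` objects.
#' @return Data frame with columns label, outcome, term, role, B, LL, UL,
#'   p, n, joint_p.
#' @export
models_table <- function(models) {
  do.call(rbind, lapply(models, model_rows))
}

#' Predicted-outcome interaction plot
#'
#' Predicted outcome versus the rsFC variable for each MeDi group, with
#' 95% confidence bands for the mean prediction, all other covariates held
#' at their analytic-sample means. Mirrors the usual way a group-by-slope
#' moderation is displayed.
#'
#' @param analytic Analytic table.
#' @param model A `dc_model` from [interaction_model()].
#' @param rsfc_var Connectivity column used in the model.
#' @param file Optional PDF path; when given the plot is written there.
#' @return Invisibly, the data frame of predictions.
#' @export
plot_interaction <- function(analytic, model, rsfc_var = "overall_z",
                             file = NULL) {
  fit <- model$fit
  cn <- names(fit$coefficients)
  zr <- range(analytic[[rsfc_var]])
  zs <- seq(zr[1], zr[2], length.out = 50)
  groups <- levels(analytic$medi_group)
  covs <- setdiff(cn, c(
    "(Intercept)", "rsfc", paste0("medi_", groups),
    paste0("rsfc:medi_", groups)
  ))
  cov_means <- vapply(covs, function(v) mean(analytic[[v]]), numeric(1))
  preds <- list()
  for (g in groups) {
    X <- matrix(0, length(zs), length(cn), dimnames = list(NULL, cn))
    X[, "(Intercept)"] <- 1
    X[, "rsfc"] <- zs
    dg <- paste0("medi_", g)
    if (dg %in% cn) {
      X[, dg] <- 1
      X[, paste0("rsfc:", dg)] <- zs
    }
    X[, covs] <- rep(cov_means, each = length(zs))
    mu <- drop(X %*% fit$coefficients)
    se <- sqrt(rowSums((X %*% fit$vcov) * X))
    preds[[g]] <- data.frame(
      group = g, rsfc = zs, fit = mu,
      lower = mu - fit$crit * se, upper = mu + fit$crit * se
    )
  }
  pd <- do.call(rbind, preds)
  draw <- function() {
    cols <- setNames(c("#D55E00", "#0072B2", "#009E73"), groups)
    ylim <- range(pd$lower, pd$upper)
    plot(NA,
      xlim = zr, ylim = ylim, xlab = rsfc_var,
      ylab = paste("predicted", model$outcome),
      main = paste0(
        model$outcome, " ~ ", rsfc_var, " by MeDi group (n = ", model$n, ")"
      )
    )
    for (g in groups) {
      p <- preds[[g]]
      polygon(c(p$rsfc, rev(p$rsfc)), c(p$lower, rev(p$upper)),
        col = adjustcolor(cols[g], 0.2), border = NA
      )
      lines(p$rsfc, p$fit, col = cols[g], lwd = 2)
    }
    legend("topright", legend = groups, col = cols, lwd = 2, bty = "n")
  }
  if (!is.null(file)) {
    pdf(file, width = 7, height = 5)
    on.exit(dev.off())
    draw()
  } else {
    draw()
  }
  invisible(pd)
}

#' Write publication-style tables and the interaction figure
#'
#' Produces the four standard tables as CSV files plus the interaction
#' figure: group descriptives; overall interaction coefficients per
#' reference ability; stratified rsFC slopes; continuous food-type
#' interactions.
#'
#' @param results A result list from [run_pipeline()].
#' @param dir Output directory.
#' @return Character vector of file paths written, invisibly.
#' @export
render_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(results$descriptives, "table1_descriptives.csv")

  t2 <- do.call(rbind, lapply(results$interaction, function(m) {
    tm <- model_term(m, "rsfc:medi_moderate")
    th <- model_term(m, "rsfc:medi_high")
    data.frame(
      outcome = m$outcome, joint_p = m$joint$p,
      B_moderate = tm$B, LL_moderate = tm$LL, UL_moderate = tm$UL,
      p_moderate = tm$p,
      B_high = th$B, LL_high = th$LL, UL_high = th$UL, p_high = th$p,
      n = m$n, stringsAsFactors = FALSE
    )
  }))
  w(t2, "table2_interactions.csv")

  t3 <- do.call(rbind, lapply(results$stratified, function(m) {
    tr <- model_term(m, "rsfc")
    data.frame(
      outcome = m$outcome, stratum = sub("stratified:", "", m$label),
      B = tr$B, LL = tr$LL, UL = tr$UL, p = tr$p, n = m$n,
      stringsAsFactors = FALSE
    )
  }))
  w(t3, "table3_stratified.csv")

  t4 <- do.call(rbind, lapply(results$foodtype, function(m) {
    tr <- model_term(m, "rsfc:subscore")
    data.frame(
      outcome = m$outcome, subscore = sub("foodtype:", "", m$label),
      B = tr$B, LL = tr$LL, UL = tr$UL, p = tr$p, n = m$n,
      stringsAsFactors = FALSE
    )
  }))
  w(t4, "table4_foodtype.csv")

  fig <- file.path(dir, "figure1_interaction.pdf")
  plot_interaction(
    results$analytic, results$interaction[["FLUID"]],
    rsfc_var = results$rsfc_var, file = fig
  )
  paths <- c(paths, fig)
  invisible(paths)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> score MeDi -> score reference abilities -> (full mode:
#' connectivity reduction) -> assemble -> model -> report. Every output file
#' is listed in the run manifest together with the seed, the configuration
#' hash and the under-specified constants in force (FD threshold, FFQ
#' cutpoints, processing order, interval flavour), so a rerun with the same
#' configuration reproduces the analytic tables byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param fast Fast mode (skip time-series stage; default `TRUE`).
#' @param scans Optional character subset of `c("network", "pairwise")`
#'   requesting the exploratory scans (full mode only).
#' @param sensitivity_scrub Optional scrub-percentage cut; when given the
#'   models are refit on the filtered sample and written alongside.
#' @param ci Interval flavour for all models.
#' @param fd_threshold_mm,min_distance_mm Connectivity-stage parameters.
#' @return Invisibly, a list with `analytic`, `flow`, `models`,
#'   `descriptives`, `interaction`, `stratified`, `foodtype`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, fast = TRUE, scans = character(),
                         sensitivity_scrub = NULL, ci = "wald",
                         fd_threshold_mm = 0.5, min_distance_mm = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch(
    {
      cohort <- generate_cohort(config, fast = fast)
      write_cohort(cohort, file.path(out_dir, "inputs"))

      stage <- "score-medi"
      medi <- score_medi(cohort$ffq, config$cutpoints)

      stage <- "cognition"
      ra <- score_ra_table(cohort$tasks, cohort$norms)

      stage <- "connectivity"
      rsfc <- NULL
      if (!fast) {
        rsfc <- summarize_cohort_connectivity(
          cohort,
          fd_threshold_mm = fd_threshold_mm,
          min_distance_mm = min_distance_mm
        )
        write.csv(rsfc, file.path(out_dir, "summaries.csv"), row.names = FALSE)
      }

      stage <- "assemble"
      asm <- assemble_analytic(cohort$participants, medi, ra, rsfc)
      analytic <- asm$analytic
      write.csv(analytic, file.path(out_dir, "analytic.csv"), row.names = FALSE)
      jsonlite::write_json(
        as.list(asm$flow), file.path(out_dir, "flow_report.json"),
        auto_unbox = TRUE
      )

      stage <- "analyze"
      outcomes <- c("FLUID", "MEMORY", "VOCAB", "SPEED")
      interaction <- lapply(
        setNames(nm = outcomes),
        function(o) interaction_model(analytic, o, ci = ci)
      )
      stratified <- list()
      for (o in outcomes) {
        for (g in levels(analytic$medi_group)) {
          stratified[[paste(o, g, sep = ".")]] <-
            stratified_model(analytic, o, group = g, ci = ci)
        }
      }
      foodtype <- list(
        beneficial = foodtype_interaction(analytic, subscore = "beneficial", ci = ci),
        detrimental = foodtype_interaction(analytic, subscore = "detrimental", ci = ci)
      )
      main_effect <- medi_main_effect_on_rsfc(analytic, ci = ci)
      threeway <- list(
        age = threeway_interaction(analytic, modifier = "age", ci = ci),
        gender = threeway_interaction(analytic, modifier = "gender", ci = ci)
      )
      models <- c(
        list(main_effect), interaction, stratified, foodtype, threeway
      )
      mt <- models_table(models)
      if ("network" %in% scans) {
        sc <- network_level_scan(analytic)
        for (k in names(sc)) {
          mt <- rbind(mt, model_rows(sc[[k]]$interaction))
        }
      }
      if ("pairwise" %in% scans) {
        pw <- pairwise_scan(analytic)
        write.csv(pw, file.path(out_dir, "pairwise_scan.csv"), row.names = FALSE)
      }
      write.csv(mt, file.path(out_dir, "models.csv"), row.names = FALSE)

      if (!is.null(sensitivity_scrub)) {
        sens <- sensitivity_filter(analytic, sensitivity_scrub)
        sens_models <- lapply(
          setNames(nm = outcomes),
          function(o) interaction_model(sens, o, ci = ci)
        )
        write.csv(
          models_table(sens_models),
          file.path(out_dir, "models_sensitivity.csv"),
          row.names = FALSE
        )
      }

      stage <- "report"
      descriptives <- group_descriptives(analytic)
      results <- list(
        analytic = analytic, flow = asm$flow, models = mt,
        descriptives = descriptives, interaction = interaction,
        stratified = stratified, foodtype = foodtype,
        rsfc_var = "overall_z"
      )
      render_tables(results, file.path(out_dir, "tables"))
      results
    },
    error = function(e) {
      partial <- list(
        failed_stage = stage, error = conditionMessage(e),
        seed = config$seed, config_hash = config_hash(config)
      )
      jsonlite::write_json(
        partial, file.path(out_dir, "manifest_partial.json"),
        auto_unbox = TRUE
      )
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )

  manifest <- list(
    package = "dietconn",
    version = as.character(packageVersion("dietconn")),
    seed = config$seed,
    config_hash = config_hash(config),
    fast = fast,
    stages = list(
      inputs = file.path(out_dir, "inputs"),
      analytic = file.path(out_dir, "analytic.csv"),
      flow = file.path(out_dir, "flow_report.json"),
      models = file.path(out_dir, "models.csv"),
      tables = file.path(out_dir, "tables")
    ),
    decisions = list(
      fd_threshold_mm = fd_threshold_mm,
      min_distance_mm = min_distance_mm,
      cutpoints = config$cutpoints,
      filter = "zero-phase 4th-order Butterworth magnitude (FFT), 0.01-0.08 Hz",
      processing_order = "scrub -> band-pass -> nuisance regression",
      ci = ci,
      interaction_joint_test = "2-df Wald",
      alpha_main = 0.05, alpha_interaction = 0.10
    )
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  res$manifest <- manifest
  invisible(res)
}
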