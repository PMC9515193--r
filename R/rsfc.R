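# ROI time series -> Fisher-z connectivity -> internetwork summaries.
#
# Processing order (configurable inputs, fixed order): framewise displacement
# -> scrubbing (volume replacement by interpolation) -> zero-phase band-pass
# 0.01-0.08 Hz -> nuisance regression (FD, BOLD rms-difference, left/right
# white matter, ventricles; traces filtered identically before regression).

#' Canonical network labels
#'
#' The 10 large-scale networks used for internetwork summaries, in canonical
#' order: somatomotor hand (`Hand`), visual (`Vis`), somatomotor mouth
#' (`Mouth`), auditory (`Aud`), default mode (`DMN`), salience (`Sal`),
#' cingulo-opercular (`CO`), frontoparietal (`FP`), dorsal attention
#' (`DAN`) and ventral attention (`VAN`). ROIs labelled `"excluded"` are
#' dropped before any summary.
#'
#' @return Character vector of the 10 network labels.
#' @export
dc_networks <- function() {
  c("Hand", "Vis", "Mouth", "Aud", "DMN", "Sal", "CO", "FP", "DAN", "VAN")
}

check_parcellation <- function(parcellation) {
  need <- c("roi_id", "x_mm", "y_mm", "z_mm", "network")
  if (!all(need %in% names(parcellation))) {
    stop("parcellation needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(parcellation$roi_id)) stop("duplicate ROI ids")
  coords <- as.matrix(parcellation[, c("x_mm", "y_mm", "z_mm")])
  if (any(!is.finite(coords))) stop("non-finite ROI coordinates")
  invisible(parcellation)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `fd[t] = sum |delta translation| + r * sum |delta rotation|`, the Power
#' convention: rotations (radians) are converted to arc length on a sphere of
#' radius `sphere_radius_mm`. The first frame has no predecessor and gets 0.
#'
#' @param motion Frames x 6 matrix: 3 translations (mm) then 3 rotations
#'   (radians).
#' @param sphere_radius_mm Head-radius for the rotation arc length
#'   (default 50).
#' @return Numeric FD trace (mm), one value per frame.
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("motion must have 6 columns (3 translations mm, 3 rotations rad)")
  }
  if (nrow(motion) < 2L) stop("need at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
    sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Replace motion-contaminated volumes
#'
#' Frames whose FD exceeds the threshold are replaced, per ROI, by linear
#' interpolation between the nearest clean neighbours (edge frames take the
#' nearest clean value). Frame count is unchanged; the fraction replaced is
#' returned as the scrub percentage.
#'
#' @param ts Frames x ROIs signal matrix.
#' @param fd FD trace from [framewise_displacement()].
#' @param fd_threshold_mm Positive censoring threshold in mm (default 0.5, a
#'   conventional value; the threshold itself is a tunable, not estimated).
#' @return List with `signal` (repaired matrix), `scrub_pct` (0-100) and the
#'   `fd` trace.
#' @export
scrub_and_replace <- function(ts, fd, fd_threshold_mm = 0.5) {
  ts <- as.matrix(ts)
  if (fd_threshold_mm <= 0) stop("FD threshold must be positive")
  if (length(fd) != nrow(ts)) stop("fd trace and signal disagree on frames")
  bad <- fd > fd_threshold_mm
  if (all(bad)) stop("every frame exceeds the FD threshold")
  out <- ts
  if (any(bad)) {
    good <- which(!bad)
    for (j in seq_len(ncol(ts))) {
      out[bad, j] <- approx(good, ts[good, j], xout = which(bad), rule = 2)$y
    }
  }
  list(signal = out, scrub_pct = 100 * mean(bad), fd = fd)
}

#' Zero-phase band-pass filter
#'
#' Removes the per-column mean and applies a zero-phase band-pass in the
#' frequency domain using a 4th-order Butterworth magnitude response (the
#' band, not a specific kernel, is the contract: DC and out-of-band
#' components are strongly attenuated, in-band components pass essentially
#' unchanged and without phase shift).
#'
#' @param ts Frames x columns matrix.
#' @param tr Repetition time in seconds.
#' @param f_low,f_high Pass band in Hz (defaults 0.01-0.08); must satisfy
#'   `f_low < f_high < 1/(2 tr)`.
#' @param order Butterworth order (default 4).
#' @return Filtered matrix, same dimensions.
#' @export
bandpass <- function(ts, tr, f_low = 0.01, f_high = 0.08, order = 4) {
  ts <- as.matrix(ts)
  nyquist <- 1 / (2 * tr)
  if (!(f_low > 0 && f_low < f_high && f_high < nyquist)) {
    stop("band must satisfy 0 < f_low < f_high < Nyquist = ", nyquist, " Hz")
  }
  n <- nrow(ts)
  ts <- sweep(ts, 2, colMeans(ts))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  hp <- ifelse(f == 0, 0, 1 / sqrt(1 + (f_low / pmax(f, 1e-12))^(2 * order)))
  lp <- 1 / sqrt(1 + (f / f_high)^(2 * order))
  h <- hp * lp
  out <- Re(mvfft(mvfft(ts) * h, inverse = TRUE)) / n
  dimnames(out) <- dimnames(ts)
  out
}

#' Root-mean-square frame-to-frame BOLD difference
#'
#' @param ts Frames x ROIs signal matrix.
#' @return Per-frame rms of the first difference across ROIs (first frame 0).
#' @export
rms_diff_trace <- function(ts) {
  ts <- as.matrix(ts)
  c(0, sqrt(rowMeans(diff(ts)^2)))
}

#' Regress nuisance traces out of every ROI time series
#'
#' Per-ROI ordinary least squares on the nuisance matrix plus an intercept;
#' the residuals (orthogonal to every nuisance column) are returned.
#'
#' @param ts Frames x ROIs matrix.
#' @param nuisance Frames x k nuisance matrix; must be full column rank after
#'   adding the intercept.
#' @return Residual matrix, same dimensions as `ts`.
#' @export
nuisance_regress <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts)) stop("nuisance and signal disagree on frames")
  x <- cbind(1, nuisance)
  if (qr(x)$rank < ncol(x)) stop("nuisance regressors are collinear")
  res <- lm.fit(x, ts)$residuals
  if (!is.matrix(res)) res <- matrix(res, nrow(ts), ncol(ts))
  dimnames(res) <- dimnames(ts)
  res
}

#' Run the full time-series processing chain
#'
#' FD computation, scrubbing, band-pass filtering, then nuisance regression
#' of FD, BOLD rms-difference and the supplied white-matter / ventricle
#' traces (all filtered with the same band-pass before regression).
#'
#' @param ts Frames x ROIs signal matrix.
#' @param motion Frames x 6 motion parameters (mm, mm, mm, rad, rad, rad).
#' @param nuisance Frames x 3 matrix: left white matter, right white matter,
#'   ventricles.
#' @param tr Repetition time (s).
#' @param fd_threshold_mm,f_low,f_high,sphere_radius_mm Stage parameters.
#' @return Object of class `dc_processed`: `signal` (residual series, frame
#'   count unchanged), `fd`, `scrub_pct`, `tr`.
#' @export
process_timeseries <- function(ts, motion, nuisance, tr,
                               fd_threshold_mm = 0.5,
                               f_low = 0.01, f_high = 0.08,
                               sphere_radius_mm = 50) {
  fd <- framewise_displacement(motion, sphere_radius_mm)
  sc <- scrub_and_replace(ts, fd, fd_threshold_mm)
  rms <- rms_diff_trace(sc$signal)
  sig <- bandpass(sc$signal, tr, f_low, f_high)
  nuis <- cbind(fd = fd, rms_diff = rms, as.matrix(nuisance))
  nuis <- bandpass(nuis, tr, f_low, f_high)
  resid <- nuisance_regress(sig, nuis)
  structure(
    list(signal = resid, fd = fd, scrub_pct = sc$scrub_pct, tr = tr),
    class = "dc_processed"
  )
}

#' Fisher-z connectivity matrix with exclusion masks
#'
#' Pearson correlation per ROI pair, clipped away from +/-1 and
#' Fisher-z-transformed (`atanh`). Pairs whose ROI centres lie strictly
#' within `min_distance_mm` of one another are set to zero and masked
#' (self-pairs included); non-positive z values are flagged so that only
#' strictly positive internetwork values ever enter a mean. A zeroed pair is
#' treated as excluded-from-averaging, never as a literal zero in a mean.
#'
#' @param ts Frames x ROIs matrix or a `dc_processed` object.
#' @param parcellation Data frame with `roi_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `network` (one row per ROI, same order as the columns of `ts`).
#' @param min_distance_mm Distance exclusion radius (default 20; exactly
#'   20 mm is retained).
#' @param clip Correlations are clipped to `+/- clip` before `atanh`.
#' @return Object of class `dc_connectivity`: symmetric `z` matrix,
#'   symmetric logical `excluded` mask (self and near pairs), `nonpositive`
#'   mask, `network` labels, `roi_id`.
#' @export
connectivity_matrix <- function(ts, parcellation, min_distance_mm = 20,
                                clip = 1 - 1e-7) {
  if (inherits(ts, "dc_processed")) ts <- ts$signal
  ts <- as.matrix(ts)
  check_parcellation(parcellation)
  if (nrow(ts) < 10L) stop("need at least 10 frames")
  if (ncol(ts) != nrow(parcellation)) {
    stop("ROI count mismatch between time series and parcellation")
  }
  if (any(apply(ts, 2, sd) == 0)) {
    stop("zero-variance ROI time series: correlation undefined")
  }
  r <- cor(ts)
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  d <- as.matrix(dist(parcellation[, c("x_mm", "y_mm", "z_mm")]))
  near <- d < min_distance_mm # includes the diagonal
  z[near] <- 0
  structure(
    list(
      z = z, excluded = near, nonpositive = z <= 0,
      network = as.character(parcellation$network),
      roi_id = parcellation$roi_id
    ),
    class = "dc_connectivity"
  )
}

#' Build a connectivity object from an explicit z matrix
#'
#' Mainly for toy examples and tests: wraps a symmetric Fisher-z matrix and
#' network labels into the container used by [internetwork_summaries()].
#'
#' @param z Symmetric numeric matrix.
#' @param network Character vector of network labels, one per ROI.
#' @param excluded Optional symmetric logical mask; defaults to the diagonal.
#' @return A `dc_connectivity` object.
#' @export
new_connectivity <- function(z, network, excluded = NULL) {
  z <- as.matrix(z)
  if (!isSymmetric(unname(z))) stop("z must be symmetric")
  if (length(network) != nrow(z)) stop("one network label per ROI required")
  if (is.null(excluded)) excluded <- diag(nrow(z)) == 1
  structure(
    list(
      z = z, excluded = excluded, nonpositive = z <= 0,
      network = as.character(network), roi_id = seq_len(nrow(z))
    ),
    class = "dc_connectivity"
  )
}

order_networks <- function(labels) {
  canon <- intersect(dc_networks(), labels)
  c(canon, setdiff(unique(labels), c(canon, "excluded")))
}

#' Internetwork connectivity summaries
#'
#' Means over the retained entries of a Fisher-z connectivity matrix:
#' entries are retained when they are not distance/self masked, strictly
#' positive, and connect two different networks (each unordered ROI pair
#' counted once). Reports the overall mean (edge-weighted over all retained
#' cross-network entries), one mean per network (entries with exactly one
#' endpoint in that network), and one mean per unordered network pair.
#' ROIs labelled `"excluded"` are dropped first. An empty retained set yields
#' `NA` with a warning, never a silent zero.
#'
#' @param cm A `dc_connectivity` object.
#' @param include_within If `TRUE` the overall mean also includes
#'   within-network pairs (alternative reading of "connectivity between all
#'   ROIs"); default `FALSE`, cross-network only.
#' @return Object of class `dc_internetwork`: `overall_z`, named
#'   `per_network_z`, named `pairwise_z` (names `"A.B"` in canonical network
#'   order), and `n_retained`.
#' @export
internetwork_summaries <- function(cm, include_within = FALSE) {
  stopifnot(inherits(cm, "dc_connectivity"))
  keep <- cm$network != "excluded"
  if (sum(keep) < 2L) stop("need at least 2 non-excluded ROIs")
  z <- cm$z[keep, keep, drop = FALSE]
  excl <- cm$excluded[keep, keep, drop = FALSE]
  net <- cm$network[keep]
  nets <- order_networks(net)
  if (length(nets) < 2L) stop("need at least 2 labelled networks")

  ut <- upper.tri(z)
  positive <- z > 0
  cross <- outer(net, net, "!=")
  overall_sel <- ut & !excl & positive & (cross | include_within)
  overall <- if (any(overall_sel)) {
    mean(z[overall_sel])
  } else {
    warning("no retained entries for the overall summary")
    NA_real_
  }

  per_network <- setNames(rep(NA_real_, length(nets)), nets)
  for (k in nets) {
    sel <- ut & !excl & positive & outer(net == k, net == k, xor)
    if (any(sel)) {
      per_network[k] <- mean(z[sel])
    } else {
      warning("no retained entries for network ", k)
    }
  }

  pairs <- combn(nets, 2)
  pairwise <- setNames(
    rep(NA_real_, ncol(pairs)),
    paste(pairs[1, ], pairs[2, ], sep = ".")
  )
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    sel <- ut & !excl & positive &
      (outer(net == a, net == b) | outer(net == b, net == a))
    if (any(sel)) {
      pairwise[j] <- mean(z[sel])
    } else {
      warning("no retained entries for network pair ", a, "-", b)
    }
  }

  structure(
    list(
      overall_z = overall, per_network_z = per_network,
      pairwise_z = pairwise, n_retained = sum(overall_sel)
    ),
    class = "dc_internetwork"
  )
}

#' Per-participant connectivity summaries for a synthetic cohort
#'
#' Runs [process_timeseries()], [connectivity_matrix()] and
#' [internetwork_summaries()] for every participant of a full-mode cohort
#' (see [generate_cohort()]) and returns one row per participant with the
#' overall, per-network (`net_*`) and pairwise (`pair_*`) Fisher-z means and
#' the scrub percentage.
#'
#' @param cohort A `dc_cohort` generated with `fast = FALSE`.
#' @param fd_threshold_mm,min_distance_mm Stage parameters.
#' @param tr Repetition time; defaults to the cohort's configured value.
#' @return Data frame of connectivity summaries.
#' @export
summarize_cohort_connectivity <- function(cohort, fd_threshold_mm = 0.5,
                                          min_distance_mm = 20, tr = NULL) {
  stopifnot(inherits(cohort, "dc_cohort"))
  if (is.null(cohort$timeseries)) {
    stop("cohort has no time series; it was generated in fast mode")
  }
  if (is.null(tr)) tr <- cohort$config$tr
  if (is.null(tr)) stop("supply `tr`: the cohort carries no configuration")
  ids <- names(cohort$timeseries)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    proc <- process_timeseries(
      cohort$timeseries[[id]], cohort$motion[[id]], cohort$nuisance[[id]],
      tr = tr, fd_threshold_mm = fd_threshold_mm
    )
    cm <- connectivity_matrix(proc, cohort$parcellation, min_distance_mm)
    s <- internetwork_summaries(cm)
    row <- data.frame(
      participant_id = id, overall_z = s$overall_z,
      scrub_pct = proc$scrub_pct, stringsAsFactors = FALSE
    )
    for (k in names(s$per_network_z)) row[[paste0("net_", k)]] <- s$per_network_z[[k]]
    for (k in names(s$pairwise_z)) row[[paste0("pair_", k)]] <- s$pairwise_z[[k]]
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
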