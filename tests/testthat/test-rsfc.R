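test_that("framewise displacement is the Power sum with arc-length rotations", {
  m <- matrix(0.2, 10, 6) # constant parameters -> no displacement
  expect_equal(framewise_displacement(m), rep(0, 10))

  m2 <- matrix(0, 10, 6)
  m2[5:10, 1] <- 0.3 # one 0.3 mm x-step
  fd <- framewise_displacement(m2)
  expect_equal(fd[5], 0.3)
  expect_equal(fd[-5], rep(0, 9))

  m3 <- matrix(0, 10, 6)
  m3[5:10, 4] <- 0.01 # one 0.01 rad rotation step -> 50 * 0.01 = 0.5 mm
  expect_equal(framewise_displacement(m3)[5], 0.5)
  expect_equal(framewise_displacement(m3, sphere_radius_mm = 100)[5], 1.0)

  expect_error(framewise_displacement(matrix(0, 10, 5)), "6 columns")
})

test_that("scrubbing replaces contaminated frames by linear interpolation", {
  set.seed(2)
  ts <- matrix(rnorm(300), 100, 3)
  fd <- rep(0.1, 100)
  clean <- scrub_and_replace(ts, fd, 0.5)
  expect_identical(clean$signal, ts)
  expect_equal(clean$scrub_pct, 0)

  fd[50] <- 2
  ts[49, 1] <- 2
  ts[51, 1] <- 4
  sc <- scrub_and_replace(ts, fd, 0.5)
  expect_equal(sc$scrub_pct, 1.0)
  expect_equal(sc$signal[50, 1], 3.0) # midpoint of clean neighbours
  expect_equal(sc$signal[-50, ], ts[-50, ]) # untouched elsewhere

  # edge frames take the nearest clean value
  fd2 <- rep(0, 100)
  fd2[1] <- 2
  sc2 <- scrub_and_replace(ts, fd2, 0.5)
  expect_equal(sc2$signal[1, ], ts[2, ])

  expect_error(scrub_and_replace(ts, rep(9, 100), 0.5), "every frame")
  expect_error(scrub_and_replace(ts, fd, 0), "positive")
})

test_that("band-pass passes the band and kills DC and high frequencies", {
  tr <- 2
  n <- 300
  t <- (0:(n - 1)) * tr

  # amplitude oracle: project onto the sin/cos pair at frequency f
  amp <- function(x, f) {
    2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
  }

  const <- matrix(5, n, 2)
  expect_lt(max(abs(bandpass(const, tr))), 1e-8 * 5)

  inband <- sin(2 * pi * 0.04 * t)
  out <- bandpass(cbind(inband), tr)
  expect_gte(amp(out[, 1], 0.04), 0.9 * amp(inband, 0.04))

  highf <- sin(2 * pi * 0.2 * t)
  outh <- bandpass(cbind(highf), tr)
  expect_lte(amp(outh[, 1], 0.2), 0.1 * amp(highf, 0.2))

  # transfer-function oracle: measured gain matches the 4th-order
  # Butterworth band magnitude at several probe frequencies
  for (f in c(0.02, 0.05, 0.1, 0.15)) {
    x <- sin(2 * pi * f * t)
    g <- amp(bandpass(cbind(x), tr)[, 1], f) / amp(x, f)
    href <- (1 / sqrt(1 + (0.01 / f)^8)) * (1 / sqrt(1 + (f / 0.08)^8))
    expect_equal(g, href, tolerance = 0.05)
  }

  expect_error(bandpass(const, tr, f_low = 0.05, f_high = 0.3), "Nyquist")
  expect_error(bandpass(const, tr, f_low = 0.1, f_high = 0.05), "Nyquist")
})

test_that("nuisance regression matches the normal-equation oracle", {
  set.seed(8)
  n <- 30
  nuis <- cbind(rnorm(n), rnorm(n), rnorm(n))
  ts <- matrix(rnorm(n * 4), n, 4)

  res <- nuisance_regress(ts, nuis)
  X <- cbind(1, nuis)
  oracle <- ts - X %*% solve(t(X) %*% X, t(X) %*% ts)
  expect_equal(unname(res), unname(oracle), tolerance = 1e-8)

  # residuals orthogonal to every nuisance column
  expect_lt(max(abs(t(res) %*% X)) / max(abs(ts)), 1e-6)

  # an ROI equal to a nuisance column is annihilated
  ts2 <- cbind(nuis[, 1], ts)
  expect_lt(max(abs(nuisance_regress(ts2, nuis)[, 1])), 1e-10)

  # a mean-zero ROI orthogonal to the nuisance set passes unchanged
  ortho <- residuals(lm(rnorm(n) ~ X - 1))
  expect_equal(unname(nuisance_regress(cbind(ortho), nuis)[, 1]),
    unname(ortho),
    tolerance = 1e-10
  )

  expect_error(nuisance_regress(ts, cbind(nuis, nuis[, 1])), "collinear")
})

test_that("connectivity matrix: Fisher z, distance mask, zero-variance error", {
  set.seed(21)
  parc <- make_parcellation(2, c("A", "B"))
  ts <- matrix(rnorm(400), 100, 4)

  cm <- connectivity_matrix(ts, parc)
  r <- cor(ts)
  expect_equal(cm$z[1, 3], atanh(r[1, 3]))
  expect_true(isSymmetric(cm$z))
  expect_true(all(diag(cm$excluded)))

  # ROIs 15 mm apart are masked and zeroed regardless of correlation
  parc2 <- parc
  parc2$x_mm[2] <- parc2$x_mm[1] + 15
  cm2 <- connectivity_matrix(ts, parc2)
  expect_true(cm2$excluded[1, 2])
  expect_equal(cm2$z[1, 2], 0)
  # exactly 20 mm is retained (strict inequality)
  parc3 <- parc
  parc3$x_mm[2] <- parc3$x_mm[1] + 20
  expect_false(connectivity_matrix(ts, parc3)$excluded[1, 2])

  ts0 <- ts
  ts0[, 2] <- 7
  expect_error(connectivity_matrix(ts0, parc), "zero-variance")
  expect_error(connectivity_matrix(ts[1:5, ], parc), "10 frames")
})

test_that("internetwork summaries implement positive-only cross-network means", {
  # 2 networks x 2 ROIs toy with cross z {0.3, -0.1, 0.5, 0.2}: the retained
  # set is {0.3, 0.5, 0.2} and the mean is exactly 1/3
  z <- matrix(0, 4, 4)
  z[1, 2] <- z[2, 1] <- 0.9 # within A, never counted
  z[3, 4] <- z[4, 3] <- 0.8 # within B, never counted
  z[1, 3] <- z[3, 1] <- 0.3
  z[1, 4] <- z[4, 1] <- -0.1
  z[2, 3] <- z[3, 2] <- 0.5
  z[2, 4] <- z[4, 2] <- 0.2
  cm <- new_connectivity(z, c("A", "A", "B", "B"))
  s <- internetwork_summaries(cm)
  expect_equal(s$overall_z, 1 / 3)
  expect_equal(s$n_retained, 3L)
  expect_equal(unname(s$per_network_z), rep(1 / 3, 2))
  expect_equal(unname(s$pairwise_z["A.B"]), 1 / 3)

  # include_within folds the within-network entries in
  sw <- internetwork_summaries(cm, include_within = TRUE)
  expect_equal(sw$overall_z, (0.3 + 0.5 + 0.2 + 0.9 + 0.8) / 5)

  # an empty retained set warns and yields NA, not zero
  zneg <- -abs(z)
  diag(zneg) <- 0
  w <- capture_warnings(
    sneg <- internetwork_summaries(new_connectivity(zneg, c("A", "A", "B", "B")))
  )
  expect_true(any(grepl("no retained", w)))
  expect_true(is.na(sneg$overall_z))

  # "excluded" ROIs are dropped before any summary
  z5 <- rbind(cbind(z, 2), 2)
  diag(z5) <- 0
  cm5 <- new_connectivity(z5, c("A", "A", "B", "B", "excluded"))
  expect_equal(internetwork_summaries(cm5)$overall_z, 1 / 3)
})

test_that("summaries are invariant to ROI order and reconstruct from pairs", {
  set.seed(31)
  parc <- make_parcellation(3, c("A", "B", "C"))
  ts <- matrix(rnorm(9 * 120), 120, 9) +
    0.4 * matrix(rnorm(120), 120, 9) # shared component -> positive r
  cm <- connectivity_matrix(ts, parc)
  s <- internetwork_summaries(cm)

  perm <- sample(9)
  cmp <- connectivity_matrix(ts[, perm], parc[perm, ])
  sp <- internetwork_summaries(cmp)
  expect_equal(sp$overall_z, s$overall_z)
  expect_equal(sp$per_network_z[names(s$per_network_z)], s$per_network_z)

  # weighted-mean consistency: pairwise means x retained counts rebuild the
  # overall mean exactly (counts recomputed by independent enumeration)
  net <- parc$network
  num <- den <- 0
  for (a in 1:8) {
    for (b in (a + 1):9) {
      if (net[a] != net[b] && cm$z[a, b] > 0 && !cm$excluded[a, b]) {
        num <- num + cm$z[a, b]
        den <- den + 1
      }
    }
  }
  expect_equal(s$overall_z, num / den)

  # per-network mean equals direct enumeration for network A
  selA <- vapply(1:8, function(a) {
    vapply((a + 1):9, function(b) {
      xor(net[a] == "A", net[b] == "A") && net[a] != net[b] &&
        cm$z[a, b] > 0 && !cm$excluded[a, b]
    }, logical(1)) |> any()
  }, logical(1))
  manual <- mean(unlist(lapply(1:8, function(a) {
    unlist(lapply((a + 1):9, function(b) {
      if (xor(net[a] == "A", net[b] == "A") && cm$z[a, b] > 0 &&
        !cm$excluded[a, b]) {
        cm$z[a, b]
      } else {
        NULL
      }
    }))
  })))
  expect_equal(unname(s$per_network_z["A"]), manual)
})

test_that("pipeline composition recovers a planted cross-network correlation", {
  cfg <- sim_config(
    parcellation = make_parcellation(5, c("A", "B")),
    n_frames = 285, seed = 99
  )
  # independence: zero within- and cross-network correlation
  cfg0 <- sim_config(
    parcellation = make_parcellation(5, c("A", "B")),
    rho_within = 0, rsfc_mean = 0, rsfc_sd = 0,
    nuisance_loading = 0, n_frames = 800, seed = 99
  )
  set.seed(1)
  p0 <- generate_roi_timeseries(0, cfg0)
  r0 <- cor(p0$signal)
  off <- r0[1:5, 6:10]
  expect_lt(mean(abs(off)), 3 / sqrt(800))

  # monotonicity plus Monte-Carlo recovery: higher planted rho -> higher
  # recovered overall z, and recovery is centred on atanh(rho)
  recover <- function(rho, reps = 12) {
    mean(vapply(seq_len(reps), function(i) {
      set.seed(1000 + i)
      p <- generate_roi_timeseries(atanh(rho), cfg)
      proc <- process_timeseries(p$signal, p$motion, p$nuisance, tr = cfg$tr)
      internetwork_summaries(
        connectivity_matrix(proc, cfg$parcellation)
      )$overall_z
    }, numeric(1)))
  }
  z25 <- recover(0.25)
  z40 <- recover(0.40)
  expect_gt(z40, z25)
  expect_equal(z25, atanh(0.25), tolerance = 0.03)

  # inserting an identity stage changes nothing
  set.seed(77)
  p <- generate_roi_timeseries(atanh(0.25), cfg)
  proc <- process_timeseries(p$signal, p$motion, p$nuisance, tr = cfg$tr)
  s1 <- internetwork_summaries(connectivity_matrix(proc, cfg$parcellation))
  s2 <- internetwork_summaries(connectivity_matrix(proc$signal + 0, cfg$parcellation))
  expect_equal(s1$overall_z, s2$overall_z)
})

test_that("process_timeseries bookkeeping: frames kept, scrub percentage", {
  cfg <- sim_config(
    parcellation = make_parcellation(2, c("A", "B")),
    n_frames = 100, n_spike_frames = 2, seed = 13
  )
  set.seed(13)
  p <- generate_roi_timeseries(atanh(0.2), cfg)
  proc <- process_timeseries(p$signal, p$motion, p$nuisance, tr = cfg$tr)
  expect_identical(nrow(proc$signal), 100L)
  expect_gt(proc$scrub_pct, 0)
  expect_lte(proc$scrub_pct, 100)

  # no spikes -> FD stays below the censoring threshold everywhere
  cfg0 <- sim_config(
    parcellation = make_parcellation(2, c("A", "B")),
    n_frames = 100, n_spike_frames = 0, seed = 13
  )
  set.seed(13)
  p0 <- generate_roi_timeseries(atanh(0.2), cfg0)
  fd <- framewise_displacement(p0$motion)
  expect_true(all(fd < 0.5))
  proc0 <- process_timeseries(p0$signal, p0$motion, p0$nuisance, tr = cfg0$tr)
  expect_equal(proc0$scrub_pct, 0)
})
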