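test_that("cardiac phantom encodes healthy and pathological myocardium", {
  ph <- make_cardiac_phantom(64, "healthy")
  myo <- ph$properties[ph$properties$tissue == "myocardium", ]
  expect_equal(c(myo$t1_ms, myo$t2_ms, myo$t2star_ms, myo$pdff),
               c(950, 48, 30, 0.01))
  pp <- make_cardiac_phantom(64, "pathPDFF")
  mp <- pp$properties[pp$properties$tissue == "myocardium", ]
  expect_equal(mp$pdff, 0.10)
  expect_equal(c(mp$t1_ms, mp$t2_ms, mp$t2star_ms), c(950, 48, 30))
  p1 <- make_cardiac_phantom(64, "pathT1")
  expect_equal(p1$properties$t1_ms[p1$properties$tissue == "myocardium"], 1250)
  # referential integrity: every label has a property row
  expect_true(all(unique(ph$label[ph$label > 0]) %in% ph$properties$label))
  expect_gt(sum(ph$label == 2), 20)
  expect_error(make_cardiac_phantom(64, "unknown"))
  expect_error(make_cardiac_phantom(16), "at least 32")
})

test_that("vial phantom is the full factorial of the four property levels", {
  vp <- make_vial_phantom(96)
  expect_equal(nrow(vp$properties), 36)
  expect_equal(length(unique(vp$label[vp$label > 0])), 36)
  g <- vp$properties
  expect_equal(sort(unique(g$t1_ms)), c(300, 800, 1200))
  expect_equal(sort(unique(g$t2_ms)), c(30, 70, 150))
  expect_equal(sort(unique(g$t2star_ms)), c(15, 30))
  expect_equal(sort(unique(g$pdff)), c(0.05, 0.15))
  combo <- paste(g$t1_ms, g$t2_ms, g$t2star_ms, g$pdff)
  expect_equal(length(unique(combo)), 36)
  expect_equal(sum(combo == "300 30 15 0.05"), 1)
  expect_true(all(g$fat_t1_ms == 250 & g$fat_t2_ms == 60 & g$fat_t2star_ms == 20))
  expect_error(make_vial_phantom(32), "at least 64")
})

test_that("simulation is deterministic and linear in spin density", {
  n <- 32
  sched <- cmrf_schedule(rep(600, 2), exc_per_heartbeat = 4)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 8)
  ph <- disk_phantom(n, t2star = 30)
  rf1 <- rf_pulse_spec(n_subslices = 1)
  ks1 <- simulate_acquisition(ph, sched, geom, NULL, noise_pct = 0.02,
                              seed = 7, rf = rf1)
  ks2 <- simulate_acquisition(ph, sched, geom, NULL, noise_pct = 0.02,
                              seed = 7, rf = rf1)
  expect_identical(ks1$segments, ks2$segments)
  ph2 <- ph; ph2$properties$m0 <- 2
  ksa <- simulate_acquisition(ph, sched, geom, NULL, rf = rf1)
  ksb <- simulate_acquisition(ph2, sched, geom, NULL, rf = rf1)
  for (e in c(1, 12, 24)) {
    expect_equal(ksb$segments[[e]], 2 * ksa$segments[[e]], tolerance = 1e-12)
  }
  expect_error(simulate_acquisition(ph, sched, geom, NULL, noise_pct = -1),
               "nonnegative")
})

test_that("realized noise level matches the requested fraction within 5%", {
  n <- 32
  sched <- cmrf_schedule(rep(600, 2), exc_per_heartbeat = 4)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 8)
  ph <- disk_phantom(n, t2star = 30)
  rf1 <- rf_pulse_spec(n_subslices = 1)
  ks0 <- simulate_acquisition(ph, sched, geom, NULL, rf = rf1)
  ks <- simulate_acquisition(ph, sched, geom, NULL, noise_pct = 0.025,
                             seed = 3, rf = rf1)
  peak <- max(vapply(ks0$segments, function(s) max(abs(s)), numeric(1)))
  resid <- unlist(lapply(seq_along(ks$segments), function(e)
    as.vector(ks$segments[[e]] - ks0$segments[[e]])))
  realized <- sqrt(mean(abs(resid)^2))
  expect_lt(abs(realized - 0.025 * peak) / (0.025 * peak), 0.05)
})

test_that("k-space at echo centers equals the transform of the weighted phantom", {
  # noiseless, no fat, no off-resonance, single coil: at each echo-center
  # sample the signal is fingerprint x decay x spatial transform of the disk
  n <- 32
  sched <- cmrf_schedule(rep(600, 2), exc_per_heartbeat = 4)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 1)
  ph <- disk_phantom(n, t2star = 40)
  rf1 <- rf_pulse_spec(n_subslices = 1)
  ks <- simulate_acquisition(ph, sched, geom, NULL, rf = rf1)
  fp <- as.vector(epg_fingerprints(950, 48, sched, rf1))
  disk <- matrix(0 + 0i, n, n); disk[ph$label == 1] <- 1
  e <- 10
  tms <- rosettecmrf:::segment_times(geom, e)
  ic <- which.min(abs(tms - geom$echoes$echo_time_ms[e]))  # echo-center sample
  m_e <- length(tms)
  pl <- rosettecmrf:::segment_plan(geom, e)
  ref_all <- nufft_forward(disk, pl)
  for (exc in c(1, 5)) {
    row <- (exc - 1) * m_e + ic
    expected <- fp[exc] * exp(-geom$echoes$echo_time_ms[e] / 40) * ref_all[row]
    expect_equal(ks$segments[[e]][row, 1], expected, tolerance = 0.01)
  }
})

test_that("confounder correlation analysis flags only on-target dependencies", {
  tp <- make_vial_phantom(96)$properties
  # measured = simulated exactly: diagonal unity
  meas <- tp[, c("t1_ms", "t2_ms", "t2star_ms", "pdff")]
  cc <- confounder_pcc(tp, meas)
  expect_equal(unname(diag(cc$r)), rep(1, 4))
  expect_true(all(diag(cc$significant)))
  expect_error(confounder_pcc(tp[1:2, ], meas[1:2, ]), "3 vials")
  # independent random measurements: diagonal not significant in >= 90% of
  # Monte-Carlo repeats (level check of the test itself)
  set.seed(8)
  reps <- 400
  hits <- numeric(4)
  for (r in seq_len(reps)) {
    mr <- data.frame(t1_ms = rnorm(36), t2_ms = rnorm(36),
                     t2star_ms = rnorm(36), pdff = rnorm(36))
    cr <- suppressWarnings(confounder_pcc(tp, mr))
    hits <- hits + !diag(cr$significant)
  }
  expect_true(all(hits / reps >= 0.9))
})
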