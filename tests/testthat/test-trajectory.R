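traj <- rosette_trajectory()

test_that("rosette geometry matches the design: crossings, rotation, extent", {
  expect_equal(count_origin_crossings(traj), 24)
  expect_equal(180 * traj$w2_cycles / traj$w1_cycles, 117.391, tolerance = 1e-4)
  k <- sqrt(traj$kx^2 + traj$ky^2)
  expect_true(all(k <= traj$kmax + 1e-9))
  expect_equal(traj$kx[1], 0)
  expect_equal(traj$ky[1], 0)
  # toy rosette: 3 lobes -> 4 crossings
  toy <- rosette_trajectory(kmax = 100, w1_cycles = 1.5, w2_cycles = 1,
                            readout_ms = 4, dt_us = 4)
  expect_equal(count_origin_crossings(toy), 4)
  expect_error(rosette_trajectory(kmax = -1), "positive")
})

test_that("azimuthal rotation between consecutive lobes follows w2/w1", {
  cross <- rosettecmrf:::origin_crossing_indices(traj)
  # direction of travel just after each crossing
  ang <- vapply(cross[-length(cross)], function(i) {
    atan2(traj$ky[i + 4] - traj$ky[i], traj$kx[i + 4] - traj$kx[i])
  }, numeric(1))
  d <- diff(ang) * 180 / pi
  d <- (d + 360) %% 180
  expect_equal(mean(abs(d - 117.391) < 1), 1, tolerance = 0.05)
})

test_that("echo splitting partitions the readout with two partial segments", {
  ech <- split_into_echoes(traj)
  expect_equal(nrow(ech), 24)
  expect_equal(sum(ech$is_full), 22)
  expect_false(ech$is_full[1])
  expect_false(ech$is_full[24])
  # partition without overlap, concatenation reproduces the ordering
  idx <- unlist(lapply(seq_len(nrow(ech)), function(i) ech$start[i]:ech$end[i]))
  expect_identical(idx, seq_along(traj$t_ms))
  # echo times sit at the analytic envelope zeros n*T/(2 w1)
  expected <- (0:23) * traj$readout_ms / (2 * traj$w1_cycles)
  expect_equal(ech$echo_time_ms, expected, tolerance = traj$dt_us / 1000)
  # spacing uniform to within one dwell
  expect_lt(max(abs(diff(ech$echo_time_ms) - diff(ech$echo_time_ms)[1])),
            traj$dt_us / 1000 + 1e-9)
  toy <- rosette_trajectory(kmax = 100, w1_cycles = 1.5, w2_cycles = 1,
                            readout_ms = 4, dt_us = 4)
  et <- split_into_echoes(toy)
  expect_equal(nrow(et), 4)
  expect_equal(sum(et$is_full), 2)
})

test_that("degenerate trajectories are rejected by the echo splitter", {
  t0 <- rosette_trajectory(kmax = 100, w1_cycles = 0.4, w2_cycles = 1,
                           readout_ms = 2, dt_us = 4)
  expect_error(split_into_echoes(t0), "degenerate")
})

test_that("off-resonance response: unity on resonance, fat strongly suppressed", {
  expect_equal(response_function(traj, 0), 1)
  expect_gt(response_function(traj, 1), 0.99)
  # numeric oracle at small f
  expect_equal(response_function(traj, 5),
               response_numeric_oracle(traj, 5), tolerance = 0.02)
  r220 <- response_function(traj, 220)
  expect_lt(r220, 0.1)
  expect_lt(abs(r220 - 0.03), 0.011)
  expect_lt(response_function(traj, 440), 0.1)
  expect_true(all(response_function(traj, c(-300, 300)) >= 0))
})

test_that("density weights compensate sampling: flat reconstruction of a flat image", {
  n <- 48
  sched <- cmrf_schedule(rep(600, 8), exc_per_heartbeat = 12)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 3)
  e <- geom$full[3]
  seg <- geom$echoes[e, ]
  w <- compute_dcf(seg, tr, geom$rotations, matrix = n)
  expect_true(all(w > 0))
  # denser center samples get smaller weights than sparse rim samples
  idx <- geom$echoes$start[e]:geom$echoes$end[e]
  r <- sqrt(tr$kx[idx]^2 + tr$ky[idx]^2)
  ru <- rep(r, length(geom$rotations))
  expect_lt(mean(w[ru < 0.2 * tr$kmax]), mean(w[ru > 0.8 * tr$kmax]))
  # round trip: flat image -> forward -> weighted adjoint -> flat center
  pl <- nufft_plan(Re(rosettecmrf:::segment_points(geom, e)),
                   Im(rosettecmrf:::segment_points(geom, e)), n)
  wseg <- rosettecmrf:::segment_dcf(geom, e)
  img <- matrix(1 + 0i, n, n)
  rec <- nufft_adjoint(wseg * nufft_forward(img, pl), pl)
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  ctr <- abs(rec[outer(xs^2, xs^2, "+") < 0.25^2])
  expect_lt((max(ctr) - min(ctr)) / mean(ctr), 0.1)
  expect_error(compute_dcf(geom$echoes[1, ], tr, geom$rotations),
               "unsupported")
})

test_that("gradient feasibility reporting and scaling laws", {
  rep1 <- check_gradient_feasibility(traj)
  expect_true(rep1$gradient_ok)   # 43 mT/m system limit
  expect_true(rep1$slew_ok)       # within 180 T/m/s per axis
  expect_gt(rep1$peak_gradient_mT_m, 10)
  # linear ramp: constant gradient, zero slew
  lin <- traj
  lin$kx <- seq(0, 100, length.out = length(traj$t_ms))
  lin$ky <- rep(0, length(traj$t_ms))
  rl <- check_gradient_feasibility(lin)
  expect_equal(rl$peak_slew_T_m_s, 0, tolerance = 1e-6)
  # doubling dwell halves the reported gradient for the same k-path
  slow <- traj; slow$dt_us <- 2 * traj$dt_us
  rs <- check_gradient_feasibility(slow)
  expect_equal(rs$peak_gradient_mT_m, rep1$peak_gradient_mT_m / 2,
               tolerance = 1e-9)
  expect_error(check_gradient_feasibility(traj, gmax_mT_m = -1), "positive")
  short <- rosette_trajectory()
  short$t_ms <- short$t_ms[1:2]; short$kx <- short$kx[1:2]; short$ky <- short$ky[1:2]
  expect_error(check_gradient_feasibility(short), "insufficient")
})

test_that("trajectory CSV/JSON round trip preserves the design", {
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(traj, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$kx, traj$kx)
  expect_equal(tr2$w1_cycles, traj$w1_cycles)
})
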