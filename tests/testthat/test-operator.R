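make_toy_op <- function(n = 32, n_coils = 2, rank = 3, b0_sd = 10, seed = 1,
                        b0_correction = TRUE) {
  sched <- cmrf_schedule(rep(600, 3), exc_per_heartbeat = 4)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 8)
  basis <- random_basis(12, rank, seed)
  set.seed(seed)
  b0 <- matrix(rnorm(n * n, sd = b0_sd), n, n)
  coils <- if (n_coils > 1) make_birdcage_coils(n, n_coils)
           else array(1 + 0i, c(n, n, 1))
  field <- field_model(b0, coils)
  list(op = cmrf_operator(geom, field, basis, b0_correction), geom = geom,
       basis = basis, field = field)
}

rand_images <- function(op, seed = 2) {
  set.seed(seed)
  d <- c(op$geom$matrix, op$geom$matrix, op$rank, op$n_echoes)
  array(stats::rnorm(prod(d)) + 1i * stats::rnorm(prod(d)), d)
}

rand_kspace <- function(y_template, seed = 3) {
  set.seed(seed)
  lapply(y_template, function(m)
    matrix(stats::rnorm(length(m)) + 1i * stats::rnorm(length(m)), nrow(m)))
}

test_that("forward and adjoint pass the dot-product test below 1e-6", {
  toy <- make_toy_op()
  x <- rand_images(toy$op)
  y <- operator_forward(toy$op, x)
  yr <- rand_kspace(y)
  xt <- operator_adjoint(toy$op, yr)
  lhs <- Re(rosettecmrf:::ksp_inner(yr, y))
  rhs <- Re(sum(Conj(xt) * x))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("operator is linear and maps zero to zero", {
  toy <- make_toy_op(n = 32, n_coils = 1, rank = 2)
  x <- rand_images(toy$op)
  z <- x * 0
  y0 <- operator_forward(toy$op, z)
  expect_equal(rosettecmrf:::ksp_norm2(y0), 0)
  x2 <- rand_images(toy$op, seed = 9)
  y_sum <- operator_forward(toy$op, x + 2i * x2)
  y_lin <- rosettecmrf:::ksp_lincomb(operator_forward(toy$op, x),
                                     operator_forward(toy$op, x2), 1, 2i)
  expect_lt(sqrt(rosettecmrf:::ksp_norm2(rosettecmrf:::ksp_lincomb(y_sum, y_lin, 1, -1)) /
                   rosettecmrf:::ksp_norm2(y_sum)), 1e-12)
  expect_equal(max(abs(operator_adjoint(toy$op, y0))), 0)
})

test_that("degenerate configuration reduces to a plain per-echo transform", {
  n <- 32
  sched <- cmrf_schedule(rep(600, 1), exc_per_heartbeat = 1)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 8)
  op <- cmrf_operator(geom, NULL, matrix(1 + 0i, 1, 1))
  set.seed(3)
  img <- matrix(rnorm(n * n) + 1i * rnorm(n * n), n, n)
  x <- array(0 + 0i, c(n, n, 1, op$n_echoes))
  for (j in seq_len(op$n_echoes)) x[, , 1, j] <- img
  y <- operator_forward(op, x)
  j <- 5
  pl <- rosettecmrf:::segment_plan(geom, op$full[j])
  expect_equal(y[[j]][, 1], nufft_forward(img, pl), tolerance = 1e-12)
})

test_that("B0 phase factor is conjugate-symmetric under field negation", {
  toyp <- make_toy_op(n = 32, n_coils = 1, rank = 2, b0_sd = 25, seed = 4)
  fieldm <- field_model(-toyp$field$b0_hz, toyp$field$coils)
  opm <- cmrf_operator(toyp$geom, fieldm, toyp$basis)
  for (j in c(1, 10)) {
    expect_equal(opm$phases[[j]], Conj(toyp$op$phases[[j]]))
  }
})

test_that("forward-adjoint of a point source peaks at the source", {
  toy <- make_toy_op(n = 32, n_coils = 1, rank = 1, b0_sd = 0)
  n <- 32
  x <- array(0 + 0i, c(n, n, 1, toy$op$n_echoes))
  x[20, 14, 1, ] <- 1
  psf <- operator_adjoint(toy$op, operator_forward(toy$op, x))
  img <- abs(psf[, , 1, 3])
  expect_equal(which.max(img), (14 - 1) * n + 20)
})

test_that("adjoint-forward of a disk resembles the disk under dense sampling", {
  n <- 32
  sched <- cmrf_schedule(rep(600, 8), exc_per_heartbeat = 12)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 4)
  op <- cmrf_operator(geom, NULL, random_basis(96, 2, 5))
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  disk <- matrix(0 + 0i, n, n)
  disk[outer(xs, xs, function(x, y) x^2 + y^2) < 0.09] <- 1
  x <- array(0 + 0i, c(n, n, 2, op$n_echoes))
  for (j in seq_len(op$n_echoes)) x[, , 1, j] <- disk
  dcf <- lapply(seq_along(op$full), function(j)
    rosettecmrf:::segment_dcf(geom, op$full[j]) * 96 * 160 / 4)
  g <- operator_adjoint(op, operator_forward(op, x), dcf = dcf)
  rec <- g[, , 1, 10]
  corr <- abs(sum(Conj(rec) * disk)) / sqrt(sum(abs(rec)^2) * sum(abs(disk)^2))
  expect_gt(corr, 0.95)
})

test_that("B0 correction lowers the residual of the true image on shifted data", {
  # simulate a disk with a uniform off-resonance; the operator with the
  # correct field explains the data better than the uncorrected operator
  n <- 32
  sched <- cmrf_schedule(rep(600, 4), exc_per_heartbeat = 6)
  tr <- rosette_trajectory(kmax = n / 0.6)
  geom <- cmrf_geometry(tr, sched, matrix = n, decimate = 6)
  phan <- disk_phantom(n, t2star = 30)
  rf1 <- rf_pulse_spec(n_subslices = 1)
  b0 <- matrix(30, n, n)
  field <- field_model(b0, array(1 + 0i, c(n, n, 1)))
  ks <- simulate_acquisition(phan, sched, geom, field, rf = rf1)
  fp <- as.vector(epg_fingerprints(950, 48, sched, rf1))
  basis <- matrix(fp / sqrt(sum(abs(fp)^2)), ncol = 1)
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  disk <- matrix(0 + 0i, n, n)
  disk[phan$label == 1] <- sqrt(sum(abs(fp)^2))
  op_on <- cmrf_operator(geom, field, basis, b0_correction = TRUE)
  op_off <- cmrf_operator(geom, field, basis, b0_correction = FALSE)
  te <- geom$echoes$echo_time_ms[geom$full]
  mk_x <- function(op) {
    x <- array(0 + 0i, c(n, n, 1, op$n_echoes))
    for (j in seq_len(op$n_echoes)) x[, , 1, j] <- disk * exp(-te[j] / 30)
    x
  }
  y <- rosettecmrf:::kspace_full_echoes(ks, op_on)
  r_on <- rosettecmrf:::ksp_norm2(
    rosettecmrf:::ksp_lincomb(operator_forward(op_on, mk_x(op_on)), y, 1, -1))
  r_off <- rosettecmrf:::ksp_norm2(
    rosettecmrf:::ksp_lincomb(operator_forward(op_off, mk_x(op_off)), y, 1, -1))
  expect_lt(r_on, 0.5 * r_off)
})
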