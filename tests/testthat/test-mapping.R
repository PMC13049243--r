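te22 <- 1.74 + 0.8 * (0:21)

decay_imgs <- function(W, F, t2w, t2f, te = te22, n = 2, fat_hz = 220) {
  s <- W * exp(-te / t2w) + F * exp(-te / t2f) * exp(1i * 2 * pi * fat_hz * te / 1000)
  array(rep(s, each = n * n), c(n, n, length(te)))
}

test_that("dual-exponential T2* fitting recovers noiseless components", {
  f <- fit_dual_t2star(decay_imgs(1, 0, 30, 20), te22)
  expect_lt(abs(f$t2star_w[1] - 30), 0.5)
  expect_lt(abs(f$amp_f[1]), 0.1)
  f2 <- fit_dual_t2star(decay_imgs(0.5, 0.5, 30, 20), te22)
  expect_lt(abs(f2$t2star_w[1] - 30) / 30, 0.1)
  expect_lt(abs(f2$t2star_f[1] - 20) / 20, 0.1)
  expect_equal(abs(f2$amp_w[1]), 0.5, tolerance = 0.05)
  expect_equal(abs(f2$amp_f[1]), 0.5, tolerance = 0.05)
})

test_that("T2* estimates are clamped to the physiological window", {
  f <- fit_dual_t2star(decay_imgs(1, 0, 1, 20), te22)
  expect_equal(f$t2star_w[1], 2.2)
  f2 <- fit_dual_t2star(decay_imgs(1, 0, 1e5, 20), te22)
  expect_lte(f2$t2star_w[1], 200)
  # clamping holds on arbitrary (noisy) inputs
  set.seed(4)
  noisy <- array(complex(real = rnorm(4 * 22), imaginary = rnorm(4 * 22)),
                 c(2, 2, 22))
  fn <- fit_dual_t2star(noisy, te22)
  expect_true(all(fn$t2star_w >= 2.2 & fn$t2star_w <= 200))
  expect_true(all(fn$t2star_f >= 2.2 & fn$t2star_f <= 200))
  expect_error(fit_dual_t2star(decay_imgs(1, 0, 30, 20)[, , 1:4], te22[1:4]),
               "6 echoes")
  # non-finite voxels are flagged invalid
  bad <- decay_imgs(1, 0, 30, 20)
  bad[1, 1, 3] <- NaN
  fb <- fit_dual_t2star(bad, te22)
  expect_true(fb$invalid[1, 1])
  expect_true(is.na(fb$amp_w[1, 1]))
})

test_that("IDEAL separation splits water and fat and conserves amplitude", {
  n <- 2; rank <- 3
  t2s <- list(t2star_w = matrix(30, n, n), t2star_f = matrix(20, n, n))
  b0 <- matrix(0, n, n)
  # subspace coefficients of a mixed voxel: coefficients scale both components
  cw <- c(1, -0.4, 0.2i); cf <- c(0.6, 0.1, -0.05)
  imgs <- array(0 + 0i, c(n, n, rank, 22))
  for (s in 1:rank) {
    imgs[, , s, ] <- decay_imgs(0.7 * cw[s], 0.3 * cf[s], 30, 20)
  }
  sep <- ideal_separate(imgs, b0, t2s, te22)
  for (s in 1:rank) {
    expect_equal(sep$water[1, 1, s], (0.7 * cw[s]) + 0i, tolerance = 0.01)
    expect_equal(sep$fat[1, 1, s], (0.3 * cf[s]) + 0i, tolerance = 0.01)
  }
  # water-only voxel: fat residue < 1%
  imgs0 <- array(0 + 0i, c(n, n, 1, 22))
  imgs0[, , 1, ] <- decay_imgs(1, 0, 30, 20)
  sep0 <- ideal_separate(imgs0, b0, t2s, te22)
  expect_lt(abs(sep0$fat[1, 1, 1]), 0.01 * abs(sep0$water[1, 1, 1]))
  # dephasing removal cannot shrink total amplitude below the observed signal
  expect_gte(abs(sep$water[1, 1, 1]) + abs(sep$fat[1, 1, 1]),
             abs(imgs[1, 1, 1, 1]) - 1e-9)
  expect_error(ideal_separate(imgs, b0, t2s, rep(5, 22)), "degenerate")
})

test_that("pattern matching: self-match, scale equivariance, tie rule", {
  sub <- fix_subspace_small()
  i <- which(sub$entries$t1_ms == 950 & sub$entries$t2_ms == 46)[1]
  atom <- sub$compressed[, i]
  n <- 2
  imgs <- array(0 + 0i, c(n, n, sub$rank))
  for (s in seq_len(sub$rank)) imgs[, , s] <- 3i * atom[s] * sub$norms[i]
  m <- pattern_match(imgs, sub)
  expect_equal(m$t1_ms[1, 1], 950)
  expect_equal(m$t2_ms[1, 1], 46)
  expect_equal(m$m0[1, 1], 3i, tolerance = 0.01)
  # all-zero voxel flagged and zeroed
  imgs[1, 2, ] <- 0
  m2 <- pattern_match(imgs, sub)
  expect_false(m2$mask[1, 2])
  expect_equal(m2$t1_ms[1, 2], 0)
  # deterministic lowest-index tie break on duplicated atoms
  dup <- sub
  dup$compressed <- cbind(atom, atom)
  dup$norms <- c(1, 1)
  dup$entries <- data.frame(t1_ms = c(1, 2), t2_ms = c(1, 2))
  md <- pattern_match(array(rep(atom, each = 4), c(2, 2, sub$rank)), dup)
  expect_true(all(md$t1_ms == 1))
})

test_that("pattern matching equals the brute-force oracle on small dictionaries", {
  sched <- fix_schedule()
  cfg <- dictionary_config(t1_grid_ms = seq(200, 2000, 60),
                           t2_grid_ms = seq(10, 200, 10))
  d <- build_dictionary(cfg, sched, fix_rf3())
  expect_lte(nrow(d$entries), 1000)
  sub <- compress_dictionary(d, 10)
  set.seed(5)
  for (k in 1:20) {
    i <- sample(nrow(d$entries), 1)
    sig180 <- d$signals[, i] * d$norms[i] * (0.5 + runif(1)) *
      exp(2i * pi * runif(1))
    sig180 <- sig180 + 0.001 * max(abs(sig180)) *
      (rnorm(180) + 1i * rnorm(180))
    oracle <- brute_force_match(sig180, d$signals, d$entries, d$norms)
    sigc <- as.vector(Conj(t(sub$basis)) %*% sig180)
    m <- pattern_match(array(rep(sigc, each = 1), c(1, 1, 10)), sub)
    expect_equal(m$t1_ms[1, 1], oracle$t1_ms)
    expect_equal(m$t2_ms[1, 1], oracle$t2_ms)
    expect_equal(m$m0[1, 1], oracle$m0, tolerance = 0.02)
  }
})

test_that("matching an atom plus noise lands within one grid step", {
  sub <- fix_subspace_small()
  i <- which(sub$entries$t1_ms == 950 & sub$entries$t2_ms == 46)[1]
  atom <- sub$compressed[, i]
  set.seed(6)
  hits <- 0
  for (k in 1:100) {
    sig <- atom + 0.01 * sqrt(sum(abs(atom)^2) / 10) *
      (rnorm(10) + 1i * rnorm(10))
    m <- pattern_match(array(sig, c(1, 1, 10)), sub)
    if (abs(m$t1_ms[1, 1] - 950) <= 25 && abs(m$t2_ms[1, 1] - 46) <= 4)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("fat-fraction estimator handles pure and balanced voxels", {
  w <- matrix(c(1, 0, 1, 0.2), 2, 2)
  f <- matrix(c(0, 1, 1, 0.8), 2, 2)
  pd <- compute_pdff(w + 0i, f + 0i)
  expect_equal(pd$pdff[1, 1], 0)
  expect_equal(pd$pdff[2, 1], 1)
  expect_equal(pd$pdff[1, 2], 0.5)
  expect_equal(pd$pdff[2, 2], 0.8)
  z <- compute_pdff(matrix(0 + 0i, 1, 1), matrix(0 + 0i, 1, 1))
  expect_false(z$valid[1, 1])
  expect_equal(z$pdff[1, 1], 0)
  expect_true(all(pd$pdff >= 0 & pd$pdff <= 1))
})
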