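# Voxelwise parameter mapping: dual-exponential T2* fitting along the echo
# dimension, IDEAL water/fat separation of the subspace-echo images, dot
# product pattern matching against the compressed dictionary, and the
# magnitude-discrimination PDFF estimator.

T2STAR_MIN <- 2.2
T2STAR_MAX <- 200

#' Dual-exponential fat/water T2* fitting
#'
#' Fits, per voxel, \eqn{S(TE) = W e^{-TE/T2^*_w} + F e^{-TE/T2^*_f}
#' e^{i 2\pi f_{fat} TE}} across the echo images of the first temporal
#' subspace (B0-demodulated input) by variable projection: the complex
#' amplitudes are solved linearly on a search grid over the two decay
#' constants (coarse grid refined locally around the optimum). Estimated
#' decay times are clamped to [2.2, 200] ms.
#'
#' @param echo_imgs Complex array (n, n, echoes): first-subspace echo images
#'   after off-resonance demodulation.
#' @param te_ms Echo times (ms).
#' @param fat_shift_hz Fat chemical shift (Hz).
#' @param mask Optional logical mask; unmasked voxels return NA amplitudes.
#' @param n_grid Coarse grid size per decay axis (default 12).
#' @return List of matrices `t2star_w`, `t2star_f` (ms), complex `amp_w`,
#'   `amp_f`.
#' @export
fit_dual_t2star <- function(echo_imgs, te_ms, fat_shift_hz = 220, mask = NULL,
                            n_grid = 12) {
  d <- dim(echo_imgs)
  n_e <- d[3]
  if (n_e < 6) stop("need at least 6 echoes", call. = FALSE)
  V <- d[1] * d[2]
  S <- t(matrix(echo_imgs, V, n_e))          # echoes x voxels
  bad <- !apply(is.finite(Re(S)) & is.finite(Im(S)), 2, all)
  S[, bad] <- 0
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  use <- as.vector(mask) & !bad
  te <- te_ms
  grid_w <- exp(seq(log(T2STAR_MIN), log(T2STAR_MAX), length.out = n_grid))
  grid_f <- exp(seq(log(T2STAR_MIN), log(80), length.out = n_grid))
  best <- varpro_t2star_grid(S, te, fat_shift_hz, grid_w, grid_f)
  # local refinement: shrinking per-voxel log-neighbourhoods around the optimum
  for (halfwidth in c(0.35, 0.12, 0.04)) {
    gw <- refine_grid(best$t2w, halfwidth, 5)
    gf <- refine_grid(best$t2f, halfwidth, 5)
    best <- varpro_t2star_pervoxel(S, te, fat_shift_hz, gw, gf, best)
  }
  t2w <- matrix(pmin(pmax(best$t2w, T2STAR_MIN), T2STAR_MAX), d[1], d[2])
  t2f <- matrix(pmin(pmax(best$t2f, T2STAR_MIN), T2STAR_MAX), d[1], d[2])
  aw <- matrix(best$aw, d[1], d[2])
  af <- matrix(best$af, d[1], d[2])
  aw[!mask | matrix(bad, d[1], d[2])] <- NA
  af[!mask | matrix(bad, d[1], d[2])] <- NA
  list(t2star_w = t2w, t2star_f = t2f, amp_w = aw, amp_f = af,
       invalid = matrix(bad, d[1], d[2]))
}

# residual minimization over a shared candidate grid (vectorized over voxels)
varpro_t2star_grid <- function(S, te, fat_hz, grid_w, grid_f) {
  V <- ncol(S)
  fat_ph <- exp(1i * 2 * pi * fat_hz * te / 1000)
  best_fit <- rep(-Inf, V)
  out <- list(t2w = rep(grid_w[1], V), t2f = rep(grid_f[1], V),
              aw = rep(0 + 0i, V), af = rep(0 + 0i, V))
  for (tw in grid_w) for (tf in grid_f) {
    a <- exp(-te / tw)
    bcol <- exp(-te / tf) * fat_ph
    sol <- ls2_solve(a, bcol, S)
    upd <- sol$fit > best_fit
    if (any(upd)) {
      best_fit[upd] <- sol$fit[upd]
      out$t2w[upd] <- tw; out$t2f[upd] <- tf
      out$aw[upd] <- sol$x1[upd]; out$af[upd] <- sol$x2[upd]
    }
  }
  out$fit <- best_fit
  out
}

# per-voxel refinement around individual optima: offsets are relative factors
varpro_t2star_pervoxel <- function(S, te, fat_hz, gw, gf, best) {
  V <- ncol(S)
  fat_ph <- exp(1i * 2 * pi * fat_hz * te / 1000)
  best_fit <- best$fit
  out <- best
  for (i in seq_len(ncol(gw))) for (j in seq_len(ncol(gf))) {
    tw <- gw[, i]; tf <- gf[, j]
    # design varies per voxel: compute projections via explicit sums
    A <- exp(-outer(te, 1 / tw))            # echoes x voxels
    B <- exp(-outer(te, 1 / tf)) * fat_ph
    sol <- ls2_solve_mat(A, B, S)
    upd <- sol$fit > best_fit
    if (any(upd)) {
      best_fit[upd] <- sol$fit[upd]
      out$t2w[upd] <- tw[upd]; out$t2f[upd] <- tf[upd]
      out$aw[upd] <- sol$x1[upd]; out$af[upd] <- sol$x2[upd]
    }
  }
  out$fit <- best_fit
  out
}

refine_grid <- function(center, halfwidth, m) {
  # per-voxel multiplicative neighbourhood around the current estimate
  fac <- exp(seq(-halfwidth, halfwidth, length.out = m))
  sapply(fac, function(f) pmin(pmax(center * f, T2STAR_MIN), T2STAR_MAX))
}

# two-column complex least squares, shared design (a, b real/complex vectors)
ls2_solve <- function(a, b, S) {
  g11 <- sum(a * a)
  g12 <- sum(a * Conj(b))
  g22 <- sum(abs(b)^2)
  c1 <- as.vector(a %*% S)                  # a real
  c2 <- as.vector(Conj(b) %*% S)
  det <- Re(g11 * g22 - abs(g12)^2)
  det <- max(det, 1e-12)
  x1 <- (g22 * c1 - Conj(g12) * c2) / det
  x2 <- (g11 * c2 - g12 * c1) / det
  fit <- Re(Conj(x1) * c1 + Conj(x2) * c2)
  list(x1 = x1, x2 = x2, fit = fit)
}

# two-column complex least squares, per-voxel designs (matrices echoes x V)
ls2_solve_mat <- function(A, B, S) {
  g11 <- colSums(A * A)
  g12 <- colSums(A * Conj(B))
  g22 <- colSums(abs(B)^2)
  c1 <- colSums(A * S)
  c2 <- colSums(Conj(B) * S)
  det <- pmax(Re(g11 * g22 - abs(g12)^2), 1e-12)
  x1 <- (g22 * c1 - Conj(g12) * c2) / det
  x2 <- (g11 * c2 - g12 * c1) / det
  fit <- Re(Conj(x1) * c1 + Conj(x2) * c2)
  list(x1 = x1, x2 = x2, fit = fit)
}

#' IDEAL water/fat separation of subspace-echo images
#'
#' For every voxel and temporal subspace coefficient, solves the two-point
#' chemical-shift model across echoes after off-resonance demodulation and
#' T2* amplitude normalization, returning water and fat subspace images
#' referenced to echo time zero (decay and dephasing removed).
#'
#' @param imgs Complex array (n, n, rank, echoes) of subspace-echo images.
#' @param b0_hz Off-resonance map (Hz).
#' @param t2star Result of [fit_dual_t2star()].
#' @param te_ms Echo times (ms).
#' @param fat_shift_hz Fat chemical shift (Hz).
#' @return List of complex arrays `water`, `fat` (n, n, rank).
#' @export
ideal_separate <- function(imgs, b0_hz, t2star, te_ms, fat_shift_hz = 220) {
  d <- dim(imgs)
  n <- d[1]; rank <- d[3]; n_e <- d[4]
  if (stats::var(te_ms) == 0) stop("degenerate echo times", call. = FALSE)
  te <- te_ms
  V <- n * n
  A <- exp(-outer(te, 1 / pmax(as.vector(t2star$t2star_w), T2STAR_MIN)))
  B <- exp(-outer(te, 1 / pmax(as.vector(t2star$t2star_f), T2STAR_MIN))) *
    exp(1i * 2 * pi * fat_shift_hz * te / 1000)
  demod <- exp(-1i * 2 * pi * outer(te / 1000, as.vector(b0_hz)))  # echoes x V
  water <- array(0 + 0i, c(n, n, rank))
  fat <- array(0 + 0i, c(n, n, rank))
  for (s in seq_len(rank)) {
    S <- t(matrix(imgs[, , s, ], V, n_e)) * demod
    sol <- ls2_solve_mat(A, B, S)
    water[, , s] <- matrix(sol$x1, n, n)
    fat[, , s] <- matrix(sol$x2, n, n)
  }
  list(water = water, fat = fat)
}

#' Dictionary pattern matching
#'
#' Voxelwise normalized dot-product search over the compressed dictionary:
#' the winning atom maximizes \eqn{|\langle s, d\rangle| / (\|s\| \|d\|)}
#' (ties broken toward the lowest entry index), and the returned spin density
#' is the complex projection onto the unnormalized atom, i.e. proportional to
#' equilibrium magnetization.
#'
#' @param imgs Complex array (n, n, rank) of subspace coefficient images.
#' @param subspace A `cmrf_subspace` (compressed dictionary).
#' @param mask Optional logical mask.
#' @return List of matrices `t1_ms`, `t2_ms`, complex `m0`, and `mask` of
#'   matched voxels (all-zero voxels are flagged unmatched and return zeros).
#' @export
pattern_match <- function(imgs, subspace, mask = NULL) {
  d <- dim(imgs)
  n <- d[1]; rank <- d[3]
  stopifnot(rank == subspace$rank)
  V <- n * n
  S <- matrix(imgs, V, rank)                # voxels x rank
  nrm <- sqrt(rowSums(abs(S)^2))
  ok <- nrm > 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  D <- subspace$compressed                  # rank x entries
  # chunked search keeps the voxels x entries correlation block small
  Sok <- S[ok, , drop = FALSE]
  nv <- nrow(Sok)
  best <- rep(-1, nv)
  idx <- rep(1L, nv)
  step <- max(1L, as.integer(2e7 / max(nv, 1)))
  i0 <- 1L
  n_ent <- ncol(D)
  while (i0 <= n_ent) {
    i1 <- min(i0 + step - 1L, n_ent)
    corr <- abs(Conj(Sok) %*% D[, i0:i1, drop = FALSE])
    j <- max.col(corr, ties.method = "first")
    v <- corr[cbind(seq_len(nv), j)]
    upd <- v > best
    best[upd] <- v[upd]
    idx[upd] <- i0 + j[upd] - 1L
    i0 <- i1 + 1L
  }
  # complex projection coefficient onto the unnormalized winning atom
  raw <- rowSums(Sok * Conj(t(D[, idx, drop = FALSE])))
  m0v <- raw / subspace$norms[idx]
  t1 <- t2 <- numeric(V)
  m0 <- rep(0 + 0i, V)
  t1[ok] <- subspace$entries$t1_ms[idx]
  t2[ok] <- subspace$entries$t2_ms[idx]
  m0[ok] <- m0v
  list(t1_ms = matrix(t1, n, n), t2_ms = matrix(t2, n, n),
       m0 = matrix(m0, n, n), mask = matrix(ok, n, n))
}

#' Noise-robust proton-density fat fraction
#'
#' Magnitude-discrimination estimator: where fat dominates the voxel the
#' fraction is computed as \eqn{|F| / |W + F|}, otherwise as
#' \eqn{1 - |W| / |W + F|}, which avoids the noise bias of the naive
#' magnitude ratio at low fat fractions; output clipped to [0, 1].
#'
#' @param m0_w,m0_f Complex water/fat spin-density maps.
#' @return List with `pdff` matrix in [0, 1] and logical `valid` mask
#'   (false where both densities vanish).
#' @export
compute_pdff <- function(m0_w, m0_f) {
  tot <- abs(m0_w + m0_f)
  valid <- (abs(m0_w) + abs(m0_f)) > 0
  pdff <- ifelse(abs(m0_f) > abs(m0_w),
                 abs(m0_f) / pmax(tot, .Machine$double.eps),
                 1 - abs(m0_w) / pmax(tot, .Machine$double.eps))
  pdff[!valid] <- 0
  pdff <- pmin(pmax(pdff, 0), 1)
  list(pdff = pdff, valid = valid)
}
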