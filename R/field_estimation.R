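# Pre-computation stage: per-echo images of the first temporal subspace,
# off-resonance estimation by discrete VARPRO search with Markov smoothing,
# and Walsh-style adaptive coil sensitivity maps.

#' Per-coil echo images of the first temporal subspace
#'
#' Projects the k-space data of every excitation onto the first subspace
#' coefficient and grids each full echo separately with density compensation,
#' yielding one complex image per echo per coil.
#'
#' @param kspace A `cmrf_kspace`.
#' @param geom A [cmrf_geometry()].
#' @param basis Subspace basis (excitations x rank); its first column is used.
#' @return Complex array (matrix, matrix, n_full_echoes, n_coils).
#' @export
echo_images_first_subspace <- function(kspace, geom, basis) {
  n <- geom$matrix
  full <- geom$full
  out <- array(0 + 0i, c(n, n, length(full), kspace$n_coils))
  for (j in seq_along(full)) {
    e <- full[j]
    pl <- segment_plan(geom, e)
    w <- segment_dcf(geom, e)
    exc <- segment_exc_index(geom, e)
    b1 <- Conj(basis[exc, 1])
    fn <- segment_flat_norm(geom, e)
    for (c in seq_len(kspace$n_coils)) {
      out[, , j, c] <- nufft_adjoint(b1 * w * kspace$segments[[e]][, c], pl) / fn
    }
  }
  out
}

#' Support mask from echo images
#'
#' Thresholds the root-sum-of-squares first-echo image at a fraction of its
#' maximum.
#' @param echo_imgs Array from [echo_images_first_subspace()].
#' @param threshold Relative threshold (default 0.05).
#' @return Logical matrix.
#' @export
support_mask <- function(echo_imgs, threshold = 0.05) {
  rss <- sqrt(apply(abs(echo_imgs[, , 1, , drop = FALSE])^2, c(1, 2), sum))
  rss >= threshold * max(rss)
}

# quick coil combination for field mapping: conjugate phase of the smoothed
# first-echo images, RSS amplitude weighting
rough_coil_combine <- function(echo_imgs) {
  n <- dim(echo_imgs)[1]; n_e <- dim(echo_imgs)[3]; n_c <- dim(echo_imgs)[4]
  ref <- array(0 + 0i, c(n, n, n_c))
  for (c in seq_len(n_c)) ref[, , c] <- box_smooth(echo_imgs[, , 1, c], 3)
  out <- array(0 + 0i, c(n, n, n_e))
  for (e in seq_len(n_e)) {
    acc <- matrix(0 + 0i, n, n)
    for (c in seq_len(n_c)) acc <- acc + Conj(ref[, , c]) * echo_imgs[, , e, c]
    rss <- sqrt(apply(abs(ref)^2, c(1, 2), sum))
    out[, , e] <- acc / pmax(rss, .Machine$double.eps)
  }
  out
}

box_smooth <- function(img, half) {
  n <- nrow(img)
  pad <- function(v) pmin(pmax(v, 1), n)
  acc <- img * 0
  cnt <- 0
  for (dx in -half:half) for (dy in -half:half) {
    acc <- acc + img[pad(seq_len(n) + dx), pad(seq_len(n) + dy)]
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Off-resonance map estimation from multi-echo images
#'
#' For each voxel the water/fat VARPRO residual is evaluated on a grid of
#' candidate field values (the two-column design holds the water resonance and
#' the fat resonance shifted by `fat_shift_hz`); the field map is then
#' selected by iterated conditional modes on a neighbourhood graph, which
#' resolves the period ambiguity toward the spatially smoothest solution, and
#' refined by local quadratic interpolation.
#'
#' @param echo_imgs Complex array (n, n, echoes) of coil-combined echo images,
#'   or (n, n, echoes, coils) which is combined first.
#' @param te_ms Echo times (ms).
#' @param fat_shift_hz Fat chemical shift (Hz).
#' @param range_hz Candidate search half-range (default 1/(2 dTE)).
#' @param step_hz Candidate spacing (default 4 Hz).
#' @param lambda Smoothness weight of the discrete optimization (default 0.3,
#'   scaled by the local residual contrast).
#' @param n_icm ICM sweeps (default 12).
#' @param mask Optional logical support mask.
#' @param envelope_t2star_ms Nominal transverse decay applied to both design
#'   columns (default 25 ms). Without it the unmodeled signal envelope can be
#'   mimicked by a water/fat beat at a spurious field offset, which biases
#'   low-fat voxels; a representative decay removes most of that envelope
#'   energy from the residual.
#' @return List with `b0_hz` (matrix) and `mask`.
#' @export
estimate_b0 <- function(echo_imgs, te_ms, fat_shift_hz = 220,
                        range_hz = NULL, step_hz = 4, lambda = 0.3,
                        n_icm = 12, mask = NULL, envelope_t2star_ms = 25) {
  if (length(dim(echo_imgs)) == 4) {
    if (is.null(mask)) mask <- support_mask(echo_imgs)
    echo_imgs <- rough_coil_combine(echo_imgs)
  }
  n_e <- dim(echo_imgs)[3]
  if (n_e < 3) stop("insufficient echoes: need at least 3", call. = FALSE)
  n <- dim(echo_imgs)[1]
  if (is.null(mask)) {
    a1 <- abs(echo_imgs[, , 1])
    mask <- a1 >= 0.05 * max(a1)
  }
  te_s <- te_ms / 1000
  if (is.null(range_hz)) range_hz <- 1 / (2 * mean(diff(te_s)))
  cand <- seq(-range_hz, range_hz, by = step_hz)
  n_cand <- length(cand)
  V <- n * n
  S <- matrix(echo_imgs, V, n_e)          # voxels x echoes
  Swt <- t(S)                              # echoes x voxels
  sig2 <- colSums(abs(Swt)^2)
  fitted <- matrix(0, V, n_cand)
  env <- exp(-te_ms / envelope_t2star_ms)
  fat_ph <- exp(1i * 2 * pi * fat_shift_hz * te_s) * env
  for (ci in seq_len(n_cand)) {
    ph <- exp(1i * 2 * pi * cand[ci] * te_s)
    u <- ph * env                             # water column
    vf <- ph * fat_ph                         # fat column
    # project S onto span{u, vf}: Gram matrix of the two columns
    g11 <- sum(env^2)
    g12 <- sum(Conj(u) * vf)
    g22 <- sum(abs(vf)^2)
    det <- Re(g11 * g22 - abs(g12)^2)
    c1 <- Conj(u) %*% Swt                     # 1 x V inner products
    c2 <- Conj(vf) %*% Swt
    # fitted energy = c^H G^{-1} c
    fit <- (g22 * abs(c1)^2 + g11 * abs(c2)^2 -
              2 * Re(g12 * Conj(c1) * c2)) / det
    fitted[, ci] <- Re(fit)
  }
  resid <- pmax(outer(sig2, rep(1, n_cand)) - fitted, 0)
  scale <- stats::median(sig2[as.vector(mask)])
  resid <- resid / max(scale, .Machine$double.eps)
  # water-only voxels fit equally well as fat shifted by the chemical shift:
  # a small field-magnitude prior breaks that exact degeneracy toward the
  # solution nearest zero off-resonance
  resid <- resid + rep(3e-2 * abs(cand) / max(range_hz, 1), each = V)
  # initialize at per-voxel minimum, then ICM with pairwise |f_i - f_j| cost
  lab <- max.col(-resid, ties.method = "first")
  lab[!as.vector(mask)] <- which.min(abs(cand))
  lab_img <- matrix(lab, n, n)
  pen <- lambda / max(range_hz, 1)
  for (sweep in seq_len(n_icm)) {
    changed <- 0L
    order_v <- if (sweep %% 2 == 0) rev(seq_len(V)) else seq_len(V)
    for (v in order_v) {
      i <- (v - 1) %% n + 1; jcol <- (v - 1) %/% n + 1
      if (!mask[i, jcol]) next
      nb <- c(if (i > 1) lab_img[i - 1, jcol], if (i < n) lab_img[i + 1, jcol],
              if (jcol > 1) lab_img[i, jcol - 1], if (jcol < n) lab_img[i, jcol + 1])
      cost <- resid[v, ] + pen * vapply(seq_len(n_cand), function(l)
        sum(abs(cand[l] - cand[nb])), numeric(1))
      new <- which.min(cost)
      if (new != lab_img[i, jcol]) { lab_img[i, jcol] <- new; changed <- changed + 1L }
    }
    if (changed == 0L) break
  }
  lab <- as.vector(lab_img)
  # quadratic refinement around the selected candidate
  b0 <- cand[lab]
  inner <- lab > 1 & lab < n_cand
  if (any(inner)) {
    idx <- which(inner)
    r0 <- resid[cbind(idx, lab[idx] - 1)]
    r1 <- resid[cbind(idx, lab[idx])]
    r2 <- resid[cbind(idx, lab[idx] + 1)]
    den <- r0 - 2 * r1 + r2
    delta <- ifelse(den > 1e-12, 0.5 * (r0 - r2) / den, 0)
    b0[idx] <- b0[idx] + pmax(pmin(delta, 1), -1) * step_hz
  }
  b0 <- matrix(b0, n, n)
  b0[!mask] <- 0
  list(b0_hz = b0, mask = mask)
}

#' Coil sensitivity maps by adaptive combination
#'
#' Walsh-style estimation: the per-voxel principal eigenvector of the
#' spatially smoothed coil covariance accumulated over off-resonance-corrected
#' echo images, root-sum-of-squares normalized and phase-referenced to the
#' first coil.
#'
#' @param echo_imgs Complex array (n, n, echoes, coils); apply B0 correction
#'   before calling (demodulate `exp(-i 2 pi b0 TE)`).
#' @param mask Optional support mask for normalization.
#' @param smooth_half Half-width of the covariance smoothing box (default 2).
#' @return Complex array (n, n, coils) with RSS = 1 inside the mask.
#' @export
estimate_coils <- function(echo_imgs, mask = NULL, smooth_half = 2) {
  n <- dim(echo_imgs)[1]; n_e <- dim(echo_imgs)[3]; n_c <- dim(echo_imgs)[4]
  if (n_c == 1) {
    warning("single-coil data: returning a uniform sensitivity map")
    return(array(1 + 0i, c(n, n, 1)))
  }
  if (is.null(mask)) mask <- support_mask(echo_imgs)
  # covariance accumulation R[c1, c2] per voxel
  R <- array(0 + 0i, c(n, n, n_c, n_c))
  for (e in seq_len(n_e)) {
    for (c1 in seq_len(n_c)) for (c2 in seq_len(n_c)) {
      R[, , c1, c2] <- R[, , c1, c2] +
        echo_imgs[, , e, c1] * Conj(echo_imgs[, , e, c2])
    }
  }
  for (c1 in seq_len(n_c)) for (c2 in seq_len(n_c)) {
    R[, , c1, c2] <- box_smooth(R[, , c1, c2], smooth_half)
  }
  # power iteration for the principal eigenvector, vectorized over voxels
  v <- array(1 + 0i, c(n, n, n_c))
  for (it in seq_len(30)) {
    w <- array(0 + 0i, c(n, n, n_c))
    for (c1 in seq_len(n_c)) {
      for (c2 in seq_len(n_c)) w[, , c1] <- w[, , c1] + R[, , c1, c2] * v[, , c2]
    }
    nrm <- sqrt(apply(abs(w)^2, c(1, 2), sum))
    for (c1 in seq_len(n_c)) v[, , c1] <- w[, , c1] / pmax(nrm, .Machine$double.eps)
  }
  # phase reference: first coil real-positive
  ph <- v[, , 1] / pmax(abs(v[, , 1]), .Machine$double.eps)
  for (c1 in seq_len(n_c)) v[, , c1] <- v[, , c1] * Conj(ph)
  v
}

#' Demodulate the static off-resonance phase from echo images
#' @param echo_imgs Array (n, n, echoes) or (n, n, echoes, coils).
#' @param b0_hz Off-resonance map (Hz).
#' @param te_ms Echo times (ms).
#' @return Array of the same shape.
#' @export
b0_demodulate <- function(echo_imgs, b0_hz, te_ms) {
  d <- dim(echo_imgs)
  out <- echo_imgs
  for (e in seq_along(te_ms)) {
    ph <- exp(-1i * 2 * pi * b0_hz * te_ms[e] / 1000)
    if (length(d) == 3) out[, , e] <- out[, , e] * ph
    else for (c in seq_len(d[4])) out[, , e, c] <- out[, , e, c] * ph
  }
  out
}

#' Combine per-coil images with conjugate sensitivities
#' @param imgs Array (n, n, ..., coils) with coils last.
#' @param coils Complex array (n, n, coils).
#' @return Array with the coil dimension removed.
#' @export
coil_combine <- function(imgs, coils) {
  d <- dim(imgs)
  n_c <- d[length(d)]
  stopifnot(dim(coils)[3] == n_c)
  out <- array(0 + 0i, d[-length(d)])
  flat <- matrix(imgs, prod(d[-length(d)]), n_c)
  inner <- prod(d[-c(1, 2, length(d))])
  cf <- matrix(Conj(coils), d[1] * d[2], n_c)
  for (c in seq_len(n_c)) {
    out <- out + array(flat[, c], d[-length(d)]) *
      array(rep(cf[, c], times = inner), d[-length(d)])
  }
  out
}
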