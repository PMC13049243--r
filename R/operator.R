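# The subspace-constrained multi-echo encoding model. Unknowns are complex
# subspace-echo images x[, , s, e] (s = temporal subspace coefficient,
# e = full echo). For excitation n and echo e the model predicts
#   y = sum_s B[n, s] * NUFFT{ C_c * exp(i 2 pi b0 TE_e) * x[,,s,e] }
# evaluated on that excitation's rotated samples; the static per-echo B0
# phase mirrors the phase-progression correction of the reconstruction.

#' Multi-echo subspace encoding operator
#'
#' @param geom A [cmrf_geometry()].
#' @param field A [field_model()] (or NULL for unit coil, zero B0).
#' @param basis Complex orthonormal basis (excitations x rank).
#' @param b0_correction Apply the per-echo static off-resonance phase
#'   (default TRUE).
#' @return A `cmrf_operator` object with `forward`, `adjoint` and meta fields.
#' @export
cmrf_operator <- function(geom, field = NULL, basis, b0_correction = TRUE) {
  n <- geom$matrix
  if (is.null(field)) field <- field_model(matrix(0, n, n), array(1 + 0i, c(n, n, 1)))
  stopifnot(nrow(basis) == geom$n_exc)
  rank <- ncol(basis)
  full <- geom$full
  n_e <- length(full)
  te_s <- geom$echoes$echo_time_ms[full] / 1000
  phases <- lapply(seq_len(n_e), function(j) {
    if (b0_correction) exp(1i * 2 * pi * field$b0_hz * te_s[j]) else matrix(1 + 0i, n, n)
  })
  # per-echo basis expansion over sample rows (excitation-major); echoes share
  # the expansion whenever their per-excitation sample counts agree
  m_e <- vapply(full, function(e) length(geom$seg_idx[[e]]), integer(1))
  bx_cache <- list()
  Bx <- lapply(seq_len(n_e), function(j) {
    key <- as.character(m_e[j])
    if (is.null(bx_cache[[key]])) {
      exc <- rep(seq_len(geom$n_exc), each = m_e[j])
      bx_cache[[key]] <<- basis[exc, , drop = FALSE]
    }
    bx_cache[[key]]
  })
  structure(list(geom = geom, field = field, basis = basis, rank = rank,
                 n_echoes = n_e, full = full, te_ms = geom$echoes$echo_time_ms[full],
                 phases = phases, Bx = Bx, b0_correction = b0_correction),
            class = "cmrf_operator")
}

#' @export
print.cmrf_operator <- function(x, ...) {
  cat(sprintf("cMRF encoding operator: rank %d x %d echoes, %d coils, B0 %s\n",
              x$rank, x$n_echoes, x$field$n_coils,
              if (x$b0_correction) "corrected" else "uncorrected"))
  invisible(x)
}

#' Forward encoding: subspace-echo images to multi-coil k-space
#'
#' @param op A `cmrf_operator`.
#' @param x Complex array (matrix, matrix, rank, n_echoes).
#' @return List of per-echo complex sample matrices (rows x coils), full
#'   echoes only.
#' @export
operator_forward <- function(op, x) {
  geom <- op$geom
  stopifnot(length(dim(x)) == 4, dim(x)[3] == op$rank, dim(x)[4] == op$n_echoes)
  out <- vector("list", op$n_echoes)
  for (j in seq_len(op$n_echoes)) {
    e <- op$full[j]
    pl <- segment_plan(geom, e)
    Bx <- op$Bx[[j]]
    y <- matrix(0 + 0i, nrow(pl$P), op$field$n_coils)
    G <- matrix(0 + 0i, pl$n_grid^2, op$rank)
    for (c in seq_len(op$field$n_coils)) {
      sens_ph <- op$field$coils[, , c] * op$phases[[j]]
      for (s in seq_len(op$rank)) G[, s] <- nufft_grid_fft(x[, , s, j] * sens_ph, pl)
      V <- sp_mul_mat(pl$P, G)
      y[, c] <- rowSums(Bx * V)
    }
    out[[j]] <- y
  }
  out
}

#' Adjoint encoding: multi-coil k-space to subspace-echo images
#'
#' Exact adjoint of [operator_forward()]; with `dcf` supplied the samples are
#' pre-weighted (adjoint gridding reconstruction rather than a true adjoint).
#'
#' @param op A `cmrf_operator`.
#' @param y List of per-echo sample matrices (full echoes).
#' @param dcf Optional list of per-echo density weights.
#' @return Complex array (matrix, matrix, rank, n_echoes).
#' @export
operator_adjoint <- function(op, y, dcf = NULL) {
  geom <- op$geom
  n <- geom$matrix
  x <- array(0 + 0i, c(n, n, op$rank, op$n_echoes))
  for (j in seq_len(op$n_echoes)) {
    e <- op$full[j]
    pl <- segment_plan(geom, e)
    Bx <- op$Bx[[j]]
    w <- if (is.null(dcf)) NULL else dcf[[j]]
    for (c in seq_len(op$field$n_coils)) {
      sens_ph <- Conj(op$field$coils[, , c] * op$phases[[j]])
      yc <- y[[j]][, c]
      if (!is.null(w)) yc <- yc * w
      R <- Conj(Bx) * yc
      G <- sp_tmul_mat(pl$P, R)
      for (s in seq_len(op$rank)) {
        x[, , s, j] <- x[, , s, j] + nufft_grid_ifft(G[, s], pl) * sens_ph
      }
    }
  }
  x
}

# <Ax, y> - <x, A^H y> consistency is exercised in the tests; helpers below
# give inner products and norms over the nested k-space lists.
ksp_inner <- function(a, b) {
  s <- 0 + 0i
  for (j in seq_along(a)) s <- s + sum(Conj(a[[j]]) * b[[j]])
  s
}
ksp_norm2 <- function(a) Re(ksp_inner(a, a))
ksp_wnorm2 <- function(a, w) {
  s <- 0
  for (j in seq_along(a)) s <- s + sum(w[[j]] * rowSums(abs(a[[j]])^2))
  s
}
ksp_lincomb <- function(a, b, ca = 1, cb = 1) {
  lapply(seq_along(a), function(j) ca * a[[j]] + cb * b[[j]])
}

# restrict a cmrf_kspace object to the operator's full echoes
kspace_full_echoes <- function(kspace, op) {
  kspace$segments[op$full]
}
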