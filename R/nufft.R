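# Non-uniform FFT via Kaiser-Bessel gridding with a sparse interpolation
# matrix, plus Pipe-Menon density compensation. The interpolator is real, so
# complex data are handled as two real sparse products; forward and adjoint
# are exact transposes of each other by construction.

kb_beta <- function(width, os) pi * sqrt(max(width^2 / os^2 * (os - 0.5)^2 - 0.8, 0.1))

kb_kernel <- function(u, width, beta) {
  x <- 1 - (2 * u / width)^2
  v <- numeric(length(u))
  ok <- x > 0
  v[ok] <- besselI(beta * sqrt(x[ok]), 0) / besselI(beta, 0)
  v
}

# Fourier transform of the KB kernel, evaluated at image positions (pixel
# units relative to the oversampled grid), used for deapodization. The
# absolute scale (width / I0(beta)) is kept so the gridding transform matches
# the plain discrete Fourier sum independent of kernel width.
kb_apodization <- function(n_im, n_grid, width, beta) {
  x <- ((seq_len(n_im)) - n_im / 2 - 1) / n_grid
  arg <- (pi * width * x)^2 - beta^2
  v <- ifelse(arg > 0, sin(sqrt(arg)) / sqrt(arg), sinh(sqrt(-arg)) / sqrt(-arg))
  v * width / besselI(beta, 0)
}

#' Plan a gridding non-uniform Fourier transform
#'
#' Precomputes the sparse Kaiser-Bessel interpolation matrix and the
#' deapodization vector for a fixed set of k-space sample locations.
#'
#' @param kx,ky Sample coordinates (1/m).
#' @param matrix Image matrix size (pixels, square).
#' @param fov_m Field of view (m).
#' @param os Grid oversampling factor (default 2).
#' @param width Interpolation kernel width in grid cells (default 4).
#' @return A `nufft_plan` list.
#' @export
nufft_plan <- function(kx, ky, matrix, fov_m = 0.3, os = 2, width = 4) {
  n_im <- as.integer(matrix)
  n_g <- as.integer(round(n_im * os))
  dk <- n_im / (n_g * fov_m)    # k-grid spacing; image pixel = fov/n_im exactly
  beta <- kb_beta(width, os)
  gx <- kx / dk + n_g / 2 + 1
  gy <- ky / dk + n_g / 2 + 1
  if (width %% 2 == 1) {
    off <- -((width - 1) / 2):((width - 1) / 2)
    fx <- round(gx); fy <- round(gy)
  } else {
    off <- (-(width / 2 - 1)):(width / 2)
    fx <- floor(gx); fy <- floor(gy)
  }
  nofs <- length(off)^2
  ii <- jj <- vv <- vector("list", nofs)
  n <- 0
  for (ox in off) for (oy in off) {
    n <- n + 1
    cx <- fx + ox; cy <- fy + oy
    w <- kb_kernel(gx - cx, width, beta) * kb_kernel(gy - cy, width, beta)
    # the discrete k-grid is periodic: wrap kernel taps modulo the grid
    cx <- ((cx - 1) %% n_g) + 1
    cy <- ((cy - 1) %% n_g) + 1
    keep <- w > 0
    ii[[n]] <- which(keep)
    jj[[n]] <- (cy[keep] - 1) * n_g + cx[keep]
    vv[[n]] <- w[keep]
  }
  # fold the DFT-centering half-shifts into the plan: the image-side shift
  # becomes a checkerboard sign absorbed into the deapodization matrix, the
  # k-side shift a sign on the interpolator columns (both real, so the
  # forward/adjoint transpose pairing is preserved)
  jj_all <- unlist(jj)
  cxw <- (jj_all - 1) %% n_g + 1
  cyw <- (jj_all - 1) %/% n_g + 1
  sgn <- 1 - 2 * ((cxw + cyw) %% 2)
  P <- Matrix::sparseMatrix(i = unlist(ii), j = jj_all, x = unlist(vv) * sgn,
                            dims = c(length(kx), n_g * n_g))
  apod <- kb_apodization(n_im, n_g, width, beta)
  cb <- outer(seq_len(n_im), seq_len(n_im), function(a, b) 1 - 2 * ((a + b) %% 2))
  list(P = P, n_im = n_im, n_grid = n_g, dk = dk, os = os, width = width,
       apod = apod, pre = cb / outer(apod, apod),
       n_samp = length(kx))
}

# complex sparse product helpers (interpolator is real)
sp_mul <- function(P, z) {
  as.vector(P %*% Re(z)) + 1i * as.vector(P %*% Im(z))
}
sp_tmul <- function(P, z) {
  as.vector(Matrix::crossprod(P, Re(z))) + 1i * as.vector(Matrix::crossprod(P, Im(z)))
}

# circular half-shift (fftshift); involution for even n
fft_swap <- function(M) {
  n <- nrow(M)
  s <- c((n / 2 + 1):n, 1:(n / 2))
  M[s, s]
}

# grid-domain halves of the transform, shared by the batched operator code;
# centering shifts are pre-folded into `pre` and the interpolator signs
nufft_grid_fft <- function(img, plan) {
  n_im <- plan$n_im; n_g <- plan$n_grid
  X <- matrix(0 + 0i, n_g, n_g)
  i0 <- (n_g - n_im) / 2
  X[i0 + seq_len(n_im), i0 + seq_len(n_im)] <- img * plan$pre
  as.vector(stats::fft(X))
}

nufft_grid_ifft <- function(gvec, plan) {
  n_im <- plan$n_im; n_g <- plan$n_grid
  X <- stats::fft(matrix(gvec, n_g, n_g), inverse = TRUE)
  i0 <- (n_g - n_im) / 2
  X[i0 + seq_len(n_im), i0 + seq_len(n_im)] * plan$pre
}

# batched complex sparse products on matrices (columns are channels); real
# and imaginary parts ride in one call
sp_mul_mat <- function(P, Z) {
  k <- ncol(Z)
  W <- as.matrix(P %*% cbind(Re(Z), Im(Z)))
  W[, seq_len(k), drop = FALSE] + 1i * W[, k + seq_len(k), drop = FALSE]
}
sp_tmul_mat <- function(P, Z) {
  k <- ncol(Z)
  W <- as.matrix(Matrix::crossprod(P, cbind(Re(Z), Im(Z))))
  W[, seq_len(k), drop = FALSE] + 1i * W[, k + seq_len(k), drop = FALSE]
}

#' Forward gridding NUFFT: image to k-space samples
#' @param img Complex image matrix (`n_im` square).
#' @param plan A `nufft_plan`.
#' @return Complex vector of samples.
#' @export
nufft_forward <- function(img, plan) {
  sp_mul(plan$P, nufft_grid_fft(img, plan))
}

#' Adjoint gridding NUFFT: k-space samples to image
#'
#' Exact transpose of [nufft_forward()]; pre-multiply samples by density
#' compensation weights for a direct (gridding) reconstruction.
#' @param y Complex sample vector.
#' @param plan A `nufft_plan`.
#' @return Complex image matrix.
#' @export
nufft_adjoint <- function(y, plan) {
  nufft_grid_ifft(sp_tmul(plan$P, y), plan)
}

#' Pipe-Menon density compensation weights
#'
#' Iterates `w <- w / (P P' w)` until the gridded density interpolated back to
#' the samples is flat, yielding nonnegative per-sample weights for adjoint
#' gridding reconstructions.
#'
#' @param plan A `nufft_plan` (its sparse interpolator defines the smoothing
#'   kernel of the density estimate).
#' @param n_iter Number of fixed-point iterations (default 25).
#' @return Positive weight vector, normalized so the weights sum to 1.
#' @export
pipe_menon_dcf <- function(plan, n_iter = 25) {
  w <- rep(1, nrow(plan$P))
  for (i in seq_len(n_iter)) {
    d <- as.vector(plan$P %*% Matrix::crossprod(plan$P, w))
    w <- w / pmax(d, 1e-12)
  }
  w / sum(w)
}

#' Density compensation for one echo of a rotated multi-excitation acquisition
#'
#' Computes Pipe-Menon weights on the union of the rotated copies of a full
#' echo segment (the fully-sampled per-echo k-space formed by combining
#' readouts).
#'
#' @param segment One row of an `echo_set` (must have `is_full = TRUE`).
#' @param traj The parent `rosette_trajectory`.
#' @param rotations Rotation angles (radians) per excitation.
#' @param matrix Image matrix size.
#' @param fov_m Field of view (m).
#' @return Weights for the samples of that echo, ordered excitation-major.
#' @export
compute_dcf <- function(segment, traj, rotations = 0, matrix = 64, fov_m = 0.3) {
  if (!isTRUE(segment$is_full))
    stop("unsupported segment: density weights are defined for full echoes only",
         call. = FALSE)
  idx <- segment$start:segment$end
  k <- complex(real = traj$kx[idx], imaginary = traj$ky[idx])
  ku <- as.vector(outer(k, exp(1i * rotations)))
  plan <- nufft_plan(Re(ku), Im(ku), matrix, fov_m)
  pipe_menon_dcf(plan)
}
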