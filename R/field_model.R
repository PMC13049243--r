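#' Static field model: off-resonance map, coil sensitivities, fat shift
#'
#' @param b0_hz Off-resonance map (Hz), matrix, finite everywhere.
#' @param coils Complex array (n x n x n_coils) of coil sensitivities; root
#'   sum of squares is normalized to 1 inside `mask`.
#' @param fat_shift_hz Fat chemical shift (Hz; 220 at 1.5 T).
#' @param mask Optional logical support mask used for normalization.
#' @return A `field_model` object.
#' @export
field_model <- function(b0_hz, coils, fat_shift_hz = 220, mask = NULL) {
  if (is.matrix(coils)) coils <- array(coils, c(dim(coils), 1))
  stopifnot(all(is.finite(b0_hz)))
  rss <- sqrt(apply(abs(coils)^2, c(1, 2), sum))
  if (is.null(mask)) mask <- rss > 0
  norm <- ifelse(mask & rss > 0, rss, 1)
  for (c in seq_len(dim(coils)[3])) coils[, , c] <- coils[, , c] / norm
  structure(list(b0_hz = b0_hz, coils = coils, fat_shift_hz = fat_shift_hz,
                 mask = mask, n_coils = dim(coils)[3]),
            class = "field_model")
}

#' Synthetic birdcage-style coil sensitivities
#'
#' Smooth complex sensitivities from `n_coils` loop elements placed on a
#' circle around the FOV, with gentle amplitude falloff and a slowly varying
#' phase, for simulation fixtures.
#'
#' @param matrix Matrix size.
#' @param n_coils Number of coils (default 8).
#' @return Complex array (matrix x matrix x n_coils).
#' @export
make_birdcage_coils <- function(matrix, n_coils = 8) {
  n <- matrix
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  X <- outer(xs, rep(1, n)); Y <- outer(rep(1, n), xs)
  out <- array(0 + 0i, c(n, n, n_coils))
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    px <- 0.55 * cos(th); py <- 0.55 * sin(th)
    d2 <- (X - px)^2 + (Y - py)^2
    amp <- 1 / (1 + d2 / 0.12)
    ph <- pi * (X * cos(th) + Y * sin(th)) + th / 2
    out[, , c] <- amp * exp(1i * ph)
  }
  out
}

#' Smooth synthetic off-resonance map
#'
#' A linear-plus-quadratic field over the FOV, optionally averaged within
#' phantom labels (so that simulation with piecewise-constant off-resonance is
#' exact).
#'
#' @param matrix Matrix size.
#' @param peak_hz Approximate maximum |B0| (default 40).
#' @param phantom Optional `digital_phantom`; if given the map is made
#'   constant within each tissue label (zero in the background).
#' @return Matrix of off-resonance values (Hz).
#' @export
make_b0_map <- function(matrix, peak_hz = 40, phantom = NULL) {
  n <- matrix
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  X <- outer(xs, rep(1, n)); Y <- outer(rep(1, n), xs)
  b0 <- peak_hz * (0.8 * X + 0.5 * Y + 0.6 * (X^2 - Y^2))
  if (!is.null(phantom)) {
    out <- matrix(0, n, n)
    for (l in phantom$properties$label) {
      m <- phantom$label == l
      out[m] <- mean(b0[m])
    }
    b0 <- out
  }
  b0
}
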