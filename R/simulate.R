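#' Simulate a rosette cMRF acquisition from a digital phantom
#'
#' Generates multi-coil k-space for the full multi-echo readout train. Each
#' voxel's signal is the sum of a water and a fat component, each following
#' its own EPG fingerprint across excitations and decaying with its own T2*
#' continuously along the readout; the fat component additionally precesses at
#' the chemical shift. Per-voxel off-resonance and coil sensitivities are
#' applied, and the spatial encoding is evaluated with a gridding Fourier
#' transform (kernel width 5) on the rotated trajectory.
#'
#' @param phantom A `digital_phantom`.
#' @param schedule A [cmrf_schedule()].
#' @param geom A [cmrf_geometry()] (matrix/FOV must match the phantom grid).
#' @param field A [field_model()] or NULL (no off-resonance, single uniform
#'   coil).
#' @param noise_pct Complex Gaussian noise SD as a fraction of the maximum
#'   signal magnitude (e.g. 0.025 for 2.5%).
#' @param seed RNG seed for the noise (required when `noise_pct > 0`).
#' @param rf An [rf_pulse_spec()] matching the dictionary simulation.
#' @param inversion_efficiency Inversion efficiency used in the fingerprints.
#' @return A `cmrf_kspace` object: per-segment complex sample matrices
#'   (rows excitation-major, one column per coil) plus acquisition metadata.
#' @export
simulate_acquisition <- function(phantom, schedule, geom, field = NULL,
                                 noise_pct = 0, seed = 1,
                                 rf = rf_pulse_spec(),
                                 inversion_efficiency = 0.95) {
  if (noise_pct < 0) stop("noise_pct must be nonnegative", call. = FALSE)
  n <- geom$matrix
  stopifnot(phantom$matrix == n)
  props <- phantom$properties
  if (is.null(field)) {
    field <- field_model(matrix(0, n, n), array(1 + 0i, c(n, n, 1)))
  }
  n_coils <- field$n_coils
  fat_shift <- field$fat_shift_hz

  # fingerprints: one per water tissue + unique fat relaxation pairs
  wat_fp <- epg_fingerprints(props$t1_ms, props$t2_ms, schedule, rf,
                             inversion_efficiency)
  fat_pairs <- unique(props[props$pdff > 0, c("fat_t1_ms", "fat_t2_ms")])
  fat_fp <- if (nrow(fat_pairs)) {
    epg_fingerprints(fat_pairs$fat_t1_ms, fat_pairs$fat_t2_ms, schedule, rf,
                     inversion_efficiency)
  } else NULL

  # component table: images, fingerprint, decay constant, frequency offset
  comps <- list()
  b0 <- field$b0_hz
  for (r in seq_len(nrow(props))) {
    m <- phantom$label == props$label[r]
    if (!any(m) || props$m0[r] == 0) next
    b0r <- b0[m]
    const_b0 <- max(b0r) - min(b0r) < 1e-6
    wimg <- matrix(0 + 0i, n, n)
    wimg[m] <- props$m0[r] * (1 - props$pdff[r])
    comps[[length(comps) + 1]] <- list(
      img = wimg, fp = wat_fp[, r], t2star = props$t2star_ms[r],
      freq = 0, b0_const = if (const_b0) b0r[1] else NA_real_)
    if (props$pdff[r] > 0) {
      fidx <- which(fat_pairs$fat_t1_ms == props$fat_t1_ms[r] &
                      fat_pairs$fat_t2_ms == props$fat_t2_ms[r])
      fimg <- matrix(0 + 0i, n, n)
      fimg[m] <- props$m0[r] * props$pdff[r]
      comps[[length(comps) + 1]] <- list(
        img = fimg, fp = fat_fp[, fidx], t2star = props$fat_t2star_ms[r],
        freq = fat_shift, b0_const = if (const_b0) b0r[1] else NA_real_)
    }
  }

  n_seg <- nrow(geom$echoes)
  segs <- vector("list", n_seg)
  exc_all <- NULL
  for (e in seq_len(n_seg)) {
    ku <- segment_points(geom, e)
    pl <- nufft_plan(Re(ku), Im(ku), n, geom$fov_m, width = 5)
    tms <- segment_times(geom, e)
    m_e <- length(tms)
    exc <- rep(seq_len(geom$n_exc), each = m_e)
    t_row <- rep(tms, times = geom$n_exc) / 1000  # seconds
    y <- matrix(0 + 0i, length(ku), n_coils)
    for (c in seq_len(n_coils)) {
      sens <- field$coils[, , c]
      for (cp in comps) {
        base <- cp$img * sens
        if (is.na(cp$b0_const)) {
          # general smooth map: 6-segment linear time interpolation
          tau <- seq(min(tms), max(tms), length.out = 6) / 1000
          V <- vapply(tau, function(tl)
            sp_mul(pl$P, nufft_grid_fft(base * exp(1i * 2 * pi * b0 * tl), pl)),
            complex(length(ku)))
          cf <- interp_hat(t_row, tau)
          v <- rowSums(V * cf)
        } else {
          v <- sp_mul(pl$P, nufft_grid_fft(base, pl)) *
            exp(1i * 2 * pi * cp$b0_const * t_row)
        }
        coef <- cp$fp[exc] * exp(-1000 * t_row / cp$t2star) *
          exp(1i * 2 * pi * cp$freq * t_row)
        y[, c] <- y[, c] + coef * v
      }
    }
    segs[[e]] <- y
  }
  noise_sd <- 0
  if (noise_pct > 0) {
    peak <- max(vapply(segs, function(s) max(abs(s)), numeric(1)))
    noise_sd <- noise_pct * peak
    rs <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    for (e in seq_len(n_seg)) {
      nn <- length(segs[[e]])
      segs[[e]] <- segs[[e]] + noise_sd *
        (matrix(stats::rnorm(nn), nrow(segs[[e]])) +
           1i * matrix(stats::rnorm(nn), nrow(segs[[e]]))) / sqrt(2)
    }
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  }
  structure(list(segments = segs, geom_matrix = n, n_exc = geom$n_exc,
                 n_coils = n_coils, noise_sd = noise_sd, noise_pct = noise_pct,
                 seed = seed, fat_shift_hz = fat_shift),
            class = "cmrf_kspace")
}

# hat-function (linear interpolation) coefficients of times t over knots tau
interp_hat <- function(t, tau) {
  L <- length(tau)
  cf <- matrix(0, length(t), L)
  d <- diff(tau)
  i <- pmin(pmax(findInterval(t, tau), 1), L - 1)
  w <- (t - tau[i]) / d[i]
  cf[cbind(seq_along(t), i)] <- 1 - w
  cf[cbind(seq_along(t), i + 1)] <- w
  cf
}

#' @export
print.cmrf_kspace <- function(x, ...) {
  ns <- sum(vapply(x$segments, nrow, integer(1)))
  cat(sprintf("cMRF k-space: %d segments, %d samples x %d coils, noise SD %.3g\n",
              length(x$segments), ns, x$n_coils, x$noise_sd))
  invisible(x)
}
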