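#' Rosette k-space trajectory
#'
#' Generates a 2D rosette readout using the sinusoidal parametrization
#' \deqn{k(t) = k_{max} \sin(2\pi \omega_1 t/T)\, e^{i 2\pi \omega_2 t/T}}
#' where \eqn{\omega_1} counts radial oscillation cycles per readout and
#' \eqn{\omega_2} rotational cycles per readout. The trajectory repeatedly
#' crosses the k-space origin, producing one gradient echo per crossing; with
#' \eqn{\omega_1 = 11.5} over an 18.4 ms readout there are 23 lobes and 24
#' origin crossings, and consecutive lobes are rotated by
#' \eqn{180^\circ\,\omega_2/\omega_1 \approx 117.4^\circ}, close to the golden
#' angle.
#'
#' @param kmax Spatial-frequency extent in 1/m (default 320).
#' @param w1_cycles Radial oscillation cycles per readout (default 11.5).
#' @param w2_cycles Rotational cycles per readout (default 7.5).
#' @param readout_ms Readout duration in ms (default 18.4).
#' @param dt_us ADC dwell time in microseconds (default 2.5).
#' @return An object of class `rosette_trajectory`: a list with fields
#'   `kx`, `ky` (1/m), `t_ms` (time stamps from readout start), and the
#'   design parameters.
#' @examples
#' traj <- rosette_trajectory()
#' count_origin_crossings(traj)  # 24
#' @export
rosette_trajectory <- function(kmax = 320, w1_cycles = 11.5, w2_cycles = 7.5,
                               readout_ms = 18.4, dt_us = 2.5) {
  if (any(c(kmax, w1_cycles, w2_cycles, readout_ms, dt_us) <= 0))
    stop("all rosette parameters must be positive", call. = FALSE)
  t_ms <- seq(0, readout_ms, by = dt_us / 1000)
  if (length(t_ms) / (2 * w1_cycles) < 2)
    stop("dwell too coarse: fewer than 2 samples per lobe", call. = FALSE)
  u <- t_ms / readout_ms
  k <- kmax * sin(2 * pi * w1_cycles * u) * exp(1i * 2 * pi * w2_cycles * u)
  structure(list(kx = Re(k), ky = Im(k), t_ms = t_ms,
                 kmax = kmax, w1_cycles = w1_cycles, w2_cycles = w2_cycles,
                 readout_ms = readout_ms, dt_us = dt_us),
            class = "rosette_trajectory")
}

#' @export
print.rosette_trajectory <- function(x, ...) {
  cat("Rosette readout trajectory\n")
  cat(sprintf("  kmax: %g 1/m, w1: %g cycles, w2: %g cycles\n",
              x$kmax, x$w1_cycles, x$w2_cycles))
  cat(sprintf("  readout: %g ms at %g us dwell (%d samples)\n",
              x$readout_ms, x$dt_us, length(x$t_ms)))
  cat(sprintf("  origin crossings: %d, inter-lobe rotation: %.2f deg\n",
              count_origin_crossings(x), 180 * x$w2_cycles / x$w1_cycles))
  invisible(x)
}

#' Count k-space origin crossings of a rosette readout
#'
#' Counts zeros of the radial envelope (including the starting point at t = 0)
#' by locating exact zeros and sign changes of the sampled envelope.
#'
#' @param traj A `rosette_trajectory`.
#' @return Integer number of origin crossings.
#' @export
count_origin_crossings <- function(traj) {
  length(origin_crossing_indices(traj))
}

# Sample indices closest to each origin crossing. Envelope zeros are found from
# sign changes of the signed radial envelope; values below a small tolerance
# (relative to kmax) are snapped to zero first so grid-aligned zeros are not
# double counted.
origin_crossing_indices <- function(traj) {
  u <- traj$t_ms / traj$readout_ms
  s <- sin(2 * pi * traj$w1_cycles * u)
  tol <- 1e-9
  s[abs(s) < tol] <- 0
  idx <- integer(0)
  n <- length(s)
  i <- 1
  while (i <= n) {
    if (s[i] == 0) {
      idx <- c(idx, i)
      while (i <= n && s[i] == 0) i <- i + 1
    } else {
      if (i < n && s[i + 1] != 0 && sign(s[i]) != sign(s[i + 1])) {
        # crossing between i and i+1: take nearer sample
        idx <- c(idx, if (abs(s[i]) <= abs(s[i + 1])) i else i + 1)
      }
      i <- i + 1
    }
  }
  idx
}

#' Split a rosette readout into echo segments
#'
#' Divides the readout at the farthest k-space extents (the apexes of the
#' radial envelope), yielding one segment per origin crossing. The first and
#' last segments cover only half a sweep (center-to-edge) and are flagged
#' `is_full = FALSE`; all interior segments are complete edge-to-edge sweeps
#' through the k-space center.
#'
#' @param traj A `rosette_trajectory`.
#' @param t0_ms Time offset (ms) from excitation to the start of the readout;
#'   echo times are reported relative to excitation.
#' @return An object of class `echo_set`: a data frame with columns
#'   `start`, `end` (sample index range, inclusive), `echo_time_ms`, `is_full`,
#'   with the parent trajectory attached as an attribute.
#' @export
split_into_echoes <- function(traj, t0_ms = 0) {
  cross <- origin_crossing_indices(traj)
  if (length(cross) < 2)
    stop("degenerate trajectory: fewer than 2 origin crossings", call. = FALSE)
  n <- length(traj$t_ms)
  # boundaries: apex (max |envelope|) between consecutive crossings
  u <- traj$t_ms / traj$readout_ms
  s <- abs(sin(2 * pi * traj$w1_cycles * u))
  nb <- length(cross) - 1
  bnd <- integer(nb)
  for (m in seq_len(nb)) {
    rng <- cross[m]:cross[m + 1]
    bnd[m] <- rng[which.max(s[rng])]
  }
  start <- c(1L, bnd + 1L)
  end <- c(bnd, n)
  data <- data.frame(start = start, end = end,
                     echo_time_ms = t0_ms + traj$t_ms[cross],
                     is_full = c(FALSE, rep(TRUE, length(cross) - 2), FALSE))
  structure(data, class = c("echo_set", "data.frame"), trajectory = traj)
}

#' Off-resonance response function of a rosette readout
#'
#' The relative amplitude with which an off-resonant species appears at its
#' true location when the full readout is gridded: the magnitude of the
#' density-weighted time average of its phase factor
#' \eqn{\exp(i 2\pi f t)} over the readout, normalized to the on-resonance
#' value. The species decays with `t2star_ms` during the 18.4 ms readout,
#' which weights the average toward early samples; the default of 20 ms is
#' the fat T2* used throughout the package, making the 220 Hz value the
#' attenuation of myocardial fat in gridded rosette images (about 3% for the
#' default readout). Set `t2star_ms = Inf` for the pure frequency response of
#' a non-decaying species (about 1.2% at 220 Hz).
#'
#' @param traj A `rosette_trajectory`.
#' @param freq_hz Off-resonance frequency (Hz), vectorized.
#' @param t2star_ms Transverse decay of the responding species (ms).
#' @param weighted Use density-compensation weighting (default TRUE). With
#'   `FALSE` a plain time average is taken.
#' @param weights Optional externally computed per-sample weights.
#' @return Relative response in `[0, 1]` per frequency.
#' @export
response_function <- function(traj, freq_hz, t2star_ms = 20, weighted = TRUE,
                              weights = NULL) {
  t_s <- traj$t_ms / 1000
  if (is.null(weights)) {
    weights <- if (weighted) readout_density_weights(traj) else rep(1, length(t_s))
  }
  weights <- weights * exp(-traj$t_ms / t2star_ms)
  r0 <- sum(weights)
  vapply(freq_hz, function(f) {
    min(1, abs(sum(weights * exp(1i * 2 * pi * f * t_s))) / r0)
  }, numeric(1))
}

# Per-sample density-compensation weights for a single full readout,
# approximating the area of the k-space cell owned by each sample: the product
# of the local spacing along the trajectory and the azimuthal gap to the
# neighbouring lobes at the same radius (a separable stand-in for Voronoi cell
# areas, which kernel-smoothed density iteration underestimates near the
# sparsely covered rim).
readout_density_weights <- function(traj) {
  k <- complex(real = traj$kx, imaginary = traj$ky)
  n <- length(k)
  dk <- abs(diff(k))
  along <- (c(dk[1], dk) + c(dk, dk[n - 1])) / 2
  r <- abs(k)
  # azimuthal spacing between adjacent lobes at radius r: adjacent lobes are
  # rotated by 180*w2/w1 degrees; the nearest angular neighbour gap at radius r
  # scales with r; cap by the lobe-arc estimate so the center is not zeroed.
  gap <- 2 * pi * r / (2 * traj$w1_cycles)
  w <- along * pmax(gap, median(along))
  w / sum(w)
}

#' Gradient and slew-rate feasibility report
#'
#' Computes peak gradient amplitude and per-axis slew rate of a trajectory via
#' finite differences, using \eqn{G = (dk/dt)/\bar\gamma}, and compares them
#' against hardware limits.
#'
#' @param traj A `rosette_trajectory` sampled on a uniform time grid.
#' @param gmax_mT_m Gradient amplitude limit in mT/m (default 43).
#' @param smax Slew-rate limit, in the units given by `smax_units`
#'   (default 180 T/m/s).
#' @param smax_units Unit string for `smax`, either `"T/m/s"` or `"mT/m/s"`;
#'   stored verbatim in the report.
#' @param gamma_hz_t Gyromagnetic ratio in Hz/T (default 42.577e6 for protons).
#' @return A list of class `gradient_report` with peak values and pass flags.
#' @export
check_gradient_feasibility <- function(traj, gmax_mT_m = 43, smax = 180,
                                       smax_units = "T/m/s",
                                       gamma_hz_t = 42.577e6) {
  if (gmax_mT_m <= 0 || smax <= 0) stop("limits must be positive", call. = FALSE)
  if (length(traj$t_ms) < 3)
    stop("insufficient data: need at least 3 samples", call. = FALSE)
  dt <- traj$dt_us * 1e-6
  gx <- diff(traj$kx) / dt / gamma_hz_t   # T/m
  gy <- diff(traj$ky) / dt / gamma_hz_t
  sx <- diff(gx) / dt                     # T/m/s
  sy <- diff(gy) / dt
  peak_g <- max(sqrt(gx^2 + gy^2)) * 1e3  # mT/m
  peak_s <- max(abs(c(sx, sy)))           # T/m/s per axis
  smax_T <- if (identical(smax_units, "mT/m/s")) smax * 1e-3 else smax
  structure(list(peak_gradient_mT_m = peak_g,
                 peak_slew_T_m_s = peak_s,
                 gmax_mT_m = gmax_mT_m,
                 smax = smax, smax_units = smax_units,
                 gradient_ok = peak_g <= gmax_mT_m,
                 slew_ok = peak_s <= smax_T),
            class = "gradient_report")
}

#' @export
print.gradient_report <- function(x, ...) {
  cat(sprintf("peak |G| = %.2f mT/m (limit %.1f): %s\n", x$peak_gradient_mT_m,
              x$gmax_mT_m, if (x$gradient_ok) "PASS" else "FAIL"))
  cat(sprintf("peak slew = %.1f T/m/s (limit %g %s): %s\n", x$peak_slew_T_m_s,
              x$smax, x$smax_units, if (x$slew_ok) "PASS" else "FAIL"))
  invisible(x)
}

#' Rotated copies of a trajectory for a multi-excitation acquisition
#'
#' Each excitation reuses the same rosette shape rotated by a fixed increment
#' (golden angle by default) so that, combined over excitations, every echo's
#' k-space is densely covered.
#'
#' @param traj A `rosette_trajectory`.
#' @param n_excitations Number of excitations.
#' @param increment_deg Rotation increment per excitation in degrees.
#' @return Numeric vector of rotation angles (radians), one per excitation.
#' @export
excitation_rotations <- function(traj, n_excitations,
                                 increment_deg = 111.24611) {
  (seq_len(n_excitations) - 1) * increment_deg * pi / 180
}

#' Export / import a trajectory as plain text
#'
#' Writes samples as a 3-column CSV (`kx`, `ky`, `t_ms`) plus a JSON sidecar of
#' design parameters; `read_trajectory` reverses the operation.
#'
#' @param traj A `rosette_trajectory`.
#' @param path CSV file path; the sidecar is written alongside with extension
#'   `.json`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(kx = traj$kx, ky = traj$ky, t_ms = traj$t_ms),
                   path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(traj[c("kmax", "w1_cycles", "w2_cycles",
                              "readout_ms", "dt_us")],
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  traj <- do.call(rosette_trajectory, side)
  samples <- utils::read.csv(path)
  stopifnot(nrow(samples) == length(traj$t_ms))
  traj
}
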