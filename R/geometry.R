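# Acquisition geometry: the rosette readout, its echo segmentation with
# absolute echo times, per-excitation rotations, and cached per-echo gridding
# plans plus density weights for the union of rotated readouts.

#' Acquisition geometry for a rotated multi-excitation rosette scan
#'
#' Bundles the trajectory, its echo segmentation (echo times referenced to the
#' excitation via the configured first echo time), the per-excitation rotation
#' angles, and lazily built per-echo gridding plans with density weights.
#'
#' @param traj A [rosette_trajectory()].
#' @param schedule A [cmrf_schedule()] (supplies TE1 and the excitation count).
#' @param matrix Reconstruction matrix size.
#' @param fov_m Field of view in meters (default 0.3).
#' @param decimate Keep every `decimate`-th ADC sample (default 1 = all).
#' @param rot_increment_deg Rotation increment per excitation (golden angle).
#' @return A `cmrf_geometry` object.
#' @export
cmrf_geometry <- function(traj, schedule, matrix = 64, fov_m = 0.3,
                          decimate = 1L, rot_increment_deg = 111.24611) {
  n_exc <- nrow(schedule$excitations)
  echoes <- split_into_echoes(traj)
  # anchor the first full crossing at the configured TE1
  t_first <- echoes$echo_time_ms[2]
  te0 <- schedule$te1_ms - t_first
  echoes$echo_time_ms <- echoes$echo_time_ms + te0
  rot <- excitation_rotations(traj, n_exc, rot_increment_deg)
  seg_idx <- lapply(seq_len(nrow(echoes)), function(e) {
    idx <- echoes$start[e]:echoes$end[e]
    if (decimate > 1) idx <- idx[seq(1, length(idx), by = decimate)]
    idx
  })
  structure(list(traj = traj, echoes = echoes, te0_ms = te0,
                 rotations = rot, n_exc = n_exc, matrix = as.integer(matrix),
                 fov_m = fov_m, decimate = as.integer(decimate),
                 seg_idx = seg_idx, full = which(echoes$is_full),
                 cache = new.env(parent = emptyenv())),
            class = "cmrf_geometry")
}

#' @export
print.cmrf_geometry <- function(x, ...) {
  cat(sprintf("cMRF geometry: %d excitations, %d echoes (%d full), matrix %d\n",
              x$n_exc, nrow(x$echoes), length(x$full), x$matrix))
  invisible(x)
}

# union of rotated sample positions for segment e (excitation-major blocks)
segment_points <- function(geom, e) {
  idx <- geom$seg_idx[[e]]
  k <- complex(real = geom$traj$kx[idx], imaginary = geom$traj$ky[idx])
  as.vector(outer(k, exp(1i * geom$rotations)))
}

# absolute sample times (ms from excitation) for segment e (one excitation)
segment_times <- function(geom, e) {
  geom$te0_ms + geom$traj$t_ms[geom$seg_idx[[e]]]
}

# gridding plan for segment e; width 4 for reconstruction, cached
segment_plan <- function(geom, e, width = 4) {
  key <- sprintf("plan_%d_w%d", e, width)
  if (!is.null(geom$cache[[key]])) return(geom$cache[[key]])
  ku <- segment_points(geom, e)
  pl <- nufft_plan(Re(ku), Im(ku), geom$matrix, geom$fov_m, width = width)
  geom$cache[[key]] <- pl
  pl
}

# density weights for full segment e, cached
segment_dcf <- function(geom, e) {
  key <- sprintf("dcf_%d", e)
  if (!is.null(geom$cache[[key]])) return(geom$cache[[key]])
  w <- pipe_menon_dcf(segment_plan(geom, e))
  geom$cache[[key]] <- w
  w
}

# flat-field response of the DCF-weighted gridding reconstruction for one
# echo: reconstruction of a uniform unit image, used to normalize the smooth
# shading left by the approximate density weights
segment_flat_norm <- function(geom, e) {
  key <- sprintf("flat_%d", e)
  if (!is.null(geom$cache[[key]])) return(geom$cache[[key]])
  pl <- segment_plan(geom, e)
  w <- segment_dcf(geom, e)
  ones <- matrix(1 + 0i, geom$matrix, geom$matrix)
  r <- Re(nufft_adjoint(w * nufft_forward(ones, pl), pl))
  r <- pmax(r, 0.05 * max(r))
  geom$cache[[key]] <- r
  r
}

# excitation index per row of a segment's sample union
segment_exc_index <- function(geom, e) {
  rep(seq_len(geom$n_exc), each = length(geom$seg_idx[[e]]))
}

clear_plan_cache <- function(geom, pattern = "^plan_.*_w5$") {
  rm(list = grep(pattern, ls(geom$cache), value = TRUE), envir = geom$cache)
  invisible(geom)
}
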