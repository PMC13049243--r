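#' cMRF acquisition schedule
#'
#' Builds the excitation/preparation schedule of the 15-heartbeat rosette cMRF
#' sequence: 12 FISP excitations per heartbeat inside a diastolic acquisition
#' window, with a repeating 5-heartbeat magnetization-preparation block
#' (inversion / none / T2-prep 30 ms / T2-prep 80 ms / none) and a sinusoidal
#' flip-angle ramp between 5.7 and 20 degrees.
#'
#' @param rr_ms Per-heartbeat R-R intervals (ms); length defines the number of
#'   heartbeats.
#' @param exc_per_heartbeat Excitations per heartbeat (default 12).
#' @param tr_ms Repetition time (ms, default 20.4).
#' @param te1_ms First echo time (ms, default 1.74).
#' @param dte_ms Nominal echo spacing (ms, default 0.79).
#' @param flip_range_deg Flip-angle extrema (default `c(5.7, 20)`).
#' @param prep_pattern Character vector recycled over heartbeats; entries
#'   `"inversion"`, `"none"`, or `"t2prep:<TE ms>"`.
#' @param ti_ms Delay from inversion to the first excitation (ms, default 21).
#' @param flip_deg Optional explicit per-excitation flip angles overriding the
#'   default ramp.
#' @return A `cmrf_schedule` object.
#' @examples
#' sched <- cmrf_schedule(rep(1000, 15))
#' nrow(sched$excitations)  # 180
#' @export
cmrf_schedule <- function(rr_ms = rep(1000, 15), exc_per_heartbeat = 12,
                          tr_ms = 20.4, te1_ms = 1.74, dte_ms = 0.79,
                          flip_range_deg = c(5.7, 20),
                          prep_pattern = c("inversion", "none",
                                           "t2prep:30", "t2prep:80", "none"),
                          ti_ms = 21, flip_deg = NULL) {
  n_hb <- length(rr_ms)
  if (n_hb < 1) stop("at least one heartbeat is required", call. = FALSE)
  window_ms <- exc_per_heartbeat * tr_ms
  if (any(rr_ms <= window_ms))
    stop(sprintf("R-R interval shorter than the %.0f ms acquisition window",
                 window_ms), call. = FALSE)
  if (is.null(flip_deg)) {
    i <- seq_len(exc_per_heartbeat)
    ramp <- flip_range_deg[1] + diff(flip_range_deg) *
      (1 - cos(2 * pi * (i - 1) / exc_per_heartbeat)) / 2
    flip_deg <- rep(ramp, n_hb)
  }
  stopifnot(length(flip_deg) == n_hb * exc_per_heartbeat)
  prep <- rep_len(prep_pattern, n_hb)
  exc <- data.frame(heartbeat = rep(seq_len(n_hb), each = exc_per_heartbeat),
                    flip_deg = flip_deg)
  structure(list(excitations = exc, prep = prep, rr_ms = rr_ms,
                 tr_ms = tr_ms, te1_ms = te1_ms, dte_ms = dte_ms,
                 exc_per_heartbeat = exc_per_heartbeat, ti_ms = ti_ms,
                 n_heartbeats = n_hb, window_ms = window_ms),
            class = "cmrf_schedule")
}

#' @export
print.cmrf_schedule <- function(x, ...) {
  cat(sprintf("cMRF schedule: %d heartbeats x %d excitations (TR %.1f ms)\n",
              x$n_heartbeats, x$exc_per_heartbeat, x$tr_ms))
  cat(sprintf("  flip angles %.1f-%.1f deg, prep: %s ...\n",
              min(x$excitations$flip_deg), max(x$excitations$flip_deg),
              paste(utils::head(x$prep, 5), collapse = ", ")))
  invisible(x)
}

#' Slice-profile effective flip angles
#'
#' Discretizes the small-tip excitation profile of a Hamming-windowed sinc
#' pulse (time-bandwidth product `time_bandwidth`) into `n_subslices`
#' positions across the nominal slice, returning the relative profile
#' amplitude at each position. Effective flip angles are the nominal flip
#' scaled by these weights; fingerprints are averaged over subslices.
#'
#' @param rf List with fields `duration_us`, `time_bandwidth`, `n_subslices`
#'   (see [rf_pulse_spec()]).
#' @param nominal_flip_deg Nominal flip angle (degrees).
#' @return Vector of effective flip angles, one per subslice.
#' @export
slice_profile_weights <- function(rf, nominal_flip_deg = 1) {
  n <- rf$n_subslices
  if (n < 1) stop("n_subslices must be >= 1", call. = FALSE)
  if (n == 1) return(nominal_flip_deg)
  prof <- slice_profile_shape(rf$time_bandwidth)
  # subslice positions uniformly across the nominal slice (full width = TBP
  # bandwidth mapped to unit thickness)
  z <- seq(-0.5, 0.5, length.out = n)
  w <- stats::approx(prof$z, prof$a, xout = z, rule = 2)$y
  nominal_flip_deg * w
}

# small-tip profile: |FT| of the windowed sinc, z in units of slice thickness
slice_profile_shape <- function(tbp, n_t = 256, n_pad = 4096) {
  tt <- seq(-0.5, 0.5, length.out = n_t)
  b1 <- sin(pi * tbp * tt + 1e-12) / (pi * tbp * tt + 1e-12)
  b1 <- b1 * (0.54 + 0.46 * cos(2 * pi * tt))
  p <- c(b1, rep(0, n_pad - n_t))
  prof <- abs(stats::fft(p))
  prof <- prof / max(prof)
  # frequency axis in units of pulse bandwidth: df = 1/n_pad per unit time;
  # slice thickness corresponds to the TBP bandwidth
  f <- c(seq(0, n_pad / 2 - 1), seq(-n_pad / 2, -1)) * (n_t / n_pad)
  z <- f / tbp
  o <- order(z)
  list(z = z[o], a = prof[o])
}

#' RF pulse specification
#' @param duration_us Pulse duration (microseconds, default 800).
#' @param time_bandwidth Time-bandwidth product (default 2).
#' @param n_subslices Slice-profile discretization count (default 5).
#' @return A list used by the simulation routines.
#' @export
rf_pulse_spec <- function(duration_us = 800, time_bandwidth = 2, n_subslices = 5) {
  if (n_subslices < 1) stop("n_subslices must be >= 1", call. = FALSE)
  list(duration_us = duration_us, time_bandwidth = time_bandwidth,
       n_subslices = n_subslices)
}

parse_prep <- function(prep) {
  lapply(prep, function(p) {
    if (identical(p, "inversion")) return(list(type = "inversion"))
    if (identical(p, "none")) return(list(type = "none"))
    if (grepl("^t2prep:", p))
      return(list(type = "t2prep", te_ms = as.numeric(sub("^t2prep:", "", p))))
    stop("unknown preparation event: ", p, call. = FALSE)
  })
}
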