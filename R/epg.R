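# Extended phase graph (EPG) simulation of the FISP cMRF sequence, vectorized
# over dictionary entries. States are stored as (n_states x n_entries)
# complex matrices Fp (F_k), Fm (conjugate of F_{-k}) and Z (Z_k); the
# unbalanced FISP spoiler advances dephasing by one state order per TR.

epg_rf <- function(st, alpha_rad) {
  # alpha_rad may vary per column (entry); broadcast over rows
  ca2 <- rep(cos(alpha_rad / 2)^2, each = nrow(st$Fp))
  sa2 <- rep(sin(alpha_rad / 2)^2, each = nrow(st$Fp))
  sa <- rep(sin(alpha_rad), each = nrow(st$Fp))
  ca <- rep(cos(alpha_rad), each = nrow(st$Fp))
  Fp <- ca2 * st$Fp + sa2 * st$Fm - 1i * sa * st$Z
  Fm <- sa2 * st$Fp + ca2 * st$Fm + 1i * sa * st$Z
  Z <- -0.5i * sa * st$Fp + 0.5i * sa * st$Fm + ca * st$Z
  list(Fp = Fp, Fm = Fm, Z = Z)
}

epg_relax <- function(st, dt_ms, e1, e2) {
  # e1, e2: row vectors exp(-dt/T1), exp(-dt/T2) per entry (recycled by row)
  Fp <- sweep(st$Fp, 2, e2, "*")
  Fm <- sweep(st$Fm, 2, e2, "*")
  Z <- sweep(st$Z, 2, e1, "*")
  Z[1, ] <- Z[1, ] + (1 - e1)
  list(Fp = Fp, Fm = Fm, Z = Z)
}

epg_shift <- function(st) {
  n <- nrow(st$Fp)
  Fp <- rbind(Conj(st$Fm[2, , drop = FALSE]), st$Fp[-n, , drop = FALSE])
  Fm <- rbind(st$Fm[-1, , drop = FALSE], 0 * st$Fm[1, , drop = FALSE])
  list(Fp = Fp, Fm = Fm, Z = st$Z)
}

#' Simulate cMRF fingerprints for a set of (T1, T2) entries
#'
#' EPG simulation of the FISP cMRF sequence with inversion and T2-preparation
#' events, per-heartbeat recovery gaps and optional slice-profile correction
#' (signals averaged over subslice flip scales). The returned signal is the
#' transverse state at the first echo time of each excitation; T2*/fat
#' evolution along the multi-echo readout is applied by the acquisition
#' simulator, not here.
#'
#' @param t1_ms,t2_ms Equal-length vectors of relaxation times.
#' @param schedule A [cmrf_schedule()].
#' @param rf An [rf_pulse_spec()]; `n_subslices = 1` disables slice-profile
#'   correction.
#' @param inversion_efficiency Magnitude of longitudinal inversion (default
#'   0.95).
#' @param n_states Number of EPG dephasing orders retained (default 13).
#' @return Complex matrix (excitations x entries).
#' @export
epg_fingerprints <- function(t1_ms, t2_ms, schedule, rf = rf_pulse_spec(),
                             inversion_efficiency = 0.95, n_states = 13) {
  stopifnot(length(t1_ms) == length(t2_ms))
  if (any(t2_ms > t1_ms))
    stop("invalid entries: T2 exceeds T1", call. = FALSE)
  if (any(t2_ms <= 0)) stop("relaxation times must be positive", call. = FALSE)
  prof <- slice_profile_weights(rf, 1)
  n_sub <- length(prof)
  n_ent <- length(t1_ms)
  # replicate entries per subslice: columns grouped entry-major
  t1 <- rep(t1_ms, each = n_sub)
  t2 <- rep(t2_ms, each = n_sub)
  scale <- rep(prof, times = n_ent)
  sig <- epg_run(t1, t2, scale, schedule, inversion_efficiency, n_states)
  if (n_sub == 1) return(sig)
  # average over subslices
  idx <- rep(seq_len(n_ent), each = n_sub)
  out <- matrix(0 + 0i, nrow(sig), n_ent)
  for (k in seq_len(n_sub)) out <- out + sig[, seq(k, by = n_sub, length.out = n_ent), drop = FALSE]
  out / n_sub
}

epg_run <- function(t1, t2, flip_scale, schedule, inv_eff, n_states) {
  n_col <- length(t1)
  n_exc <- nrow(schedule$excitations)
  prep <- parse_prep(schedule$prep)
  tr <- schedule$tr_ms
  te <- schedule$te1_ms
  zero <- matrix(0 + 0i, n_states, n_col)
  st <- list(Fp = zero, Fm = zero, Z = zero)
  st$Z[1, ] <- 1
  e1_tr <- exp(-tr / t1); e2_tr <- exp(-tr / t2)
  e2_te <- exp(-te / t2)
  sig <- matrix(0 + 0i, n_exc, n_col)
  i_exc <- 0
  for (hb in seq_len(schedule$n_heartbeats)) {
    pv <- prep[[hb]]
    used_ms <- 0
    if (pv$type == "inversion") {
      st$Z <- -inv_eff * st$Z
      st$Fp[] <- 0; st$Fm[] <- 0
      ti <- schedule$ti_ms
      st <- epg_relax(st, ti, exp(-ti / t1), exp(-ti / t2))
      used_ms <- ti
    } else if (pv$type == "t2prep") {
      st$Z <- sweep(st$Z, 2, exp(-pv$te_ms / t2), "*")
      st$Fp[] <- 0; st$Fm[] <- 0
    }
    for (i in seq_len(schedule$exc_per_heartbeat)) {
      i_exc <- i_exc + 1
      alpha <- schedule$excitations$flip_deg[i_exc] * pi / 180 * flip_scale
      st <- epg_rf(st, alpha)
      sig[i_exc, ] <- st$Fp[1, ] * e2_te
      st <- epg_relax(st, tr, e1_tr, e2_tr)
      st <- epg_shift(st)
    }
    gap <- schedule$rr_ms[hb] - schedule$window_ms - used_ms
    if (gap > 0) st <- epg_relax(st, gap, exp(-gap / t1), exp(-gap / t2))
  }
  sig
}

#' Simulate a single cMRF fingerprint
#'
#' Convenience wrapper around [epg_fingerprints()] for one (T1, T2) pair.
#'
#' @inheritParams epg_fingerprints
#' @return Complex vector over excitations.
#' @export
simulate_fingerprint <- function(t1_ms, t2_ms, schedule, rf = rf_pulse_spec(),
                                 inversion_efficiency = 0.95, n_states = 13) {
  if (t2_ms > t1_ms) stop("invalid entries: T2 exceeds T1", call. = FALSE)
  drop(epg_fingerprints(t1_ms, t2_ms, schedule, rf, inversion_efficiency,
                        n_states))
}
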