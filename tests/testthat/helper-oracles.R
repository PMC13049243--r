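# Independent oracles used to validate the package's fast implementations.

# Brute-force isochromat Bloch simulation of the FISP cMRF sequence with ideal
# spoiling: n_spins equally spaced dephasing increments per TR. Rotation
# convention matches the EPG engine (flip about x: Mz -> -sin(a) My').
iso_bloch_fingerprint <- function(t1, t2, sched, inv_eff = 0.95,
                                  n_spins = 500) {
  phi <- 2 * pi * ((seq_len(n_spins) - 0.5) / n_spins)
  Mx <- My <- rep(0, n_spins); Mz <- rep(1, n_spins)
  tr <- sched$tr_ms; te <- sched$te1_ms
  relax <- function(dt) {
    e1 <- exp(-dt / t1); e2 <- exp(-dt / t2)
    Mx <<- Mx * e2; My <<- My * e2; Mz <<- Mz * e1 + (1 - e1)
  }
  rot <- function(a) {
    My2 <- cos(a) * My - sin(a) * Mz
    Mz2 <- sin(a) * My + cos(a) * Mz
    My <<- My2; Mz <<- Mz2
  }
  dephase <- function() {
    c0 <- cos(phi); s0 <- sin(phi)
    Mx2 <- c0 * Mx - s0 * My; My2 <- s0 * Mx + c0 * My
    Mx <<- Mx2; My <<- My2
  }
  sig <- rep(0 + 0i, nrow(sched$excitations))
  i_exc <- 0
  for (hb in seq_len(sched$n_heartbeats)) {
    pv <- sched$prep[hb]
    used <- 0
    if (pv == "inversion") {
      Mz <- -inv_eff * Mz; Mx[] <- 0; My[] <- 0
      relax(sched$ti_ms); used <- sched$ti_ms
    } else if (grepl("^t2prep:", pv)) {
      tep <- as.numeric(sub("^t2prep:", "", pv))
      Mz <- Mz * exp(-tep / t2); Mx[] <- 0; My[] <- 0
    }
    for (i in seq_len(sched$exc_per_heartbeat)) {
      i_exc <- i_exc + 1
      rot(sched$excitations$flip_deg[i_exc] * pi / 180)
      sig[i_exc] <- mean(Mx + 1i * My) * exp(-te / t2)
      relax(tr)
      dephase()
    }
    gap <- sched$rr_ms[hb] - sched$window_ms - used
    if (gap > 0) relax(gap)
  }
  sig
}

# Exhaustive pattern-matching oracle over an uncompressed dictionary
brute_force_match <- function(signal, signals_unit, entries, norms) {
  corr <- abs(Conj(signal) %*% signals_unit)
  best <- which.max(corr)
  proj <- sum(signal * Conj(signals_unit[, best])) / norms[best]
  list(t1_ms = entries$t1_ms[best], t2_ms = entries$t2_ms[best],
       m0 = proj, index = best)
}

# numeric-integration oracle for the readout response at small off-resonance
response_numeric_oracle <- function(traj, f_hz, t2star_ms = 20) {
  t_s <- traj$t_ms / 1000
  w <- exp(-traj$t_ms / t2star_ms)
  abs(sum(w * exp(1i * 2 * pi * f_hz * t_s))) / sum(w)
}
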