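#' Dictionary grid configuration
#'
#' Default T1/T2 grids of the cMRF dictionary. Entries with T2 > T1 are
#' physically invalid and excluded, leaving 28010 combinations on the default
#' grids.
#'
#' @param t1_grid_ms,t2_grid_ms Strictly increasing grids (ms).
#' @param inversion_efficiency Scalar in (0, 1] (default 0.95).
#' @return A list of class `dictionary_config`.
#' @export
dictionary_config <- function(t1_grid_ms = c(seq(10, 2000, 10), seq(2020, 3000, 20)),
                              t2_grid_ms = c(seq(6, 100, 2), seq(105, 300, 5),
                                             seq(310, 500, 10), seq(540, 1180, 40)),
                              inversion_efficiency = 0.95) {
  if (is.unsorted(t1_grid_ms, strictly = TRUE) ||
      is.unsorted(t2_grid_ms, strictly = TRUE))
    stop("grids must be strictly increasing", call. = FALSE)
  if (inversion_efficiency <= 0 || inversion_efficiency > 1)
    stop("inversion efficiency must lie in (0, 1]", call. = FALSE)
  structure(list(t1_grid_ms = t1_grid_ms, t2_grid_ms = t2_grid_ms,
                 inversion_efficiency = inversion_efficiency),
            class = "dictionary_config")
}

#' Enumerate valid dictionary entries
#'
#' @param cfg A [dictionary_config()].
#' @return Data frame with columns `t1_ms`, `t2_ms`, all pairs with
#'   T2 <= T1 in T2-major order.
#' @export
dictionary_entries <- function(cfg = dictionary_config()) {
  g <- expand.grid(t2_ms = cfg$t2_grid_ms, t1_ms = cfg$t1_grid_ms)
  g <- g[g$t2_ms <= g$t1_ms, c("t1_ms", "t2_ms")]
  rownames(g) <- NULL
  g
}

#' Build the cMRF dictionary
#'
#' Simulates one fingerprint per valid (T1, T2) grid pair for the given
#' schedule using the EPG engine with slice-profile and inversion-efficiency
#' corrections. Signals are stored unit-L2-normalized with the norms kept
#' separately so matched amplitudes remain proportional to spin density.
#'
#' @param cfg A [dictionary_config()].
#' @param schedule A [cmrf_schedule()].
#' @param rf An [rf_pulse_spec()].
#' @param chunk Entries simulated per block (memory control).
#' @return Object of class `cmrf_dictionary` with fields `entries` (data
#'   frame), `signals` (excitations x entries, unit columns), `norms`.
#' @export
build_dictionary <- function(cfg = dictionary_config(), schedule, rf = rf_pulse_spec(),
                             chunk = 4000) {
  entries <- dictionary_entries(cfg)
  if (nrow(entries) == 0) stop("empty dictionary grid", call. = FALSE)
  n_exc <- nrow(schedule$excitations)
  sig <- matrix(0 + 0i, n_exc, nrow(entries))
  i <- 1
  while (i <= nrow(entries)) {
    j <- min(i + chunk - 1, nrow(entries))
    sig[, i:j] <- epg_fingerprints(entries$t1_ms[i:j], entries$t2_ms[i:j],
                                   schedule, rf, cfg$inversion_efficiency)
    i <- j + 1
  }
  norms <- sqrt(colSums(abs(sig)^2))
  sig <- sweep(sig, 2, pmax(norms, .Machine$double.eps), "/")
  structure(list(entries = entries, signals = sig, norms = norms,
                 config = cfg),
            class = "cmrf_dictionary")
}

#' @export
print.cmrf_dictionary <- function(x, ...) {
  cat(sprintf("cMRF dictionary: %d entries x %d excitations\n",
              nrow(x$entries), nrow(x$signals)))
  invisible(x)
}

#' Compress a dictionary to a low-rank temporal subspace
#'
#' Computes the dominant left singular vectors of the fingerprint matrix; the
#' resulting orthonormal basis spans the temporal subspace in which images are
#' reconstructed, and the compressed dictionary holds each atom's subspace
#' coefficients.
#'
#' @param dict A `cmrf_dictionary`.
#' @param rank Subspace rank (default 10).
#' @return List of class `cmrf_subspace` with `basis` (excitations x rank,
#'   orthonormal), `compressed` (rank x entries), `singular_values`,
#'   `energy_fraction`, and the dictionary's `entries`/`norms`.
#' @export
compress_dictionary <- function(dict, rank = 10) {
  n_exc <- nrow(dict$signals)
  n_ent <- ncol(dict$signals)
  if (rank > min(n_exc, n_ent))
    stop("rank exceeds dictionary dimensions", call. = FALSE)
  G <- dict$signals %*% Conj(t(dict$signals))
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(Re(eg$values), 0)
  basis <- eg$vectors[, seq_len(rank), drop = FALSE]
  compressed <- Conj(t(basis)) %*% dict$signals
  structure(list(basis = basis,
                 compressed = compressed,
                 singular_values = sqrt(vals),
                 energy_fraction = sum(vals[seq_len(rank)]) / sum(vals),
                 entries = dict$entries, norms = dict$norms, rank = rank),
            class = "cmrf_subspace")
}

#' @export
print.cmrf_subspace <- function(x, ...) {
  cat(sprintf("cMRF subspace: rank %d, %.3f%% of fingerprint energy\n",
              x$rank, 100 * x$energy_fraction))
  invisible(x)
}
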