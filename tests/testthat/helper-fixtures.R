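# Shared fixtures, memoized across test files (test_dir runs them in one
# session). Expensive objects (dictionaries, simulated k-space) are built once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_schedule <- function() fixture("schedule", function() cmrf_schedule(rep(1000, 15)))

fix_rf3 <- function() rf_pulse_spec(n_subslices = 3)

# reduced-grid dictionary + rank-10 subspace for pipeline tests
fix_subspace_small <- function() fixture("subspace_small", function() {
  cfg <- dictionary_config(t1_grid_ms = seq(100, 2000, 25),
                           t2_grid_ms = seq(6, 300, 4))
  dict <- build_dictionary(cfg, fix_schedule(), fix_rf3())
  compress_dictionary(dict, 10)
})

# full printed-grid dictionary + subspace (acceptance-fidelity matching)
fix_subspace_full <- function() fixture("subspace_full", function() {
  dict <- build_dictionary(dictionary_config(), fix_schedule(), rf_pulse_spec())
  compress_dictionary(dict, 10)
})

# standard reduced-scale geometry at matrix 64
fix_geom64 <- function() fixture("geom64", function() {
  cmrf_geometry(rosette_trajectory(kmax = 64 / 0.6), fix_schedule(),
                matrix = 64, decimate = 2)
})

# noiseless healthy-phantom single-coil acquisition at matrix 64
fix_kspace_healthy <- function() fixture("kspace_healthy", function() {
  simulate_acquisition(make_cardiac_phantom(64, "healthy"), fix_schedule(),
                       fix_geom64(), NULL, rf = fix_rf3())
})

# tiny disk phantom helper
disk_phantom <- function(n, t1 = 950, t2 = 48, t2star = 1e6, pdff = 0,
                         radius = 0.3, fov_mm = 300) {
  lab <- matrix(0L, n, n)
  xs <- (seq_len(n) - n / 2 - 0.5) / n
  lab[outer(xs, xs, function(x, y) x^2 + y^2) < radius^2] <- 1L
  props <- data.frame(label = 1L, tissue = "disk", t1_ms = t1, t2_ms = t2,
                      t2star_ms = t2star, pdff = pdff, m0 = 1,
                      fat_t1_ms = 250, fat_t2_ms = 60, fat_t2star_ms = 20)
  structure(list(label = lab, properties = props, matrix = n, fov_mm = fov_mm),
            class = "digital_phantom")
}

# random orthonormal complex basis
random_basis <- function(n_exc, rank, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(n_exc * rank) + 1i * stats::rnorm(n_exc * rank),
                 n_exc, rank)))
}
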