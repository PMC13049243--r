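#' Run the five-stage rosette cMRF mapping pipeline
#'
#' Executes the full reconstruction chain on measured or simulated k-space:
#' (1) pre-computation of dictionary, subspace basis, density weights,
#' off-resonance and coil maps; (2) reconstruction of subspace-echo images
#' (direct gridding, locally-low-rank iteration, or deep image prior);
#' (3) voxelwise dual-exponential T2* fitting; (4) IDEAL water/fat separation
#' followed by dictionary pattern matching of both components; (5) fat
#' fraction computation from the matched spin densities.
#'
#' @param phantom A `digital_phantom` to simulate from (omit when `kspace`
#'   given).
#' @param kspace A `cmrf_kspace` (omit to simulate from `phantom`).
#' @param method Reconstruction method: `"dip"`, `"direct"` or `"lowrank"`.
#' @param matrix Reconstruction matrix (default 64); the rosette `kmax` is
#'   tied to it as `matrix / (2 FOV)` so the readout is Nyquist-consistent.
#' @param fov_mm Field of view (default 300).
#' @param n_coils Simulated receive coils (default 1).
#' @param b0_peak_hz Peak of the simulated smooth off-resonance map (0
#'   disables off-resonance in simulation).
#' @param noise_pct Simulated complex noise SD as a fraction of peak signal.
#' @param seed Seed for simulation noise and the DIP network.
#' @param schedule A [cmrf_schedule()]; default 15 heartbeats at RR 1000 ms.
#' @param subspace Optional precomputed `cmrf_subspace` (skips dictionary
#'   simulation; must match the schedule).
#' @param rank Subspace rank when the dictionary is built here (default 10).
#' @param decimate Readout decimation for reconstruction (default 2).
#' @param dip A [dip_config()].
#' @param lowrank A [lowrank_config()].
#' @param rf An [rf_pulse_spec()].
#' @param inversion_efficiency Inversion efficiency (default 0.95).
#' @param geom Optional precomputed [cmrf_geometry()] (its cached gridding
#'   plans and density weights are reused; must match `matrix`, the schedule
#'   and `decimate`).
#' @param verbose Progress messages.
#' @return An object of class `cmrf_fit` containing the tissue maps, the
#'   reconstructed subspace-echo images, estimated fields, per-region summary
#'   (when simulated from a phantom) and the resolved configuration.
#' @export
cmrf_pipeline <- function(phantom = NULL, kspace = NULL,
                          method = c("dip", "direct", "lowrank"),
                          matrix = 64, fov_mm = 300, n_coils = 1,
                          b0_peak_hz = 0, noise_pct = 0, seed = 1,
                          schedule = NULL, subspace = NULL, rank = 10,
                          decimate = 2, dip = dip_config(conv_channels = 48,
                                                         seed = seed),
                          lowrank = lowrank_config(), rf = rf_pulse_spec(),
                          inversion_efficiency = 0.95, geom = NULL,
                          verbose = FALSE) {
  method <- match.arg(method)
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(schedule)) schedule <- cmrf_schedule(rep(1000, 15))
  fov_m <- fov_mm / 1000
  kmax <- matrix / (2 * fov_m)
  if (is.null(geom)) {
    traj <- rosette_trajectory(kmax = kmax)
    geom <- cmrf_geometry(traj, schedule, matrix = matrix, fov_m = fov_m,
                          decimate = decimate)
  } else {
    stopifnot(geom$matrix == matrix, geom$decimate == decimate)
  }

  say("stage 1: dictionary and subspace basis")
  if (is.null(subspace)) {
    dict <- build_dictionary(dictionary_config(inversion_efficiency =
                                                 inversion_efficiency),
                             schedule, rf)
    subspace <- compress_dictionary(dict, rank)
  }
  basis <- subspace$basis

  sim_field <- NULL
  if (is.null(kspace)) {
    if (is.null(phantom)) stop("either phantom or kspace is required", call. = FALSE)
    say("simulating acquisition (%d coils, noise %.1f%%)", n_coils,
        100 * noise_pct)
    coils <- if (n_coils > 1) make_birdcage_coils(matrix, n_coils)
             else array(1 + 0i, c(matrix, matrix, 1))
    b0 <- if (b0_peak_hz > 0) make_b0_map(matrix, b0_peak_hz, phantom)
          else base::matrix(0, matrix, matrix)
    sim_field <- field_model(b0, coils)
    kspace <- simulate_acquisition(phantom, schedule, geom, sim_field,
                                   noise_pct = noise_pct, seed = seed, rf = rf,
                                   inversion_efficiency = inversion_efficiency)
  }
  gc(FALSE)

  say("stage 1: off-resonance and coil maps")
  echo_imgs <- echo_images_first_subspace(kspace, geom, basis)
  mask <- support_mask(echo_imgs)
  te_ms <- geom$echoes$echo_time_ms[geom$full]
  b0_est <- estimate_b0(echo_imgs, te_ms, mask = mask)
  if (kspace$n_coils > 1) {
    corr <- b0_demodulate(echo_imgs, b0_est$b0_hz, te_ms)
    coil_maps <- estimate_coils(corr, mask = mask)
  } else {
    coil_maps <- array(1 + 0i, c(matrix, matrix, 1))
  }
  field <- field_model(b0_est$b0_hz, coil_maps,
                       fat_shift_hz = kspace$fat_shift_hz, mask = mask)

  say("stage 2: %s reconstruction", method)
  imgs <- switch(method,
    direct = recon_direct(kspace, geom, field, basis),
    lowrank = recon_lowrank(kspace, geom, field, basis, cfg = lowrank,
                            verbose = verbose),
    dip = recon_dip(kspace, geom, field, basis, cfg = dip, verbose = verbose))

  say("stage 3: dual-exponential T2* fitting")
  sub1 <- imgs[, , 1, ]
  sub1 <- b0_demodulate(sub1, field$b0_hz, te_ms)
  t2star <- fit_dual_t2star(sub1, te_ms, field$fat_shift_hz, mask = mask)

  say("stage 4: IDEAL separation and pattern matching")
  sep <- ideal_separate(imgs, field$b0_hz, t2star, te_ms, field$fat_shift_hz)
  mw <- pattern_match(sep$water, subspace, mask = mask)
  mf <- pattern_match(sep$fat, subspace, mask = mask)

  say("stage 5: fat fraction")
  pd <- compute_pdff(mw$m0, mf$m0)

  maps <- list(t1_w = mw$t1_ms, t2_w = mw$t2_ms, t2star_w = t2star$t2star_w,
               t1_f = mf$t1_ms, t2_f = mf$t2_ms, t2star_f = t2star$t2star_f,
               m0_w = mw$m0, m0_f = mf$m0, pdff = pd$pdff)
  fit <- structure(list(
    maps = maps, images = imgs, mask = mask,
    field = field, b0_sim = sim_field, t2star = t2star,
    subspace_entries = subspace$entries,
    method = method, phantom = phantom,
    te_ms = te_ms, loss = attr(imgs, "loss"),
    objective = attr(imgs, "objective"),
    config = list(method = method, matrix = matrix, fov_mm = fov_mm,
                  n_coils = n_coils, b0_peak_hz = b0_peak_hz,
                  noise_pct = noise_pct, seed = seed, rank = rank,
                  decimate = decimate, kmax = kmax,
                  dip = dip, lowrank = lowrank,
                  inversion_efficiency = inversion_efficiency),
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "cmrf_fit")
  if (!is.null(phantom)) fit$summary <- summarize_rois(fit, phantom)
  fit
}

#' Region-of-interest statistics
#'
#' Mean, voxelwise standard deviation and count of a map over a labeled
#' region, optionally after morphological erosion of the region (to exclude
#' partial-volume boundary voxels, the package's ROI convention).
#'
#' @param map Numeric matrix.
#' @param label_map Integer matrix of the same size.
#' @param label Region label.
#' @param erode Erosion radius in pixels (default 0).
#' @return List with `mean`, `sd`, `n`.
#' @export
roi_stats <- function(map, label_map, label, erode = 0) {
  stopifnot(all(dim(map) == dim(label_map)))
  m <- label_map == label
  if (erode > 0) m <- erode_mask(m, erode)
  if (!any(m)) stop("empty region of interest", call. = FALSE)
  v <- map[m]
  list(mean = mean(v), sd = stats::sd(v), n = sum(m))
}

erode_mask <- function(m, r = 1) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  for (k in seq_len(r)) {
    p <- out
    shr <- p
    shr[-1, ] <- shr[-1, ] & p[-n1, ]
    shr[-n1, ] <- shr[-n1, ] & p[-1, ]
    shr[, -1] <- shr[, -1] & p[, -n2]
    shr[, -n2] <- shr[, -n2] & p[, -1]
    out <- shr
  }
  out
}

summarize_rois <- function(fit, phantom, erode = 1) {
  props <- phantom$properties
  rows <- list()
  for (r in seq_len(nrow(props))) {
    lab <- props$label[r]
    m <- phantom$label == lab
    if (sum(erode_mask(m, erode)) < 4) next
    stats_of <- function(map) roi_stats(map, phantom$label, lab, erode = erode)
    t1 <- stats_of(fit$maps$t1_w); t2 <- stats_of(fit$maps$t2_w)
    t2s <- stats_of(fit$maps$t2star_w); pf <- stats_of(fit$maps$pdff)
    rows[[length(rows) + 1]] <- data.frame(
      tissue = props$tissue[r], label = lab, n = t1$n,
      t1_true = props$t1_ms[r], t1_mean = t1$mean, t1_sd = t1$sd,
      t2_true = props$t2_ms[r], t2_mean = t2$mean, t2_sd = t2$sd,
      t2star_true = props$t2star_ms[r], t2star_mean = t2s$mean,
      t2star_sd = t2s$sd,
      pdff_true = props$pdff[r], pdff_mean = pf$mean, pdff_sd = pf$sd)
  }
  do.call(rbind, rows)
}

#' @export
print.cmrf_fit <- function(x, ...) {
  cat(sprintf("rosette cMRF fit (%s reconstruction, matrix %d)\n",
              x$method, x$config$matrix))
  cat(sprintf("  runtime %.1f s\n", x$runtime_s))
  if (!is.null(x$summary)) {
    cat("  region summary (water maps, mean +/- voxelwise SD):\n")
    s <- x$summary
    for (r in seq_len(nrow(s))) {
      cat(sprintf("   %-12s T1 %6.0f/%6.1f+-%-5.1f T2 %5.0f/%5.1f+-%-4.1f T2* %4.0f/%5.1f+-%-4.1f PDFF %4.1f%%/%4.1f%%\n",
                  s$tissue[r], s$t1_true[r], s$t1_mean[r], s$t1_sd[r],
                  s$t2_true[r], s$t2_mean[r], s$t2_sd[r],
                  s$t2star_true[r], s$t2star_mean[r], s$t2star_sd[r],
                  100 * s$pdff_true[r], 100 * s$pdff_mean[r]))
    }
  }
  invisible(x)
}

#' @export
summary.cmrf_fit <- function(object, ...) {
  out <- list(method = object$method, config = object$config,
              summary = object$summary,
              final_loss = if (!is.null(object$loss)) utils::tail(object$loss, 1)
                           else NULL)
  class(out) <- "summary.cmrf_fit"
  out
}

#' @export
print.summary.cmrf_fit <- function(x, ...) {
  cat(sprintf("cMRF %s reconstruction\n", x$method))
  if (!is.null(x$final_loss))
    cat(sprintf("final data-consistency loss: %.4g\n", x$final_loss))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cmrf_fit <- function(object, ...) {
  if (is.null(object$summary)) return(NULL)
  s <- object$summary
  stats::setNames(
    c(s$t1_mean, s$t2_mean, s$t2star_mean, s$pdff_mean),
    c(paste0("t1_", s$tissue), paste0("t2_", s$tissue),
      paste0("t2star_", s$tissue), paste0("pdff_", s$tissue)))
}

#' @export
plot.cmrf_fit <- function(x, which = c("t1_w", "t2_w", "t2star_w", "pdff"),
                          ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  lims <- list(t1_w = c(0, 2000), t2_w = c(0, 300), t2star_w = c(0, 100),
               pdff = c(0, 1))
  for (w in which) {
    m <- x$maps[[w]]
    m <- pmin(pmax(Re(m), lims[[w]][1]), lims[[w]][2])
    graphics::image(t(m)[, nrow(m):1], axes = FALSE, main = w,
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  invisible(x)
}

#' Regional fat fraction from coherently averaged spin densities
#'
#' Averages the complex water and fat densities over a region before forming
#' the fat fraction. Spurious fat with random phase across voxels cancels in
#' the average while genuine fat adds coherently, so the regional estimate is
#' far less noise-biased than averaging the voxelwise fat-fraction map.
#'
#' @param m0_w,m0_f Complex spin-density maps.
#' @param label_map Integer region labels.
#' @param label Region to evaluate.
#' @param erode Erosion radius applied to the region (default 1).
#' @return Scalar fat fraction in `[0, 1]`.
#' @export
roi_pdff <- function(m0_w, m0_f, label_map, label, erode = 1) {
  m <- label_map == label
  if (erode > 0) m <- erode_mask(m, erode)
  if (!any(m)) stop("empty region of interest", call. = FALSE)
  compute_pdff(matrix(mean(m0_w[m])), matrix(mean(m0_f[m])))$pdff[1]
}

#' Confounder correlation analysis over the vial phantom
#'
#' Pearson correlation between each simulated property and each measured
#' property across vials, with two-sided significance tests: on-target
#' (diagonal) correlations are expected significant, off-target ones not.
#'
#' @param true_props Data frame with columns `t1_ms`, `t2_ms`, `t2star_ms`,
#'   `pdff` (one row per vial).
#' @param measured Data frame with the same columns (per-vial ROI means).
#' @param alpha Significance level (default 0.05).
#' @return List with `r` (4x4 correlation matrix, simulated x measured),
#'   `p` (p-values), `significant` (logical).
#' @export
confounder_pcc <- function(true_props, measured, alpha = 0.05) {
  vars <- c("t1_ms", "t2_ms", "t2star_ms", "pdff")
  if (nrow(true_props) < 3) stop("need at least 3 vials", call. = FALSE)
  stopifnot(nrow(true_props) == nrow(measured))
  r <- p <- matrix(NA_real_, 4, 4, dimnames = list(vars, vars))
  for (i in 1:4) for (j in 1:4) {
    ct <- stats::cor.test(true_props[[vars[i]]], measured[[vars[j]]])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, significant = p < alpha, alpha = alpha)
}
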