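# Reconstruction of subspace-echo images from rosette cMRF k-space by
# (i) direct DCF-weighted adjoint gridding, (ii) conjugate-gradient /
# proximal iteration with locally-low-rank and total-variation penalties,
# (iii) per-scan deep-image-prior optimization through the encoding model.

#' Direct gridding reconstruction
#'
#' Projects the data onto the temporal subspace, grids each echo with density
#' compensation and combines coils with conjugate sensitivities.
#'
#' @param kspace A `cmrf_kspace`.
#' @param geom A [cmrf_geometry()].
#' @param field A [field_model()] (or NULL).
#' @param basis Subspace basis.
#' @param b0_correction Remove the per-echo static off-resonance phase.
#' @return Complex array (n, n, rank, n_echoes) of class `echo_image_set`.
#' @export
recon_direct <- function(kspace, geom, field = NULL, basis,
                         b0_correction = TRUE) {
  op <- cmrf_operator(geom, field, basis, b0_correction)
  dcf <- lapply(seq_along(op$full), function(j) segment_dcf(geom, op$full[j]))
  x <- operator_adjoint(op, kspace_full_echoes(kspace, op), dcf = dcf)
  # normalize the residual shading of the approximate density weights and the
  # coil-map RSS so homogeneous tissue reconstructs homogeneously
  rss2 <- apply(abs(op$field$coils)^2, c(1, 2), sum)
  for (j in seq_len(op$n_echoes)) {
    fn <- segment_flat_norm(geom, op$full[j]) * pmax(rss2, 1e-6)
    for (s in seq_len(op$rank)) x[, , s, j] <- x[, , s, j] / fn
  }
  structure(x, class = "echo_image_set", te_ms = op$te_ms)
}

#' Configuration for the regularized iterative reconstruction
#' @param lambda_llr Locally-low-rank weight (>= 0).
#' @param lambda_tv Spatial total-variation weight (>= 0).
#' @param patch Patch edge length for the low-rank penalty (default 8).
#' @param iterations Outer iterations (default 30).
#' @param tol Relative tolerance on objective increase before erroring.
#' @export
lowrank_config <- function(lambda_llr = 0.02, lambda_tv = 0.01, patch = 8,
                           iterations = 30, tol = 1e-6) {
  if (lambda_llr < 0 || lambda_tv < 0) stop("weights must be >= 0", call. = FALSE)
  list(lambda_llr = lambda_llr, lambda_tv = lambda_tv, patch = patch,
       iterations = iterations, tol = tol)
}

#' Iterative locally-low-rank + total-variation reconstruction
#'
#' Minimizes \eqn{\|Ax-y\|^2 + \lambda_{llr}\sum_p \|P_p x\|_* +
#' \lambda_{tv} TV(x)} by proximal gradient steps with backtracking (pure
#' conjugate gradient when both weights are zero). The objective is evaluated
#' every outer iteration and must be non-increasing.
#'
#' @inheritParams recon_direct
#' @param cfg A [lowrank_config()].
#' @param verbose Print objective values.
#' @return `echo_image_set` with attribute `objective` (per-iteration values).
#' @export
recon_lowrank <- function(kspace, geom, field = NULL, basis,
                          cfg = lowrank_config(), b0_correction = TRUE,
                          verbose = FALSE) {
  op <- cmrf_operator(geom, field, basis, b0_correction)
  y <- kspace_full_echoes(kspace, op)
  # scale data so the objective is O(1)
  sc <- sqrt(ksp_norm2(y))
  y <- lapply(y, function(m) m / sc)
  b <- operator_adjoint(op, y)
  if (cfg$lambda_llr == 0 && cfg$lambda_tv == 0) {
    x <- cg_solve(op, b, n_iter = cfg$iterations, verbose = verbose)
    obj <- attr(x, "objective")
  } else {
    L <- power_lipschitz(op, dim(b))
    tau <- 1 / L
    x <- b * 0
    obj <- numeric(0)
    f_prev <- objective_value(op, x, y, cfg)
    for (it in seq_len(cfg$iterations)) {
      g <- operator_adjoint(op, operator_forward(op, x))
      grad <- 2 * (g - b)
      tau_it <- tau
      accepted <- FALSE
      for (bt in seq_len(8)) {
        xn <- x - tau_it * grad
        if (cfg$lambda_llr > 0)
          xn <- prox_llr(xn, cfg$lambda_llr * tau_it, cfg$patch)
        if (cfg$lambda_tv > 0)
          xn <- prox_tv(xn, cfg$lambda_tv * tau_it)
        f <- objective_value(op, xn, y, cfg)
        if (!is.finite(f))
          stop(sprintf("objective diverged at iteration %d", it), call. = FALSE)
        if (f <= f_prev * (1 + cfg$tol)) { accepted <- TRUE; break }
        tau_it <- tau_it / 2
      }
      if (accepted) {
        x <- xn
        f_prev <- min(f_prev, f)
        tau <- tau_it
      }
      obj <- c(obj, f_prev)
      if (verbose) message(sprintf("iter %d objective %.6g", it, f_prev))
    }
  }
  x <- x * sc
  structure(x, class = "echo_image_set", te_ms = op$te_ms, objective = obj)
}

objective_value <- function(op, x, y, cfg) {
  r <- ksp_lincomb(operator_forward(op, x), y, 1, -1)
  f <- ksp_norm2(r)
  if (cfg$lambda_llr > 0) f <- f + cfg$lambda_llr * llr_nuclear(x, cfg$patch)
  if (cfg$lambda_tv > 0) f <- f + cfg$lambda_tv * tv_value(x)
  f
}

cg_solve <- function(op, b, n_iter = 20, verbose = FALSE) {
  x <- b * 0
  r <- b
  p <- r
  rs <- sum(abs(r)^2)
  obj <- numeric(0)
  for (it in seq_len(n_iter)) {
    Ap <- operator_adjoint(op, operator_forward(op, p))
    alpha <- rs / max(Re(sum(Conj(p) * Ap)), .Machine$double.eps)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(abs(r)^2)
    obj <- c(obj, rs_new)
    if (verbose) message(sprintf("cg iter %d residual %.3g", it, rs_new))
    if (rs_new < 1e-14) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  attr(x, "objective") <- obj
  x
}

power_lipschitz <- function(op, dims, n_iter = 8) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(7)
  x <- array(stats::rnorm(prod(dims)), dims) + 1i * array(stats::rnorm(prod(dims)), dims)
  for (i in seq_len(n_iter)) {
    x <- operator_adjoint(op, operator_forward(op, x))
    nx <- sqrt(sum(abs(x)^2))
    x <- x / nx
  }
  2 * nx
}

# nuclear-norm penalty value and proximal map over non-overlapping patches,
# each patch reshaped to (patch^2) x (rank*echoes)
patch_index <- function(n, patch) {
  nb <- n / patch
  idx <- vector("list", nb * nb)
  k <- 0
  for (bx in seq_len(nb)) for (by in seq_len(nb)) {
    k <- k + 1
    rows <- (by - 1) * patch + seq_len(patch)
    cols <- (bx - 1) * patch + seq_len(patch)
    idx[[k]] <- as.vector(outer(rows, (cols - 1) * n, "+"))
  }
  idx
}

llr_nuclear <- function(x, patch) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- patch_index(d[1], patch)
  s <- 0
  for (ii in idx) s <- s + sum(svd(X[ii, , drop = FALSE], nu = 0, nv = 0)$d)
  s
}

prox_llr <- function(x, thr, patch) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- patch_index(d[1], patch)
  for (ii in idx) {
    sv <- svd(X[ii, , drop = FALSE])
    dshr <- pmax(sv$d - thr, 0)
    X[ii, ] <- sv$u %*% (dshr * Conj(t(sv$v)))
  }
  array(X, d)
}

tv_value <- function(x) {
  d <- dim(x)
  s <- 0
  for (e in seq_len(d[4])) for (sb in seq_len(d[3])) {
    img <- x[, , sb, e]
    s <- s + sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
  }
  s
}

# anisotropic TV proximal map by a few dual (Chambolle-style) iterations,
# applied to real and imaginary parts channel-wise
prox_tv <- function(x, thr, n_iter = 8) {
  if (thr <= 0) return(x)
  d <- dim(x)
  for (e in seq_len(d[4])) for (sb in seq_len(d[3])) {
    img <- x[, , sb, e]
    x[, , sb, e] <- tv_prox_real(Re(img), thr, n_iter) +
      1i * tv_prox_real(Im(img), thr, n_iter)
  }
  x
}

tv_prox_real <- function(f, lambda, n_iter) {
  # dual projection algorithm: ascend p along the gradient of
  # div p - f/lambda, clip to the unit box (anisotropic TV), return
  # u = f - lambda div p
  n1 <- nrow(f); n2 <- ncol(f)
  px <- matrix(0, n1, n2); py <- matrix(0, n1, n2)
  tau <- 0.245
  divp <- matrix(0, n1, n2)
  for (i in seq_len(n_iter)) {
    G <- divp - f / lambda
    gx <- rbind(G[-1, , drop = FALSE] - G[-n1, , drop = FALSE], rep(0, n2))
    gy <- cbind(G[, -1, drop = FALSE] - G[, -n2, drop = FALSE], rep(0, n1))
    px <- pmin(pmax(px + tau * gx, -1), 1)
    py <- pmin(pmax(py + tau * gy, -1), 1)
    divx <- px - rbind(matrix(0, 1, n2), px[-n1, , drop = FALSE])
    divy <- py - cbind(matrix(0, n1, 1), py[, -n2, drop = FALSE])
    divp <- divx + divy
  }
  f - lambda * divp
}

#' Configuration for the deep-image-prior reconstruction
#'
#' @param iterations Optimization iterations (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param conv_channels Convolution width (128 in the full-scale protocol).
#' @param input_channels Channels of the fixed noise input (default 32).
#' @param levels Encoder/decoder depth (default 5).
#' @param dropout_rate Dropout probability during optimization (default 0.07).
#' @param seed RNG seed controlling noise input, initialization and dropout.
#' @param b0_correction Include the static off-resonance phase in the forward
#'   model.
#' @param dcf_weight Weight the data-consistency residual by the density
#'   compensation function (default TRUE). This preconditions the normal
#'   operator toward the identity so the fixed iteration budget is spent on
#'   image content rather than on inverting the sampling density; plain
#'   unweighted least squares is available with FALSE.
#' @param average_last The returned images average the outputs of this many
#'   final iterations together with the dropout-free inference pass (default
#'   10), suppressing optimizer-path fluctuation.
#' @param warmup_iterations Image-domain initialization steps: before the
#'   data-consistency iterations the generator is regressed onto the
#'   density-compensated adjoint images (no operator evaluations), which
#'   brings the fixed-budget optimization into the basin of the data-
#'   consistent solution. Set 0 for a cold start from noise.
#' @param warmup_rate Adam step size of the initialization phase.
#' @export
dip_config <- function(iterations = 100, learning_rate = 3e-3,
                       conv_channels = 128, input_channels = 32, levels = 5,
                       dropout_rate = 0.07, seed = 1, b0_correction = TRUE,
                       dcf_weight = TRUE, average_last = 10,
                       warmup_iterations = 150, warmup_rate = 1e-2) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  list(iterations = iterations, learning_rate = learning_rate,
       conv_channels = conv_channels, input_channels = input_channels,
       levels = levels, dropout_rate = dropout_rate, seed = seed,
       b0_correction = b0_correction, dcf_weight = dcf_weight,
       average_last = average_last,
       warmup_iterations = warmup_iterations, warmup_rate = warmup_rate)
}

#' Deep-image-prior reconstruction
#'
#' Optimizes an untrained convolutional generator so that the subspace-echo
#' images it outputs are consistent with the acquired k-space through the
#' encoding model (data-consistency mean-squared-error loss). The network maps
#' a fixed noise tensor to `2 * rank * echoes` real channels interpreted as
#' complex images (channel order: real/imaginary pairs, subspace-major,
#' echo-minor). Dropout is active during optimization and disabled for the
#' final inference pass.
#'
#' @inheritParams recon_direct
#' @param cfg A [dip_config()].
#' @param verbose Print loss every 10 iterations.
#' @param trace_reference Optional complex reference image; when supplied the
#'   result carries an `rmse` attribute with the per-iteration root-mean-
#'   square error of the first subspace-echo image against it (used to study
#'   how the off-resonance-corrected forward model accelerates convergence).
#' @return `echo_image_set` with attribute `loss` (per-iteration data
#'   consistency).
#' @export
recon_dip <- function(kspace, geom, field = NULL, basis, cfg = dip_config(),
                      verbose = FALSE, trace_reference = NULL) {
  op <- cmrf_operator(geom, field, basis, cfg$b0_correction)
  y <- kspace_full_echoes(kspace, op)
  n <- geom$matrix
  rank <- op$rank; n_e <- op$n_echoes
  # scale the data so the network's target images are O(1): estimate the
  # solution amplitude from one adjoint/forward pair and renormalize
  ynorm <- sqrt(ksp_norm2(y))
  y <- lapply(y, function(m) m / ynorm)
  wts <- if (isTRUE(cfg$dcf_weight)) {
    lapply(seq_along(op$full), function(j) {
      w <- segment_dcf(geom, op$full[j])
      w / mean(w)
    })
  } else NULL
  # scale the data so the (preconditioned) least-squares solution is O(1):
  # with DCF weighting A^H W A is close to a multiple of the identity, so
  # x* ~ A^H W y / c with c estimated by one operator round trip
  b <- operator_adjoint(op, y, dcf = wts)
  xhat <- b / max(abs(b))
  cc <- Re(sum(Conj(xhat) * operator_adjoint(op, operator_forward(op, xhat),
                                             dcf = wts))) / sum(abs(xhat)^2)
  xstar <- b / cc
  alpha <- 0.7 / max(abs(xstar))
  y <- lapply(y, function(m) m * alpha)
  ynorm <- ynorm / alpha
  target <- xstar * alpha
  ucfg <- unet_config(n, out_ch = 2 * rank * n_e, in_ch = cfg$input_channels,
                      width = cfg$conv_channels, levels = cfg$levels,
                      dropout = cfg$dropout_rate)
  geo <- unet_geometry(ucfg)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  z <- matrix(stats::rnorm(ucfg$in_ch * n * n, sd = 0.1), ucfg$in_ch, n * n)
  p <- unet_init(ucfg)
  m <- adam_init(p); v <- adam_init(p)
  dtar <- images_to_out(target, n, rank, n_e)
  for (it in seq_len(cfg$warmup_iterations)) {
    fw <- unet_forward(p, z, ucfg, geo, train = TRUE)
    dout <- 2 * (fw$out - dtar) / length(dtar)
    g <- unet_backward(p, ucfg, geo, fw$cache, dout)
    g <- clip_gradients(g, 10)
    st <- adam_step(p, g, m, v, cfg$warmup_rate, it)
    p <- st$p; m <- st$m; v <- st$v
  }
  m <- adam_init(p); v <- adam_init(p)
  loss <- numeric(cfg$iterations)
  rmse <- if (is.null(trace_reference)) NULL else numeric(cfg$iterations)
  avg_from <- max(1, cfg$iterations - cfg$average_last + 1)
  x_avg <- 0
  n_avg <- 0
  for (it in seq_len(cfg$iterations)) {
    fw <- unet_forward(p, z, ucfg, geo, train = TRUE)
    x <- out_to_images(fw$out, n, rank, n_e)
    if (it >= avg_from) {
      x_avg <- x_avg + x
      n_avg <- n_avg + 1
    }
    r <- ksp_lincomb(operator_forward(op, x), y, 1, -1)
    loss[it] <- if (is.null(wts)) ksp_norm2(r) else ksp_wnorm2(r, wts)
    if (!is.finite(loss[it]))
      stop("deep-image-prior loss diverged (non-finite)", call. = FALSE)
    gx <- 2 * operator_adjoint(op, r, dcf = wts)
    dout <- images_to_out(gx, n, rank, n_e)
    g <- unet_backward(p, ucfg, geo, fw$cache, dout)
    g <- clip_gradients(g, 10)
    st <- adam_step(p, g, m, v, cfg$learning_rate, it)
    p <- st$p; m <- st$m; v <- st$v
    if (!is.null(trace_reference)) {
      fe <- unet_forward(p, z, ucfg, geo, train = FALSE)
      xe <- out_to_images(fe$out, n, rank, n_e)[, , 1, 1] * ynorm
      al <- sum(Conj(trace_reference) * xe) /
        max(sum(abs(trace_reference)^2), .Machine$double.eps)
      rmse[it] <- sqrt(mean(abs(xe - al * trace_reference)^2))
    }
    if (verbose && (it %% 10 == 0 || it == 1))
      message(sprintf("dip iter %d loss %.5g", it, loss[it]))
  }
  # final estimate: inference pass without dropout, averaged with the tail
  # iterations' outputs (an ensemble over the dropout/optimizer path that
  # suppresses iteration-to-iteration fluctuation)
  fw <- unet_forward(p, z, ucfg, geo, train = FALSE)
  x_fin <- out_to_images(fw$out, n, rank, n_e)
  x <- (x_fin + x_avg) / (n_avg + 1) * ynorm
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(x, class = "echo_image_set", te_ms = op$te_ms, loss = loss,
            rmse = rmse)
}

# global-norm gradient clipping over the nested gradient list
clip_gradients <- function(g, max_norm) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else total <<- total + sum(x^2)
    invisible(NULL)
  }
  walk(g)
  total <- sqrt(total)
  if (!is.finite(total) || total <= max_norm) return(g)
  fac <- max_norm / total
  scale <- function(x) if (is.list(x)) lapply(x, scale) else x * fac
  scale(g)
}

# channel packing: channel index 2*((s-1)*n_e + e) - 1 (real), ... (imag)
out_to_images <- function(out, n, rank, n_e) {
  x <- array(0 + 0i, c(n, n, rank, n_e))
  for (s in seq_len(rank)) for (e in seq_len(n_e)) {
    k <- 2 * ((s - 1) * n_e + e) - 1
    x[, , s, e] <- matrix(out[k, ], n, n) + 1i * matrix(out[k + 1, ], n, n)
  }
  x
}

images_to_out <- function(x, n, rank, n_e) {
  out <- matrix(0, 2 * rank * dim(x)[4], n * n)
  for (s in seq_len(rank)) for (e in seq_len(n_e)) {
    k <- 2 * ((s - 1) * n_e + e) - 1
    out[k, ] <- as.vector(Re(x[, , s, e]))
    out[k + 1, ] <- as.vector(Im(x[, , s, e]))
  }
  out
}
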