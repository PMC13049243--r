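# A small convolutional encoder-decoder with skip connections, attention
# gating and dropout, written with explicit forward/backward passes on
# channels-x-pixels matrices so the per-scan deep-image-prior optimization
# runs without any deep-learning runtime. Architecture: `levels` encoding
# stages of paired 3x3 convolutions followed by 2x average-pool downsampling;
# decoding stages of 2x nearest upsampling, skip concatenation, an attention
# gate (ReLU -> channel-wise scaling -> sigmoid, applied multiplicatively),
# a single 3x3 convolution and a channel-wise scaling; a final 1x1 projection
# to the output channels.

unet_config <- function(matrix, out_ch, in_ch = 32, width = 128, levels = 5,
                        dropout = 0.07, lrelu = 0.1) {
  if (matrix %% 2^levels != 0)
    stop("matrix must be divisible by 2^levels", call. = FALSE)
  list(matrix = matrix, out_ch = out_ch, in_ch = in_ch, width = width,
       levels = levels, dropout = dropout, lrelu = lrelu)
}

# ---- index helpers per resolution ----------------------------------------
shift_indices <- function(h, w) {
  # 9 offset index vectors; offset order k = 1..9 over (dy, dx) in -1..1,
  # with opp[k] giving the opposite offset's position
  ks <- expand.grid(dy = -1:1, dx = -1:1)
  P <- h * w
  ys <- rep(seq_len(h), times = w)
  xs <- rep(seq_len(w), each = h)
  idx <- lapply(seq_len(9), function(k) {
    sy <- ys + ks$dy[k]; sx <- xs + ks$dx[k]
    ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
    out <- integer(P)
    out[ok] <- (sx[ok] - 1) * h + sy[ok]
    out
  })
  opp <- vapply(seq_len(9), function(k)
    which(ks$dy == -ks$dy[k] & ks$dx == -ks$dx[k]), integer(1))
  list(idx = idx, opp = opp)
}

pool_indices <- function(h, w) {
  # children[[k]] (k=1..4): input pixel index of each output pixel's k-th child
  ho <- h / 2; wo <- w / 2
  yo <- rep(seq_len(ho), times = wo)
  xo <- rep(seq_len(wo), each = ho)
  ch <- list()
  k <- 0
  for (dx in 0:1) for (dy in 0:1) {
    k <- k + 1
    ch[[k]] <- (2 * xo - 1 + dx - 1) * h + (2 * yo - 1 + dy)
  }
  ch
}

shift_cols <- function(x, idx) {
  y <- x[, pmax(idx, 1), drop = FALSE]
  if (any(idx == 0)) y[, idx == 0] <- 0
  y
}

# ---- layers ---------------------------------------------------------------
conv3_fwd <- function(x, W, b, sh) {
  y <- matrix(b, length(b), ncol(x))
  for (k in 1:9) y <- y + W[[k]] %*% shift_cols(x, sh$idx[[k]])
  list(y = y, X9 = x)
}
conv3_bwd <- function(dy, x, W, sh) {
  dW <- vector("list", 9)
  dx <- matrix(0, ncol(W[[1]]), ncol(dy))
  for (k in 1:9) {
    dW[[k]] <- dy %*% t(shift_cols(x, sh$idx[[k]]))
    dx <- dx + crossprod(W[[k]], shift_cols(dy, sh$idx[[sh$opp[k]]]))
  }
  list(dW = dW, db = rowSums(dy), dx = dx)
}

# per-channel instance normalization (zero mean, unit variance over pixels);
# stabilizes the multiplicative depth of the generator so large step sizes
# remain usable
norm_fwd <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sg <- sqrt(rowMeans(xc^2) + 1e-6)
  yh <- xc / sg
  list(y = yh, yh = yh, sg = sg)
}
norm_bwd <- function(dy, yh, sg) {
  (dy - rowMeans(dy) - yh * rowMeans(dy * yh)) / sg
}

lrelu_fwd <- function(x, a) {
  m <- x > 0
  list(y = pmax(x, 0) + a * pmin(x, 0), m = m)
}
lrelu_bwd <- function(dy, m, a) dy * (a + (1 - a) * m)

drop_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, m = NULL))
  m <- matrix(stats::runif(length(x)) >= p, nrow(x)) / (1 - p)
  list(y = x * m, m = m)
}
drop_bwd <- function(dy, m) if (is.null(m)) dy else dy * m

pool_fwd <- function(x, ch) {
  (x[, ch[[1]], drop = FALSE] + x[, ch[[2]], drop = FALSE] +
     x[, ch[[3]], drop = FALSE] + x[, ch[[4]], drop = FALSE]) / 4
}
pool_bwd <- function(dy, ch, P_in) {
  dx <- matrix(0, nrow(dy), P_in)
  for (k in 1:4) dx[, ch[[k]]] <- dy / 4
  dx
}

up_fwd <- function(x, ch, P_out) {
  # nearest-neighbour 2x upsampling: inverse map of pool children
  y <- matrix(0, nrow(x), P_out)
  for (k in 1:4) y[, ch[[k]]] <- x
  y
}
up_bwd <- function(dy, ch) {
  dy[, ch[[1]], drop = FALSE] + dy[, ch[[2]], drop = FALSE] +
    dy[, ch[[3]], drop = FALSE] + dy[, ch[[4]], drop = FALSE]
}

att_fwd <- function(u, gamma) {
  r <- pmax(u, 0)
  s <- gamma * r              # gamma recycles down rows? need per-channel rows
  g <- 1 / (1 + exp(-s))
  list(y = u * g, r = r, g = g)
}
att_bwd <- function(dy, u, gamma, r, g) {
  dg <- dy * u
  ds <- dg * g * (1 - g)
  dgamma <- rowSums(ds * r)
  du <- dy * g + gamma * ds * (u > 0)
  list(du = du, dgamma = dgamma)
}

# ---- parameter initialization --------------------------------------------
he_conv <- function(cin, cout) {
  lapply(1:9, function(k) matrix(stats::rnorm(cout * cin, sd = sqrt(2 / (9 * cin))),
                                 cout, cin))
}

unet_init <- function(cfg) {
  W <- cfg$width
  p <- list(enc = vector("list", cfg$levels),
            dec = vector("list", cfg$levels))
  cin <- cfg$in_ch
  for (l in seq_len(cfg$levels)) {
    p$enc[[l]] <- list(W1 = he_conv(cin, W), b1 = numeric(W),
                       W2 = he_conv(W, W), b2 = numeric(W))
    cin <- W
  }
  for (l in seq_len(cfg$levels)) {
    p$dec[[l]] <- list(gamma_att = rep(1, 2 * W),
                       Wc = he_conv(2 * W, W), bc = numeric(W),
                       gamma_sc = rep(1, W))
  }
  # final projection starts at zero so optimization begins from the zero
  # image and builds structure driven purely by the data-consistency gradient
  p$out <- list(W = matrix(0, cfg$out_ch, W), b = numeric(cfg$out_ch))
  p
}

unet_geometry <- function(cfg) {
  n <- cfg$matrix
  sh <- list(); po <- list()
  for (l in seq_len(cfg$levels + 1)) {
    r <- n / 2^(l - 1)
    sh[[l]] <- shift_indices(r, r)
    if (l <= cfg$levels) po[[l]] <- pool_indices(r, r)
  }
  list(sh = sh, po = po)
}

# forward pass; returns output (out_ch x n^2) and cache for backprop
unet_forward <- function(p, z, cfg, geo, train = TRUE) {
  L <- cfg$levels
  cache <- list(z = z, enc = vector("list", L), dec = vector("list", L))
  x <- z
  for (l in seq_len(L)) {
    e <- list()
    e$x_in <- x
    c1f <- conv3_fwd(x, p$enc[[l]]$W1, p$enc[[l]]$b1, geo$sh[[l]])
    e$x9_1 <- c1f$X9
    n1 <- norm_fwd(c1f$y); e$n1 <- n1
    r1 <- lrelu_fwd(n1$y, cfg$lrelu); e$m1 <- r1$m
    d1 <- drop_fwd(r1$y, cfg$dropout, train); e$dm1 <- d1$m
    c2f <- conv3_fwd(d1$y, p$enc[[l]]$W2, p$enc[[l]]$b2, geo$sh[[l]])
    e$x9_2 <- c2f$X9
    n2 <- norm_fwd(c2f$y); e$n2 <- n2
    r2 <- lrelu_fwd(n2$y, cfg$lrelu); e$m2 <- r2$m
    d2 <- drop_fwd(r2$y, cfg$dropout, train); e$dm2 <- d2$m
    e$skip <- d2$y
    x <- pool_fwd(d2$y, geo$po[[l]])
    cache$enc[[l]] <- e
  }
  for (l in rev(seq_len(L))) {
    d <- list()
    d$x_in <- x
    P_out <- ncol(cache$enc[[l]]$skip)
    u <- up_fwd(x, geo$po[[l]], P_out)
    d$cat <- rbind(u, cache$enc[[l]]$skip)
    at <- att_fwd(d$cat, p$dec[[l]]$gamma_att)
    d$att_r <- at$r; d$att_g <- at$g
    cf <- conv3_fwd(at$y, p$dec[[l]]$Wc, p$dec[[l]]$bc, geo$sh[[l]])
    d$x9c <- cf$X9
    nc <- norm_fwd(cf$y); d$nc <- nc
    x <- p$dec[[l]]$gamma_sc * nc$y
    cache$dec[[l]] <- d
  }
  out <- p$out$W %*% x + p$out$b
  cache$pre_out <- x
  list(out = out, cache = cache)
}

unet_backward <- function(p, cfg, geo, cache, dout) {
  L <- cfg$levels
  g <- list(enc = vector("list", L), dec = vector("list", L))
  g$out <- list(W = dout %*% t(cache$pre_out), b = rowSums(dout))
  dx <- crossprod(p$out$W, dout)
  for (l in seq_len(L)) {
    d <- cache$dec[[l]]
    dnc <- p$dec[[l]]$gamma_sc * dx
    dgamma_sc <- rowSums(dx * d$nc$y)
    dac <- norm_bwd(dnc, d$nc$yh, d$nc$sg)
    cb <- conv3_bwd(dac, d$x9c, p$dec[[l]]$Wc, geo$sh[[l]])
    ab <- att_bwd(cb$dx, d$cat, p$dec[[l]]$gamma_att, d$att_r, d$att_g)
    W2 <- cfg$width
    du <- ab$du[seq_len(W2), , drop = FALSE]
    dskip <- ab$du[W2 + seq_len(W2), , drop = FALSE]
    g$dec[[l]] <- list(gamma_att = ab$dgamma, Wc = cb$dW, bc = cb$db,
                       gamma_sc = dgamma_sc)
    g$enc_skip_grad <- NULL
    dx_low <- up_bwd(du, geo$po[[l]])
    # stash skip gradient on the encoder cache for the upward pass
    cache$enc[[l]]$dskip <- dskip
    dx <- dx_low
  }
  # dx now flows back into the deepest pooled encoder output
  for (l in rev(seq_len(L))) {
    e <- cache$enc[[l]]
    dpool <- pool_bwd(dx, geo$po[[l]], ncol(e$skip))
    dskip_tot <- dpool + e$dskip
    d2 <- drop_bwd(dskip_tot, e$dm2)
    dn2 <- lrelu_bwd(d2, e$m2, cfg$lrelu)
    da2 <- norm_bwd(dn2, e$n2$yh, e$n2$sg)
    c2 <- conv3_bwd(da2, e$x9_2, p$enc[[l]]$W2, geo$sh[[l]])
    d1 <- drop_bwd(c2$dx, e$dm1)
    dn1 <- lrelu_bwd(d1, e$m1, cfg$lrelu)
    da1 <- norm_bwd(dn1, e$n1$yh, e$n1$sg)
    c1 <- conv3_bwd(da1, e$x9_1, p$enc[[l]]$W1, geo$sh[[l]])
    g$enc[[l]] <- list(W1 = c1$dW, b1 = c1$db, W2 = c2$dW, b2 = c2$db)
    dx <- c1$dx
  }
  g
}

# ---- Adam on the nested parameter list ------------------------------------
adam_init <- function(p) rapply(p, function(a) a * 0, how = "replace")

adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  walk(p, g, m, v)
}
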