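# Low-level differentiable tensor kernels.
#
# Feature maps are numeric arrays with dim c(H, W, C, N): rows, columns,
# channels, batch. All kernels come in fwd/bwd pairs; backward passes are
# exact reverse-mode gradients used by the network assembly in model.R.

# ---- layout helpers ----------------------------------------------------

# (H,W,C,N) -> matrix (H*W*N, C); row order is h fastest, then w, then n.
t4_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

# inverse of t4_mat
mat_t4 <- function(m, H, W, N, C) {
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1L, 2L, 4L, 3L))
}

pad_zero <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  out
}

# multiply each channel c (and batch n) of x by v[c, n] or v[c]
scale_channels <- function(x, v) {
  d <- dim(x)
  x * rep(as.vector(v), each = d[1L] * d[2L], length.out = length(x))
}

# ---- activations -------------------------------------------------------

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
relu_bwd <- function(x, dy) dy * (x > 0)

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(y, dy) dy * y * (1 - y)   # y = sigmoid(x)

tanh_bwd <- function(y, dy) dy * (1 - y * y)      # y = tanh(x)

# ---- convolution (stride 1, square kernel, zero 'same' padding) --------

conv2d_fwd <- function(x, w, b) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; Cin <- d[3L]; N <- d[4L]
  k <- dim(w)[1L]
  stopifnot(dim(w)[2L] == k, dim(w)[3L] == Cin)
  Cout <- dim(w)[4L]
  p <- (k - 1L) %/% 2L
  xp <- pad_zero(x, p)
  ymat <- matrix(b, H * W * N, Cout, byrow = TRUE)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      xs <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE]
      ymat <- ymat + t4_mat(xs) %*% matrix(w[di, dj, , ], Cin, Cout)
    }
  }
  mat_t4(ymat, H, W, N, Cout)
}

conv2d_bwd <- function(x, w, dy) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; Cin <- d[3L]; N <- d[4L]
  k <- dim(w)[1L]
  Cout <- dim(w)[4L]
  p <- (k - 1L) %/% 2L
  xp <- pad_zero(x, p)
  dymat <- t4_mat(dy)
  db <- colSums(dymat)
  dw <- array(0, dim(w))
  dxp <- array(0, dim(xp))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      ri <- di:(di + H - 1L); rj <- dj:(dj + W - 1L)
      xs <- xp[ri, rj, , , drop = FALSE]
      dw[di, dj, , ] <- crossprod(t4_mat(xs), dymat)
      dxs <- dymat %*% t(matrix(w[di, dj, , ], Cin, Cout))
      dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] +
        mat_t4(dxs, H, W, N, Cin)
    }
  }
  dx <- if (p == 0L) dxp else
    dxp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# ---- batch normalization (per channel over H, W, N) --------------------

bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  m <- t4_mat(x)
  d <- dim(x)
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, ivar, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = mat_t4(y, d[1L], d[2L], d[4L], d[3L]),
       cache = list(xhat = xhat, ivar = ivar, dims = d, train = train),
       state = state)
}

bn_bwd <- function(cache, gamma, dy) {
  d <- cache$dims
  dym <- t4_mat(dy)
  xhat <- cache$xhat
  M <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dxm <- sweep(dxhat, 2L, s1 / M, "-") - sweep(xhat, 2L, s2 / M, "*")
    dxm <- sweep(dxm, 2L, cache$ivar, "*")
  } else {
    dxm <- sweep(dxhat, 2L, cache$ivar, "*")
  }
  list(dx = mat_t4(dxm, d[1L], d[2L], d[4L], d[3L]),
       dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling -----------------------------------------------------------

# 2x2 average pooling, H and W assumed even
avgpool2_fwd <- function(x) {
  d <- dim(x)
  (x[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), , , drop = FALSE] +
   x[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), , , drop = FALSE] +
   x[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), , , drop = FALSE] +
   x[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), , , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, dims) {
  dx <- array(0, dims)
  g <- dy / 4
  dx[seq(1L, dims[1L], 2L), seq(1L, dims[2L], 2L), , ] <- g
  dx[seq(2L, dims[1L], 2L), seq(1L, dims[2L], 2L), , ] <- g
  dx[seq(1L, dims[1L], 2L), seq(2L, dims[2L], 2L), , ] <- g
  dx[seq(2L, dims[1L], 2L), seq(2L, dims[2L], 2L), , ] <- g
  dx
}

# global average pool: (H,W,C,N) -> (C,N)
gap_fwd <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])), d[3L], d[4L])
}

gap_bwd <- function(dy, dims) {
  hw <- dims[1L] * dims[2L]
  array(rep(as.vector(dy), each = hw) / hw, dims)
}

# ---- fully connected: x (C,N) -> (K,N) ---------------------------------

fc_fwd <- function(x, w, b) w %*% x + b

fc_bwd <- function(x, w, dy) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

# ---- normalized base grid and bilinear sampling ------------------------

# Eq-style base lattice: -1 + 2j/(n-1), exactly hitting the endpoints.
base_axis <- function(n) {
  if (n < 2L) stop("grid axis needs at least 2 points", call. = FALSE)
  seq(-1, 1, length.out = n)
}

#' @keywords internal
grid_sample_fwd <- function(f, grid) {
  df <- dim(f); H <- df[1L]; W <- df[2L]; C <- df[3L]; N <- df[4L]
  dg <- dim(grid); Ho <- dg[1L]; Wo <- dg[2L]
  stopifnot(dg[3L] == 2L, dg[4L] == N)
  gx <- as.vector(grid[, , 1L, , drop = FALSE])
  gy <- as.vector(grid[, , 2L, , drop = FALSE])
  if (any(gx < -1 - 1e-9 | gx > 1 + 1e-9 | gy < -1 - 1e-9 | gy > 1 + 1e-9))
    stop("sampling grid coordinates must lie in [-1, 1]", call. = FALSE)
  px <- (gx + 1) / 2 * (W - 1)
  py <- (gy + 1) / 2 * (H - 1)
  x0 <- floor(px); y0 <- floor(py)
  u <- px - x0; v <- py - y0
  clampx <- function(z) pmin.int(pmax.int(z, 0), W - 1L)
  clampy <- function(z) pmin.int(pmax.int(z, 0), H - 1L)
  x0c <- clampx(x0); x1c <- clampx(x0 + 1)
  y0c <- clampy(y0); y1c <- clampy(y0 + 1)
  P <- length(px)
  nrep <- rep(seq_len(N) - 1L, each = Ho * Wo)
  base <- nrep * (H * W * C)
  choff <- (seq_len(C) - 1L) * (H * W)
  lin <- function(yc, xc) outer(base + yc + xc * H + 1, choff, "+")
  i00 <- lin(y0c, x0c); i10 <- lin(y0c, x1c)
  i01 <- lin(y1c, x0c); i11 <- lin(y1c, x1c)
  f00 <- matrix(f[i00], P, C); f10 <- matrix(f[i10], P, C)
  f01 <- matrix(f[i01], P, C); f11 <- matrix(f[i11], P, C)
  w00 <- (1 - u) * (1 - v); w10 <- u * (1 - v)
  w01 <- (1 - u) * v;       w11 <- u * v
  ymat <- f00 * w00 + f10 * w10 + f01 * w01 + f11 * w11
  list(y = mat_t4(ymat, Ho, Wo, N, C),
       cache = list(i00 = i00, i10 = i10, i01 = i01, i11 = i11,
                    f00 = f00, f10 = f10, f01 = f01, f11 = f11,
                    u = u, v = v, dimf = df, dimg = dg))
}

#' @keywords internal
grid_sample_bwd <- function(cache, dy) {
  df <- cache$dimf; dg <- cache$dimg
  H <- df[1L]; W <- df[2L]; C <- df[3L]; N <- df[4L]
  dym <- t4_mat(dy)
  u <- cache$u; v <- cache$v
  v00 <- dym * ((1 - u) * (1 - v)); v10 <- dym * (u * (1 - v))
  v01 <- dym * ((1 - u) * v);       v11 <- dym * (u * v)
  idx <- c(cache$i00, cache$i10, cache$i01, cache$i11)
  val <- c(v00, v10, v01, v11)
  s <- rowsum(val, idx)
  dfout <- array(0, df)
  dfout[as.integer(rownames(s))] <- s
  # d/d(px), d/d(py) of the bilinear rule at fixed corner values
  dpdx <- rowSums(dym * ((1 - v) * (cache$f10 - cache$f00) +
                         v * (cache$f11 - cache$f01)))
  dpdy <- rowSums(dym * ((1 - u) * (cache$f01 - cache$f00) +
                         u * (cache$f11 - cache$f10)))
  dgx <- dpdx * (W - 1) / 2
  dgy <- dpdy * (H - 1) / 2
  dgrid <- array(0, dg)
  dgrid[, , 1L, ] <- dgx
  dgrid[, , 2L, ] <- dgy
  list(df = dfout, dgrid = dgrid)
}

# bilinear resize via sampling at the target-size base lattice
resize_bilinear_fwd <- function(f, Ho, Wo) {
  N <- dim(f)[4L]
  if (Ho == dim(f)[1L] && Wo == dim(f)[2L]) {
    return(list(y = f, cache = list(identity = TRUE, dimf = dim(f))))
  }
  g <- array(0, c(Ho, Wo, 2L, N))
  g[, , 1L, ] <- matrix(base_axis(Wo), Ho, Wo, byrow = TRUE)
  g[, , 2L, ] <- matrix(base_axis(Ho), Ho, Wo)
  out <- grid_sample_fwd(f, g)
  out$cache$identity <- FALSE
  out
}

resize_bilinear_bwd <- function(cache, dy) {
  if (isTRUE(cache$identity)) return(dy)
  grid_sample_bwd(cache, dy)$df
}

# convenience: plain resize of a single H x W x C image, returns array
resize_image <- function(img, H, W) {
  x <- array(img, c(dim(img)[1L], dim(img)[2L], dim(img)[3L], 1L))
  y <- resize_bilinear_fwd(x, H, W)$y
  array(y, c(H, W, dim(img)[3L]))
}
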