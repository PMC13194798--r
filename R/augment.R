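# Training-time stochastic transforms, deterministic eval transform,
# channelwise normalization, and MixUp interpolation.
#
# Geometric warps (rotation, perspective) reuse the package's own bilinear
# grid sampler so that every resampling in the package follows the same
# align-corners convention; out-of-frame samples replicate the border.

#' Default augmentation configuration
#'
#' Keys mirror the training recipe of the classifier: random resized crop
#' with area scale 0.85-1.0, horizontal flip p = 0.5, vertical flip p = 0.3,
#' rotation within +/- 5 degrees, mild perspective distortion, additive
#' Gaussian noise with std 0.005 on the [0, 1] scale, multiplicative
#' intensity scaling, small brightness/contrast jitter, random erasing
#' p = 0.1, and MixUp alpha 0.1. Every value can be overridden.
#'
#' @param ... named overrides of the defaults.
#' @return named list of augmentation parameters.
#' @export
aug_config <- function(...) {
  cfg <- list(random_crop_scale = c(0.85, 1.0),
              crop_ratio = c(3 / 4, 4 / 3),
              hflip_p = 0.5,
              vflip_p = 0.3,
              rotation_deg = 5,
              perspective_p = 0.3,
              perspective_distortion = 0.2,
              noise_std = 0.005,
              intensity_range = c(0.9, 1.1),
              jitter_brightness = 0.1,
              jitter_contrast = 0.1,
              erasing_p = 0.1,
              mixup_alpha = 0.1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown augmentation keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

# warp an H x W x C image given a (H, W, 2) source-coordinate grid
warp_image <- function(img, grid) {
  d <- dim(img)
  f <- array(img, c(d[1L], d[2L], d[3L], 1L))
  g <- array(grid, c(dim(grid)[1L], dim(grid)[2L], 2L, 1L))
  g <- pmin(pmax(g, -1), 1)
  array(grid_sample_fwd(f, g)$y, d)
}

# identity target grid in normalized coordinates
target_grid <- function(H, W) {
  g <- array(0, c(H, W, 2L))
  g[, , 1L] <- matrix(base_axis(W), H, W, byrow = TRUE)
  g[, , 2L] <- matrix(base_axis(H), H, W)
  g
}

# homography mapping the unit square corners (+-1) onto `corners` (4 x 2,
# order TL, TR, BR, BL), returned as a 3 x 3 matrix acting on (x, y, 1)
solve_homography <- function(corners) {
  src <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1L]; y <- src[i, 2L]
    u <- corners[i, 1L]; v <- corners[i, 2L]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Stochastic training transform
#'
#' Applies, in order: random resized crop to \code{size} x \code{size},
#' horizontal/vertical flips, rotation, perspective distortion, additive
#' Gaussian noise, multiplicative intensity scaling, brightness/contrast
#' jitter, and random erasing. Random draws consume the global RNG stream,
#' so a fixed \code{set.seed()} yields identical output.
#'
#' @param img H x W x 3 array on [0, 1].
#' @param cfg configuration from [aug_config()].
#' @param size output side length in pixels (default 224).
#' @return \code{size} x \code{size} x 3 array on [0, 1].
#' @export
train_transform <- function(img, cfg = aug_config(), size = 224L) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("img must be an H x W x 3 array", call. = FALSE)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  # random resized crop
  a <- stats::runif(1, cfg$random_crop_scale[1L], cfg$random_crop_scale[2L])
  r <- exp(stats::runif(1, log(cfg$crop_ratio[1L]), log(cfg$crop_ratio[2L])))
  ch <- min(H, max(2L, round(sqrt(a * H * W / r))))
  cw <- min(W, max(2L, round(sqrt(a * H * W * r))))
  top <- sample.int(H - ch + 1L, 1L)
  left <- sample.int(W - cw + 1L, 1L)
  out <- resize_image(img[top:(top + ch - 1L), left:(left + cw - 1L), ,
                          drop = FALSE], size, size)
  # flips
  if (stats::runif(1) < cfg$hflip_p) out <- out[, size:1L, , drop = FALSE]
  if (stats::runif(1) < cfg$vflip_p) out <- out[size:1L, , , drop = FALSE]
  # rotation about the image center
  theta <- stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
  if (theta != 0) {
    tg <- target_grid(size, size)
    gx <- cos(theta) * tg[, , 1L] - sin(theta) * tg[, , 2L]
    gy <- sin(theta) * tg[, , 1L] + cos(theta) * tg[, , 2L]
    out <- warp_image(out, array(c(gx, gy), c(size, size, 2L)))
  }
  # perspective
  if (stats::runif(1) < cfg$perspective_p) {
    d <- cfg$perspective_distortion
    corners <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)) +
      matrix(stats::runif(8, -d, d), 4, 2)
    Hm <- solve_homography(corners)
    tg <- target_grid(size, size)
    xh <- Hm[1, 1] * tg[, , 1L] + Hm[1, 2] * tg[, , 2L] + Hm[1, 3]
    yh <- Hm[2, 1] * tg[, , 1L] + Hm[2, 2] * tg[, , 2L] + Hm[2, 3]
    wh <- Hm[3, 1] * tg[, , 1L] + Hm[3, 2] * tg[, , 2L] + Hm[3, 3]
    out <- warp_image(out, array(c(xh / wh, yh / wh), c(size, size, 2L)))
  }
  # additive Gaussian noise on the [0,1] scale
  if (cfg$noise_std > 0)
    out <- out + array(stats::rnorm(length(out), 0, cfg$noise_std), dim(out))
  # multiplicative intensity scaling
  out <- out * stats::runif(1, cfg$intensity_range[1L], cfg$intensity_range[2L])
  # brightness / contrast jitter
  if (cfg$jitter_brightness > 0)
    out <- out + stats::runif(1, -cfg$jitter_brightness, cfg$jitter_brightness)
  if (cfg$jitter_contrast > 0) {
    cfac <- 1 + stats::runif(1, -cfg$jitter_contrast, cfg$jitter_contrast)
    out <- (out - mean(out)) * cfac + mean(out)
  }
  # random erasing
  if (stats::runif(1) < cfg$erasing_p) {
    eh <- sample.int(max(1L, size %/% 4L), 1L)
    ew <- sample.int(max(1L, size %/% 4L), 1L)
    et <- sample.int(size - eh + 1L, 1L)
    el <- sample.int(size - ew + 1L, 1L)
    out[et:(et + eh - 1L), el:(el + ew - 1L), ] <- stats::runif(1)
  }
  pmin(pmax(out, 0), 1)
}

#' Per-channel standard ImageNet normalization constants
#' @return list with numeric length-3 vectors \code{mean} and \code{sd}.
#' @export
imagenet_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Channelwise standardization
#'
#' @param img H x W x 3 array.
#' @param mu,sigma per-channel mean and standard deviation (length 1 or 3);
#'   sigma must be strictly positive.
#' @return standardized array of the same shape.
#' @export
normalize_image <- function(img, mu = imagenet_stats()$mean,
                            sigma = imagenet_stats()$sd) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive", call. = FALSE)
  mu <- rep(mu, length.out = 3L); sigma <- rep(sigma, length.out = 3L)
  d <- dim(img)
  sweep(sweep(img, 3L, mu, "-"), 3L, sigma, "/")
}

#' Inverse of [normalize_image()]
#' @inheritParams normalize_image
#' @export
denormalize_image <- function(img, mu = imagenet_stats()$mean,
                              sigma = imagenet_stats()$sd) {
  mu <- rep(mu, length.out = 3L); sigma <- rep(sigma, length.out = 3L)
  sweep(sweep(img, 3L, sigma, "*"), 3L, mu, "+")
}

#' Deterministic evaluation transform: resize, then normalize
#' @param img H x W x 3 array on [0, 1].
#' @param size output side length.
#' @param mu,sigma normalization constants, see [normalize_image()].
#' @export
eval_transform <- function(img, size = 224L, mu = imagenet_stats()$mean,
                           sigma = imagenet_stats()$sd) {
  normalize_image(resize_image(img, size, size), mu, sigma)
}

#' MixUp interpolation of a batch
#'
#' Draws one mixing weight lambda ~ Beta(alpha, alpha) for the batch, pairs
#' each item with an item from a random permutation, and returns the convex
#' combinations together with both target vectors, as needed by the MixUp
#' training loss.
#'
#' @param inputs array of dim \code{c(H, W, C, N)} with N >= 2.
#' @param targets integer or factor vector of length N.
#' @param alpha Beta concentration (> 0); the classifier's default is 0.1.
#' @return list of class \code{mixup_batch}: \code{mixed} inputs,
#'   \code{y_i}, \code{y_j}, \code{lambda}, \code{alpha}, \code{perm}.
#' @export
mixup_batch <- function(inputs, targets, alpha = 0.1) {
  N <- dim(inputs)[4L]
  if (is.null(N) || N < 2L) stop("batch size must be >= 2", call. = FALSE)
  if (length(targets) != N) stop("targets length must match batch", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  lambda <- stats::rbeta(1, alpha, alpha)
  perm <- sample.int(N)
  mixed <- lambda * inputs + (1 - lambda) * inputs[, , , perm, drop = FALSE]
  structure(list(mixed = mixed, y_i = targets, y_j = targets[perm],
                 lambda = lambda, alpha = alpha, perm = perm),
            class = "mixup_batch")
}
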