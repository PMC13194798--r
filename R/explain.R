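# Explainability operators: Grad-CAM on the fused attention features, and
# Shapley-value attribution with an exact enumerator for small feature
# counts and a permutation-sampling estimator otherwise.

#' Grad-CAM heatmap for one prediction
#'
#' Channel weights are the spatially averaged gradients of the pre-softmax
#' class score with respect to the fused feature map (the model's final
#' convolutional representation); the weighted channel sum passes ReLU, is
#' bilinearly upsampled to the input size, and min-max normalized to [0, 1].
#'
#' @param fit an \code{msdam_fit}.
#' @param img raw [0, 1] image, H x W x 3.
#' @param class_label target class (name or index); defaults to the
#'   predicted class.
#' @param layer gradient source; only \code{"fused"} is supported.
#' @return object of class \code{gradcam_map}: list with \code{heatmap}
#'   (input-sized, in [0, 1]), \code{target_class}, \code{alpha} (channel
#'   weights), \code{raw} (pre-normalization map).
#' @export
grad_cam <- function(fit, img, class_label = NULL, layer = "fused") {
  if (!identical(layer, "fused"))
    stop("unknown gradient source layer: ", layer, call. = FALSE)
  cfg <- fit$config
  size <- cfg$input_size
  x <- resize_image(img, size, size)
  batch <- normalize_batch(array(x, c(size, size, 3L, 1L)),
                           cfg$norm_mean, cfg$norm_sd)
  model <- fit$model
  fw <- msdam_forward(model, batch, train = FALSE, keep_cache = TRUE)
  K <- model$config$n_classes
  if (is.null(class_label)) {
    c_idx <- which.max(fw$scores[, 1L])
  } else if (is.character(class_label)) {
    c_idx <- match(class_label, fit$class_names)
    if (is.na(c_idx)) stop("unknown class: ", class_label, call. = FALSE)
  } else {
    c_idx <- as.integer(class_label)
  }
  dscores <- matrix(0, K, 1L)
  dscores[c_idx, 1L] <- 1
  bw <- msdam_backward(model, fw$cache, dscores)
  dA <- bw$intermediates$dfused            # (Hr, Wr, C, 1)
  A <- fw$fused
  alpha <- gap_fwd(dA)[, 1L]               # spatially averaged gradients
  cam <- apply_channel_weights(A, alpha)
  cam <- pmax(cam, 0)
  up <- resize_image(array(cam, c(dim(cam), 1L)), size, size)[, , 1L]
  rng <- range(up)
  heat <- if (diff(rng) > 0) (up - rng[1L]) / diff(rng) else up * 0
  structure(list(heatmap = heat, raw = cam,
                 target_class = fit$class_names[c_idx], alpha = alpha,
                 source_layer = layer),
            class = "gradcam_map")
}

apply_channel_weights <- function(A, alpha) {
  d <- dim(A)
  m <- matrix(A[, , , 1L], d[1L] * d[2L], d[3L])
  matrix(m %*% alpha, d[1L], d[2L])
}

#' Render a Grad-CAM overlay to PNG
#' @param map a \code{gradcam_map}.
#' @param img the original [0, 1] image.
#' @param path output PNG path.
#' @param alpha blending weight of the heatmap.
#' @export
gradcam_overlay <- function(map, img, path, alpha = 0.45) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  heat <- resize_image(array(map$heatmap, c(dim(map$heatmap), 1L)), H, W)[, , 1L]
  cols <- grDevices::col2rgb(grDevices::hcl.colors(256, "Inferno")) / 255
  idx <- pmin(255L, pmax(0L, as.integer(round(heat * 255)))) + 1L
  overlay <- array(0, c(H, W, 3L))
  for (c in 1:3) overlay[, , c] <- matrix(cols[c, idx], H, W)
  save_png((1 - alpha) * img + alpha * overlay, path)
  invisible(path)
}

# ---- Shapley values ----------------------------------------------------

#' Exact Shapley values by subset enumeration
#'
#' Computes, for every feature i, the factorially weighted average of
#' marginal contributions \code{f(S + i) - f(S)} over all subsets S of the
#' remaining features. Enumeration is limited to d <= 12 features (4096
#' subsets); use [shapley_sampled()] beyond that.
#'
#' @param value_fn function taking an integer vector of feature indices
#'   (possibly empty) and returning a scalar value.
#' @param d number of features (<= 12).
#' @return object of class \code{shapley_attribution}: \code{phi},
#'   \code{baseline_value} f(empty), \code{full_value} f(all),
#'   \code{method = "exact"}.
#' @export
shapley_exact <- function(value_fn, d) {
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (d > 12L)
    stop("exact enumeration limited to d <= 12; use shapley_sampled()",
         call. = FALSE)
  nsub <- bitwShiftL(1L, d)
  vals <- numeric(nsub)
  for (mask in 0:(nsub - 1L)) {
    vals[mask + 1L] <- value_fn(which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) != 0L))
  }
  sizes <- vapply(0:(nsub - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) != 0L), numeric(1))
  # weight for |S| = s: s! (d - s - 1)! / d!
  wt <- exp(lfactorial(0:(d - 1L)) + lfactorial(d - 1L - (0:(d - 1L))) - lfactorial(d))
  phi <- numeric(d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(nsub - 1L), bit) == 0L) - 1L
    s <- sizes[without + 1L]
    phi[i] <- sum(wt[s + 1L] * (vals[without + bit + 1L] - vals[without + 1L]))
  }
  structure(list(phi = phi, baseline_value = vals[1L],
                 full_value = vals[nsub], method = "exact"),
            class = "shapley_attribution")
}

#' Shapley values by permutation sampling
#'
#' Monte-Carlo estimator: averages each feature's marginal contribution
#' over random orderings. Reports per-feature standard errors.
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed integer seed.
#' @return a \code{shapley_attribution} with \code{method = "sampled"},
#'   \code{se}, \code{n_permutations}, \code{seed}.
#' @export
shapley_sampled <- function(value_fn, d, n_permutations = 200L, seed = 42L) {
  d <- as.integer(d)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  set.seed(seed)
  contrib <- matrix(0, n_permutations, d)
  base <- value_fn(integer(0))
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(d)
    prev <- base
    members <- integer(0)
    for (i in ord) {
      members <- c(members, i)
      cur <- value_fn(members)
      contrib[p, i] <- cur - prev
      prev <- cur
    }
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2L, stats::sd) / sqrt(n_permutations)
  structure(list(phi = phi, baseline_value = base,
                 full_value = value_fn(seq_len(d)), method = "sampled",
                 se = se, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s): %d features, sum(phi) = %.6g, f(F) - f(0) = %.6g\n",
              x$method, length(x$phi), sum(x$phi),
              x$full_value - x$baseline_value))
  print(round(x$phi, 4))
  invisible(x)
}

#' Shapley attribution over pooled feature-channel groups
#'
#' Explains one prediction at the level of the penultimate pooled feature
#' vector: the channels are split into \code{groups} contiguous groups,
#' a masked group is replaced by the supplied baseline vector (typically
#' the dataset mean), and the value function is the pre-softmax score of
#' the target class through the linear head. Exact enumeration is used for
#' up to 12 groups, permutation sampling otherwise.
#'
#' @param fit an \code{msdam_fit}.
#' @param img raw [0, 1] image.
#' @param class_label target class name or index (default: predicted).
#' @param groups number of channel groups (default 8).
#' @param baseline baseline pooled vector (default: all zeros).
#' @param ... passed to [shapley_sampled()] when groups > 12.
#' @return a \code{shapley_attribution}; attribute \code{group_index} maps
#'   channels to groups.
#' @export
shapley_channels <- function(fit, img, class_label = NULL, groups = 8L,
                             baseline = NULL, ...) {
  pooled <- predict(fit, img, type = "pooled")[, 1L]
  scores <- predict(fit, img, type = "score")[, 1L]
  c_idx <- if (is.null(class_label)) which.max(scores)
           else if (is.character(class_label)) match(class_label, fit$class_names)
           else as.integer(class_label)
  if (is.na(c_idx)) stop("unknown class", call. = FALSE)
  C <- length(pooled)
  groups <- min(as.integer(groups), C)
  gidx <- sort(rep_len(seq_len(groups), C))
  if (is.null(baseline)) baseline <- numeric(C)
  w <- fit$model$params$fc$w[c_idx, ]
  b <- fit$model$params$fc$b[c_idx]
  value_fn <- function(S) {
    v <- baseline
    keep <- gidx %in% S
    v[keep] <- pooled[keep]
    sum(w * v) + b
  }
  out <- if (groups <= 12L) shapley_exact(value_fn, groups)
         else shapley_sampled(value_fn, groups, ...)
  attr(out, "group_index") <- gidx
  attr(out, "target_class") <- fit$class_names[c_idx]
  out
}
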