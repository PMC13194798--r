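# The multi-scale deformable attention network.
#
# Pipeline: backbone feature pyramid -> per-level 1x1 projection + BN + ReLU
# -> bilinear alignment to the largest level's resolution -> channel
# concatenation -> bounded offset prediction (s * tanh) -> per-scale
# deformable grids -> differentiable bilinear sampling -> mean fusion ->
# spatial attention and squeeze-excitation channel attention -> 3x3
# refinement -> global average pool -> dropout -> linear head -> softmax.
#
# Everything is plain R arrays; msdam_backward() is the exact reverse-mode
# gradient of msdam_forward() and is verified against finite differences in
# the test suite.

# ---- backbone adapters -------------------------------------------------

#' Tiny convolutional pyramid backbone
#'
#' A small trainable CNN emitting four feature levels at strides 2/4/8/16
#' (stride-1 3x3 convolutions + ReLU + 2x2 average pooling per stage), with
#' a declared channel tuple. This is the desk-scale stand-in for a deep
#' pretrained backbone: any adapter exposing the same contract (fields
#' \code{channels}, \code{init}, \code{forward}, \code{backward}) can be
#' plugged into [msdam_model()] unchanged.
#'
#' @param channels integer length-4 channel tuple for the four levels.
#' @return object of class \code{msdam_backbone}.
#' @export
tiny_backbone <- function(channels = c(8L, 16L, 32L, 64L)) {
  stopifnot(length(channels) == 4L, all(channels >= 1L))
  channels <- as.integer(channels)
  structure(list(
    name = "tiny_cnn",
    channels = channels,
    init = function() {
      cin <- c(3L, channels[-4L])
      lapply(seq_len(4L), function(i)
        list(w = init_conv(3L, cin[i], channels[i]),
             b = numeric(channels[i])))
    },
    forward = function(params, x) {
      levels <- vector("list", 4L)
      cache <- vector("list", 4L)
      h <- x
      for (i in seq_len(4L)) {
        z <- conv2d_fwd(h, params[[i]]$w, params[[i]]$b)
        a <- relu_fwd(z)
        p <- avgpool2_fwd(a)
        cache[[i]] <- list(x = h, z = z, adim = dim(a))
        levels[[i]] <- p
        h <- p
      }
      list(levels = levels, cache = cache)
    },
    backward = function(params, cache, dlevels) {
      dparams <- vector("list", 4L)
      dnext <- NULL
      for (i in 4L:1L) {
        dp <- dlevels[[i]]
        if (!is.null(dnext)) dp <- dp + dnext
        da <- avgpool2_bwd(dp, cache[[i]]$adim)
        dz <- relu_bwd(cache[[i]]$z, da)
        g <- conv2d_bwd(cache[[i]]$x, params[[i]]$w, dz)
        dparams[[i]] <- list(w = g$dw, b = g$db)
        dnext <- if (i > 1L) g$dx else NULL
      }
      dparams
    }),
    class = "msdam_backbone")
}

init_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

# ---- model constructor -------------------------------------------------

#' Construct a multi-scale deformable attention classifier
#'
#' @param n_classes number of output classes (>= 2).
#' @param backbone a backbone adapter, e.g. [tiny_backbone()].
#' @param out_channels common projection width for all pyramid levels
#'   (the production recipe uses 512; desk-scale models use less).
#' @param offset_scale bound s on learned displacements: offsets are
#'   \code{s * tanh(conv(F_c))}, hence strictly inside (-s, s). Default 0.12.
#' @param se_ratio squeeze-excitation bottleneck reduction ratio.
#' @param sa_hidden hidden width of the spatial-attention branch (defaults
#'   to \code{out_channels}).
#' @param dropout dropout rate on the pooled feature before the linear head.
#' @param per_scale_offsets if TRUE (default) the offset predictor emits one
#'   (dx, dy) pair per pyramid level; if FALSE a single shared field.
#' @param input_size expected input side length in pixels (must be divisible
#'   by 16 for the tiny backbone).
#' @param seed seed for weight initialization. The offset predictor is
#'   zero-initialized so training starts from the identity sampler.
#' @return object of class \code{msdam_model}.
#' @export
msdam_model <- function(n_classes, backbone = tiny_backbone(),
                        out_channels = 64L, offset_scale = 0.12,
                        se_ratio = 16L, sa_hidden = NULL, dropout = 0.4,
                        per_scale_offsets = TRUE, input_size = 224L,
                        seed = 42L) {
  stopifnot(n_classes >= 2L, inherits(backbone, "msdam_backbone"),
            out_channels >= 1L, offset_scale > 0, dropout >= 0, dropout < 1)
  set.seed(seed)
  oc <- as.integer(out_channels)
  nlev <- length(backbone$channels)
  sa_hidden <- if (is.null(sa_hidden)) oc else as.integer(sa_hidden)
  se_hidden <- max(1L, oc %/% as.integer(se_ratio))
  noff <- if (per_scale_offsets) 2L * nlev else 2L
  params <- list(
    backbone = backbone$init(),
    proj = lapply(backbone$channels, function(ci)
      list(w = init_conv(1L, ci, oc), b = numeric(oc))),
    bn = lapply(seq_len(nlev), function(i)
      list(gamma = rep(1, oc), beta = numeric(oc))),
    off = list(w = array(0, c(3L, 3L, nlev * oc, noff)), b = numeric(noff)),
    sa1 = list(w = init_conv(3L, oc, sa_hidden), b = numeric(sa_hidden)),
    sa2 = list(w = init_conv(1L, sa_hidden, 1L), b = numeric(1L)),
    se1 = list(w = matrix(stats::rnorm(se_hidden * oc, 0, sqrt(2 / oc)),
                          se_hidden, oc), b = numeric(se_hidden)),
    se2 = list(w = matrix(stats::rnorm(oc * se_hidden, 0, sqrt(2 / se_hidden)),
                          oc, se_hidden), b = numeric(oc)),
    ref = list(w = init_conv(3L, oc, oc), b = numeric(oc)),
    bnr = list(gamma = rep(1, oc), beta = numeric(oc)),
    fc = list(w = matrix(stats::rnorm(n_classes * oc, 0, sqrt(1 / oc)),
                         n_classes, oc), b = numeric(n_classes))
  )
  state <- list(bn = lapply(seq_len(nlev), function(i)
    list(mean = numeric(oc), var = rep(1, oc))),
    bnr = list(mean = numeric(oc), var = rep(1, oc)))
  structure(list(params = params, state = state, backbone = backbone,
                 config = list(n_classes = as.integer(n_classes),
                               channels = backbone$channels,
                               out_channels = oc,
                               offset_scale = offset_scale,
                               se_ratio = as.integer(se_ratio),
                               sa_hidden = sa_hidden,
                               se_hidden = se_hidden,
                               dropout = dropout,
                               per_scale_offsets = per_scale_offsets,
                               input_size = as.integer(input_size),
                               n_levels = nlev),
                 class_names = NULL),
            class = "msdam_model")
}

# ---- exported pipeline operations --------------------------------------

#' Extract the backbone feature pyramid
#'
#' Runs the model's backbone adapter and validates the channel contract:
#' each returned level must carry the adapter's declared channel width and
#' spatial sizes must strictly decrease with level.
#'
#' @param model an [msdam_model()].
#' @param x input batch, array \code{c(H, W, 3, N)}.
#' @return list of four feature maps (class \code{feature_pyramid}).
#' @export
extract_pyramid <- function(model, x) {
  out <- model$backbone$forward(model$params$backbone, x)
  check_pyramid(out$levels, model$config$channels)
  structure(out$levels, class = "feature_pyramid", cache = out$cache)
}

check_pyramid <- function(levels, channels) {
  if (length(levels) != length(channels))
    stop("backbone returned ", length(levels), " levels, expected ",
         length(channels), call. = FALSE)
  for (i in seq_along(levels)) {
    if (dim(levels[[i]])[3L] != channels[i])
      stop("backbone contract violation: level ", i, " has ",
           dim(levels[[i]])[3L], " channels, declared ", channels[i],
           call. = FALSE)
  }
  hs <- vapply(levels, function(l) dim(l)[1L], integer(1))
  ws <- vapply(levels, function(l) dim(l)[2L], integer(1))
  if (any(diff(hs) >= 0L) || any(diff(ws) >= 0L))
    stop("pyramid spatial sizes must strictly decrease with level",
         call. = FALSE)
  invisible(TRUE)
}

#' Project pyramid levels to a common width and align resolutions
#'
#' Each level passes a 1x1 convolution, batch normalization and ReLU to the
#' common width, is bilinearly resized to the largest level's resolution,
#' and the results are concatenated along channels.
#'
#' @param model an [msdam_model()].
#' @param pyramid output of [extract_pyramid()].
#' @param train logical; training mode for batch normalization.
#' @return list with \code{fc} (concatenated map), \code{aligned}
#'   (per-level aligned maps) and internal caches.
#' @export
project_and_align <- function(model, pyramid, train = FALSE) {
  p <- model$params
  nlev <- model$config$n_levels
  Hr <- dim(pyramid[[1L]])[1L]; Wr <- dim(pyramid[[1L]])[2L]
  aligned <- vector("list", nlev)
  caches <- vector("list", nlev)
  state <- model$state
  for (i in seq_len(nlev)) {
    z <- conv2d_fwd(pyramid[[i]], p$proj[[i]]$w, p$proj[[i]]$b)
    bn <- bn_fwd(z, p$bn[[i]]$gamma, p$bn[[i]]$beta, state$bn[[i]], train)
    state$bn[[i]] <- bn$state
    a <- relu_fwd(bn$y)
    rs <- resize_bilinear_fwd(a, Hr, Wr)
    aligned[[i]] <- rs$y
    caches[[i]] <- list(x = pyramid[[i]], z = z, bn = bn$cache, a = a,
                        rs = rs$cache)
  }
  fc <- do.call(abind4, aligned)
  list(fc = fc, aligned = aligned, caches = caches, state = state,
       ref_size = c(Hr, Wr))
}

# concatenate 4-D arrays along the channel dimension
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[3L], integer(1))
  out <- array(0, c(d[1L], d[2L], sum(cs), d[4L]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3L]
    out[, , (at + 1L):(at + cc), ] <- x
    at <- at + cc
  }
  out
}

#' Predict bounded sampling offsets
#'
#' A 3x3 convolution over the concatenated map followed by tanh and scaling:
#' \code{delta = s * tanh(conv(F_c))}. All entries are strictly inside
#' (-s, s); the zero-initialized predictor returns an all-zero field.
#'
#' @param model an [msdam_model()].
#' @param fc concatenated aligned map from [project_and_align()].
#' @return offset field, array \code{c(H, W, 2n, N)} (or \code{c(H, W, 2, N)}
#'   for a shared field), with attribute \code{scale}.
#' @export
predict_offsets <- function(model, fc) {
  z <- conv2d_fwd(fc, model$params$off$w, model$params$off$b)
  th <- tanh(z)
  delta <- model$config$offset_scale * th
  attr(delta, "scale") <- model$config$offset_scale
  attr(delta, "tanh") <- th
  delta
}

#' Build the deformable sampling grid for one scale
#'
#' The base lattice spans [-1, 1] inclusive on both axes with uniform
#' spacing (\code{-1 + 2j/(W-1)}); the scale's (dx, dy) offset channels are
#' added and the result is clamped to [-1, 1].
#'
#' @param H,W grid size (both >= 2).
#' @param delta offset field from [predict_offsets()], or NULL for the base
#'   grid itself.
#' @param scale_index which pyramid level's offset pair to use.
#' @param n_batch batch size when \code{delta} is NULL.
#' @return sampling grid, array \code{c(H, W, 2, N)}; x coordinates in slice
#'   1, y in slice 2.
#' @export
make_sampling_grid <- function(H, W, delta = NULL, scale_index = 1L,
                               n_batch = 1L) {
  if (H < 2L || W < 2L)
    stop("grid needs H >= 2 and W >= 2", call. = FALSE)
  N <- if (is.null(delta)) n_batch else dim(delta)[4L]
  g <- array(0, c(H, W, 2L, N))
  g[, , 1L, ] <- matrix(base_axis(W), H, W, byrow = TRUE)
  g[, , 2L, ] <- matrix(base_axis(H), H, W)
  if (!is.null(delta)) {
    ch <- offset_channels(delta, scale_index)
    stopifnot(dim(delta)[1L] == H, dim(delta)[2L] == W)
    g <- g + delta[, , ch, , drop = FALSE]
    g <- pmin(pmax(g, -1), 1)
  }
  g
}

offset_channels <- function(delta, scale_index) {
  if (dim(delta)[3L] == 2L) c(1L, 2L)
  else c(2L * scale_index - 1L, 2L * scale_index)
}

#' Differentiable bilinear sampling
#'
#' Samples feature map \code{f} at the normalized grid coordinates by the
#' four-neighbour bilinear rule, align-corners convention ((-1, -1) is the
#' top-left pixel center). Out-of-range coordinates are an error: clamping
#' is the grid builder's job. The operation is differentiable in both the
#' map and the grid; see \code{\link{msdam_gradients}} internals.
#'
#' @param f feature map, array \code{c(H, W, C, N)}.
#' @param grid sampling grid, array \code{c(Ho, Wo, 2, N)} in [-1, 1].
#' @return sampled map, array \code{c(Ho, Wo, C, N)}.
#' @export
bilinear_sample <- function(f, grid) {
  grid_sample_fwd(f, grid)$y
}

#' Mean-fuse sampled maps and refine with dual attention
#'
#' Averages the per-scale sampled maps, computes a spatial attention mask
#' (3x3 conv, ReLU, 1x1 conv, sigmoid) and a squeeze-excitation channel
#' mask (global pool, bottleneck, sigmoid), applies both multiplicatively,
#' and refines with a 3x3 convolution + batch norm + ReLU.
#'
#' @param model an [msdam_model()].
#' @param sampled list of sampled maps with identical shapes.
#' @param train logical; training mode for batch normalization.
#' @return fused feature map; attributes \code{spatial} and \code{channel}
#'   hold the attention masks.
#' @export
attend_and_fuse <- function(model, sampled, train = FALSE) {
  out <- fuse_fwd(model, sampled, model$state, train)
  y <- out$fused
  attr(y, "spatial") <- out$cache$a_s
  attr(y, "channel") <- out$cache$a_c
  y
}

fuse_fwd <- function(model, sampled, state, train) {
  p <- model$params
  dd <- dim(sampled[[1L]])
  for (s in sampled) if (!identical(dim(s), dd))
    stop("sampled maps must share one shape", call. = FALSE)
  n <- length(sampled)
  fm <- Reduce(`+`, sampled) / n
  # spatial attention
  s1 <- conv2d_fwd(fm, p$sa1$w, p$sa1$b)
  s1r <- relu_fwd(s1)
  s2 <- conv2d_fwd(s1r, p$sa2$w, p$sa2$b)
  a_s <- sigmoid_fwd(s2)
  # channel squeeze-excitation
  g <- gap_fwd(fm)
  e1 <- fc_fwd(g, p$se1$w, p$se1$b)
  e1r <- relu_fwd(e1)
  e2 <- fc_fwd(e1r, p$se2$w, p$se2$b)
  a_c <- sigmoid_fwd(e2)
  # refinement: channel mask, then spatial mask, then conv-BN-ReLU
  fac <- scale_channels(fm, a_c)
  C <- dd[3L]
  a_sb <- a_s[, , rep(1L, C), , drop = FALSE]
  fas <- fac * a_sb
  rz <- conv2d_fwd(fas, p$ref$w, p$ref$b)
  bn <- bn_fwd(rz, p$bnr$gamma, p$bnr$beta, state$bnr, train)
  state$bnr <- bn$state
  fused <- relu_fwd(bn$y)
  list(fused = fused, state = state,
       cache = list(fm = fm, n = n, s1 = s1, s1r = s1r, a_s = a_s,
                    g = g, e1 = e1, e1r = e1r, a_c = a_c,
                    fac = fac, a_sb = a_sb, fas = fas, rz = rz,
                    bn = bn$cache, bny = bn$y, dims = dd))
}

fuse_bwd <- function(model, cache, dfused) {
  p <- model$params
  dd <- cache$dims
  C <- dd[3L]
  dbn <- relu_bwd(cache$bny, dfused)
  bnb <- bn_bwd(cache$bn, p$bnr$gamma, dbn)
  refb <- conv2d_bwd(cache$fas, p$ref$w, bnb$dx)
  dfas <- refb$dx
  # product with broadcast spatial mask
  dfac <- dfas * cache$a_sb
  das_full <- dfas * cache$fac
  das <- sum_channels_keep(das_full)
  # product with broadcast channel mask
  dfm <- scale_channels(dfac, cache$a_c)
  dac <- channel_sums(dfac * cache$fm, dd)
  # spatial attention branch
  ds2 <- sigmoid_bwd(cache$a_s, das)
  sa2b <- conv2d_bwd(cache$s1r, p$sa2$w, ds2)
  ds1 <- relu_bwd(cache$s1, sa2b$dx)
  sa1b <- conv2d_bwd(cache$fm, p$sa1$w, ds1)
  dfm <- dfm + sa1b$dx
  # channel attention branch
  de2 <- sigmoid_bwd(cache$a_c, dac)
  se2b <- fc_bwd(cache$e1r, p$se2$w, de2)
  de1 <- relu_bwd(cache$e1, se2b$dx)
  se1b <- fc_bwd(cache$g, p$se1$w, de1)
  dfm <- dfm + gap_bwd(se1b$dx, dd)
  dsampled_each <- dfm / cache$n
  list(dsampled_each = dsampled_each,
       grads = list(ref = list(w = refb$dw, b = refb$db),
                    bnr = list(gamma = bnb$dgamma, beta = bnb$dbeta),
                    sa1 = list(w = sa1b$dw, b = sa1b$db),
                    sa2 = list(w = sa2b$dw, b = sa2b$db),
                    se1 = list(w = se1b$dw, b = se1b$db),
                    se2 = list(w = se2b$dw, b = se2b$db)))
}

# sum over the channel dimension, keeping a singleton channel
sum_channels_keep <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  array(rowSums(m), c(d[1L], d[2L], 1L, d[4L]))
}

# sum over spatial positions -> (C, N)
channel_sums <- function(x, d) {
  matrix(colSums(matrix(x, d[1L] * d[2L], d[3L] * d[4L])), d[3L], d[4L])
}

#' Classification head
#'
#' Global average pool, dropout (active only in training mode), linear
#' layer, softmax.
#'
#' @param model an [msdam_model()].
#' @param fused fused feature map from [attend_and_fuse()].
#' @param train logical; enables dropout.
#' @return list with \code{probs} (K x N, rows the classes), \code{scores}
#'   (pre-softmax), and \code{pooled} (penultimate feature, C x N).
#' @export
classify <- function(model, fused, train = FALSE) {
  out <- head_fwd(model, fused, train)
  out[c("probs", "scores", "pooled")]
}

head_fwd <- function(model, fused, train) {
  p <- model$params
  pooled <- gap_fwd(fused)
  if (train && model$config$dropout > 0) {
    keep <- 1 - model$config$dropout
    mask <- matrix(stats::rbinom(length(pooled), 1L, keep) / keep,
                   nrow(pooled), ncol(pooled))
    dropped <- pooled * mask
  } else {
    mask <- NULL
    dropped <- pooled
  }
  scores <- fc_fwd(dropped, p$fc$w, p$fc$b)
  probs <- softmax_cols(scores)
  list(probs = probs, scores = scores, pooled = pooled,
       cache = list(dropped = dropped, mask = mask, fdim = dim(fused)))
}

head_bwd <- function(model, cache, dscores) {
  fcb <- fc_bwd(cache$dropped, model$params$fc$w, dscores)
  dpooled <- fcb$dx
  if (!is.null(cache$mask)) dpooled <- dpooled * cache$mask
  list(dfused = gap_bwd(dpooled, cache$fdim),
       grads = list(fc = list(w = fcb$dw, b = fcb$db)))
}

softmax_cols <- function(scores) {
  z <- sweep(scores, 2L, apply(scores, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# ---- full forward / backward -------------------------------------------

#' Full forward pass
#'
#' Composes pyramid extraction, projection/alignment, offset prediction,
#' per-scale deformable sampling, attention fusion and the head.
#'
#' @param model an [msdam_model()].
#' @param x input batch, array \code{c(H, W, 3, N)} (normalized images).
#' @param train logical; training mode (batch-norm batch statistics,
#'   dropout active).
#' @param keep_cache keep intermediate activations for [msdam_backward()].
#' @return list with \code{probs}, \code{scores}, \code{pooled},
#'   \code{fused}, \code{delta}, updated \code{state}, and (optionally)
#'   \code{cache}.
#' @export
msdam_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  pyr <- model$backbone$forward(model$params$backbone, x)
  check_pyramid(pyr$levels, model$config$channels)
  pa <- project_and_align_internal(model, pyr$levels, model$state, train)
  delta <- predict_offsets(model, pa$fc)
  nlev <- model$config$n_levels
  Hr <- pa$ref_size[1L]; Wr <- pa$ref_size[2L]
  grids <- vector("list", nlev)
  samp <- vector("list", nlev)
  scaches <- vector("list", nlev)
  for (i in seq_len(nlev)) {
    grids[[i]] <- make_sampling_grid(Hr, Wr, delta, i)
    gs <- grid_sample_fwd(pa$aligned[[i]], grids[[i]])
    samp[[i]] <- gs$y
    scaches[[i]] <- gs$cache
  }
  fu <- fuse_fwd(model, samp, pa$state, train)
  hd <- head_fwd(model, fu$fused, train)
  out <- list(probs = hd$probs, scores = hd$scores, pooled = hd$pooled,
              fused = fu$fused, delta = delta, state = fu$state)
  if (keep_cache) {
    out$cache <- list(x = x, bb = pyr, levels = pyr$levels, pa = pa,
                      delta = delta, grids = grids, scaches = scaches,
                      sampled = samp, fuse = fu$cache, head = hd$cache)
  }
  out
}

project_and_align_internal <- function(model, levels, state, train) {
  pyr <- structure(levels, class = "feature_pyramid")
  m <- model; m$state <- state
  project_and_align(m, pyr, train)
}

#' Reverse-mode gradients of the full model
#'
#' Given the cache of a forward pass with \code{keep_cache = TRUE} and the
#' gradient of the loss with respect to the pre-softmax scores, returns the
#' gradient with respect to every parameter (same nesting as
#' \code{model$params}) plus, on request, intermediate gradients (the fused
#' map, the offset field) used by the explainability operators.
#'
#' @param model an [msdam_model()].
#' @param cache forward cache.
#' @param dscores gradient at the scores, K x N.
#' @return list with \code{grads} and \code{intermediates}.
#' @export
msdam_backward <- function(model, cache, dscores) {
  p <- model$params
  cfg <- model$config
  nlev <- cfg$n_levels
  hb <- head_bwd(model, cache$head, dscores)
  fb <- fuse_bwd(model, cache$fuse, hb$dfused)
  grads <- c(hb$grads, fb$grads)
  # through per-scale sampling
  daligned <- vector("list", nlev)
  s <- cfg$offset_scale
  ddelta <- array(0, dim(cache$delta))
  for (i in seq_len(nlev)) {
    gsb <- grid_sample_bwd(cache$scaches[[i]], fb$dsampled_each)
    daligned[[i]] <- gsb$df
    ch <- offset_channels(cache$delta, i)
    # clamp gate: gradient passes only where the grid was not saturated
    open <- abs(cache$grids[[i]]) < 1
    ddelta[, , ch, ] <- ddelta[, , ch, , drop = FALSE] + gsb$dgrid * open
  }
  # offset predictor: delta = s * tanh(conv(fc))
  th <- attr(cache$delta, "tanh")
  dz <- tanh_bwd(th, ddelta * s)
  offb <- conv2d_bwd(cache$pa$fc, p$off$w, dz)
  grads$off <- list(w = offb$dw, b = offb$db)
  dfc <- offb$dx
  # split concat gradient back onto the aligned maps
  oc <- cfg$out_channels
  for (i in seq_len(nlev)) {
    chs <- ((i - 1L) * oc + 1L):(i * oc)
    daligned[[i]] <- daligned[[i]] + dfc[, , chs, , drop = FALSE]
  }
  # projection branches
  grads$proj <- vector("list", nlev)
  grads$bn <- vector("list", nlev)
  dlevels <- vector("list", nlev)
  for (i in seq_len(nlev)) {
    cc <- cache$pa$caches[[i]]
    da <- resize_bilinear_bwd(cc$rs, daligned[[i]])
    dbn <- relu_bwd(cc$a, da)
    bnb <- bn_bwd(cc$bn, p$bn[[i]]$gamma, dbn)
    cvb <- conv2d_bwd(cc$x, p$proj[[i]]$w, bnb$dx)
    grads$proj[[i]] <- list(w = cvb$dw, b = cvb$db)
    grads$bn[[i]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dlevels[[i]] <- cvb$dx
  }
  grads$backbone <- model$backbone$backward(p$backbone, cache$bb$cache,
                                            dlevels)
  list(grads = grads,
       intermediates = list(dfused = hb$dfused, ddelta = ddelta))
}

# ---- reporting ---------------------------------------------------------

count_leaves <- function(x) {
  if (is.list(x)) sum(vapply(x, count_leaves, numeric(1))) else length(x)
}

#' Parameter count per submodule
#' @param model an [msdam_model()].
#' @return data.frame with columns submodule, parameters.
#' @export
msdam_param_count <- function(model) {
  p <- model$params
  data.frame(submodule = names(p),
             parameters = vapply(p, count_leaves, numeric(1)),
             row.names = NULL)
}

#' @export
print.msdam_model <- function(x, ...) {
  cfg <- x$config
  cat("Multi-scale deformable attention classifier\n")
  cat(sprintf("  backbone: %s, channels (%s)\n", x$backbone$name,
              paste(cfg$channels, collapse = ", ")))
  cat(sprintf("  projection width %d, offset scale %.3g, SE ratio %d, dropout %.2f\n",
              cfg$out_channels, cfg$offset_scale, cfg$se_ratio, cfg$dropout))
  cat(sprintf("  classes: %d   parameters: %s\n", cfg$n_classes,
              format(sum(msdam_param_count(x)$parameters), big.mark = ",")))
  invisible(x)
}
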