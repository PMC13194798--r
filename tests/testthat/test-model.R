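# Network components: pyramid contract, grids, offsets, bilinear sampling,
# fusion, head, and the assembled forward pass.

test_that("tiny backbone satisfies the pyramid contract", {
  m <- tiny_model(channels = c(8L, 16L, 32L, 64L))
  x <- random_batch(32, 32, 2)
  pyr <- extract_pyramid(m, x)
  expect_length(pyr, 4L)
  expect_equal(vapply(pyr, function(l) dim(l)[3L], integer(1)),
               c(8L, 16L, 32L, 64L))
  hs <- vapply(pyr, function(l) dim(l)[1L], integer(1))
  expect_equal(hs, c(16L, 8L, 4L, 2L))       # strictly decreasing
  expect_true(all(vapply(pyr, function(l) dim(l)[4L], integer(1)) == 2L))
})

test_that("channel contract violations are caught", {
  m <- tiny_model()
  bad <- m
  bad$config$channels <- c(4L, 8L, 8L, 16L)  # declared tuple now wrong
  x <- random_batch()
  expect_error(extract_pyramid(bad, x), "contract")
})

test_that("projection/alignment concatenates n levels at the common width", {
  m <- tiny_model(out_channels = 8L)
  x <- random_batch()
  pyr <- extract_pyramid(m, x)
  pa <- project_and_align(m, pyr)
  expect_equal(dim(pa$fc), c(16L, 16L, 32L, 2L))  # 4 levels x 8 channels
  for (al in pa$aligned) {
    expect_equal(dim(al)[1:2], c(16L, 16L))
    expect_true(all(al >= 0))                     # ReLU output
  }
  # level already at reference size is untouched by alignment
  expect_true(isTRUE(pa$caches[[1L]]$rs$identity))
})

test_that("offsets are bounded by the scale and zero at initialization", {
  m <- tiny_model(out_channels = 8L)
  x <- random_batch()
  pa <- project_and_align(m, extract_pyramid(m, x))
  d0 <- predict_offsets(m, pa$fc)
  expect_true(all(d0 == 0))                       # zero-init conv
  for (seed in 1:3) {
    set.seed(seed)
    # moderate weights: strictly inside the open bound
    m$params$off$w <- array(rnorm(length(m$params$off$w), 0, 0.5),
                            dim(m$params$off$w))
    m$params$off$b <- rnorm(length(m$params$off$b), 0, 0.5)
    expect_lt(max(abs(predict_offsets(m, pa$fc))), 0.12)
    # extreme weights: tanh saturates to 1 in floating point, so the
    # numerical supremum is the bound itself, never beyond it
    m$params$off$w <- m$params$off$w * 100
    expect_lte(max(abs(predict_offsets(m, pa$fc))), 0.12)
  }
  # scalar evaluation of the bounding rule: pre-activation 1, s = 0.12
  expect_equal(0.12 * tanh(1), 0.0913913, tolerance = 1e-6)
})

test_that("base grid spans [-1, 1] exactly and clamping applies", {
  g <- make_sampling_grid(2L, 2L)
  expect_equal(sort(unique(as.vector(g[, , 1L, ]))), c(-1, 1))
  g5 <- make_sampling_grid(5L, 5L)
  expect_equal(g5[1L, 3L, 1L, 1L], 0)             # -1 + 2*2/4
  expect_equal(g5[3L, 1L, 2L, 1L], 0)
  expect_true(all(diff(g5[1L, , 1L, 1L]) > 0))    # monotone along x
  expect_true(all(diff(g5[, 1L, 2L, 1L]) > 0))    # monotone along y
  # 0.95 + 0.12 clamps to 1
  delta <- array(0.12, c(3L, 41L, 2L, 1L))
  gg <- make_sampling_grid(3L, 41L, delta, 1L)
  expect_equal(max(gg), 1)
  expect_equal(gg[1L, 41L, 1L, 1L], 1)            # base 1.0 stays 1.0
  base40 <- -1 + 2 * 39 / 40                      # = 0.95
  expect_equal(gg[1L, 40L, 1L, 1L], 1)            # 0.95 + 0.12 -> clamp
  expect_error(make_sampling_grid(1L, 5L), "H >= 2")
})

test_that("sampling at the base grid is the identity", {
  set.seed(4)
  f <- array(rnorm(7 * 9 * 3 * 2), c(7, 9, 3, 2))
  g <- make_sampling_grid(7L, 9L, n_batch = 2L)
  expect_equal(bilinear_sample(f, g), f, tolerance = 1e-12)
})

test_that("bilinear sampling matches hand evaluation on a 2x2 map", {
  f <- array(0, c(2, 2, 1, 1))
  f[1, 1, 1, 1] <- 0; f[1, 2, 1, 1] <- 1   # row 1: F(x0,y0), F(x1,y0)
  f[2, 1, 1, 1] <- 2; f[2, 2, 1, 1] <- 3   # row 2: F(x0,y1), F(x1,y1)
  g <- array(0, c(1, 1, 2, 1))             # center: u = v = 0.5
  expect_equal(as.vector(bilinear_sample(f, g)), 1.5)
  # off-center point: x = -0.5, y = 0 -> px = 0.25, py = 0.5
  g2 <- array(c(-0.5, 0), c(1, 1, 2, 1))
  expect_equal(as.vector(bilinear_sample(f, g2)),
               0.75 * 0.5 * 0 + 0.25 * 0.5 * 1 + 0.75 * 0.5 * 2 +
                 0.25 * 0.5 * 3)
  expect_error(bilinear_sample(f, array(1.5, c(1, 1, 2, 1))), "-1, 1")
})

test_that("vectorized sampling equals a scalar loop on exhaustive 3x3 maps", {
  # all 3x3 maps from a fixed random draw, sampled on a 5x5 lattice of
  # [-1,1]^2: compare against direct scalar evaluation of the bilinear rule
  set.seed(8)
  lattice <- seq(-1, 1, length.out = 5)
  for (rep in 1:5) {
    f <- array(rnorm(9), c(3, 3, 1, 1))
    g <- array(0, c(5, 5, 2, 1))
    g[, , 1L, 1L] <- matrix(lattice, 5, 5, byrow = TRUE)
    g[, , 2L, 1L] <- matrix(lattice, 5, 5)
    got <- bilinear_sample(f, g)
    for (i in 1:5) for (j in 1:5) {
      px <- (lattice[j] + 1) / 2 * 2   # W-1 = 2
      py <- (lattice[i] + 1) / 2 * 2
      x0 <- floor(px); y0 <- floor(py)
      u <- px - x0; v <- py - y0
      cl <- function(z) min(max(z, 0), 2)
      val <- (1 - u) * (1 - v) * f[cl(y0) + 1, cl(x0) + 1, 1, 1] +
             u * (1 - v) * f[cl(y0) + 1, cl(x0 + 1) + 1, 1, 1] +
             (1 - u) * v * f[cl(y0 + 1) + 1, cl(x0) + 1, 1, 1] +
             u * v * f[cl(y0 + 1) + 1, cl(x0 + 1) + 1, 1, 1]
      expect_equal(got[i, j, 1, 1], val, tolerance = 1e-6)
    }
  }
})

test_that("fusion identities: mean of equals, masks in [0,1], unit masks", {
  m <- tiny_model(out_channels = 8L)
  set.seed(10)
  a <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  sampled <- list(a, a, a, a)
  fu <- msdam:::fuse_fwd(m, sampled, m$state, train = FALSE)
  expect_equal(fu$cache$fm, a, tolerance = 1e-12)   # mean of equal maps
  expect_true(all(fu$cache$a_s >= 0 & fu$cache$a_s <= 1))
  expect_true(all(fu$cache$a_c >= 0 & fu$cache$a_c <= 1))
  # permutation of the scales leaves the mean unchanged
  set.seed(11)
  sm <- lapply(1:4, function(i) array(rnorm(16 * 16 * 8 * 2),
                                      c(16, 16, 8, 2)))
  f1 <- msdam:::fuse_fwd(m, sm, m$state, FALSE)
  f2 <- msdam:::fuse_fwd(m, sm[c(3, 1, 4, 2)], m$state, FALSE)
  expect_equal(f1$fused, f2$fused, tolerance = 1e-12)
  # forcing both masks to 1 reduces refinement to ReLU(BN(Conv(F_m)))
  m1 <- m
  m1$params$sa2$b <- 1e9        # sigmoid -> 1
  m1$params$se2$b <- rep(1e9, 8L)
  fu1 <- msdam:::fuse_fwd(m1, sm, m1$state, FALSE)
  z <- msdam:::conv2d_fwd(f1$cache$fm, m$params$ref$w, m$params$ref$b)
  bn <- msdam:::bn_fwd(z, m$params$bnr$gamma, m$params$bnr$beta,
                       m$state$bnr, train = FALSE)
  expect_equal(fu1$fused, msdam:::relu_fwd(bn$y), tolerance = 1e-9)
  expect_error(msdam:::fuse_fwd(m, list(a, a[, , , 1, drop = FALSE]),
                                m$state, FALSE), "shape")
})

test_that("classification head is a proper softmax with dropout semantics", {
  m <- tiny_model(dropout = 0.4)
  x <- random_batch(N = 3)
  fw1 <- msdam_forward(m, x, train = FALSE)
  expect_equal(colSums(fw1$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw1$probs >= 0))
  # eval mode is deterministic (dropout disabled)
  fw2 <- msdam_forward(m, x, train = FALSE)
  expect_identical(fw1$scores, fw2$scores)
  # zero-weight FC gives exactly uniform class probabilities
  m0 <- m
  m0$params$fc$w[] <- 0; m0$params$fc$b[] <- 0
  fw0 <- msdam_forward(m0, x, train = FALSE)
  expect_equal(fw0$probs, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  expect_equal(dim(fw1$pooled), c(8L, 3L))  # penultimate feature exposed
})

test_that("zero offsets make the deformable path equal identity resampling", {
  m <- tiny_model(out_channels = 8L)   # offset conv zero-initialized
  x <- random_batch(N = 2, seed = 20)
  fw <- msdam_forward(m, x, train = FALSE, keep_cache = TRUE)
  expect_true(all(fw$delta == 0))
  # each sampled map equals its aligned input exactly
  for (i in 1:4)
    expect_equal(fw$cache$sampled[[i]], fw$cache$pa$aligned[[i]],
                 tolerance = 1e-5)
})

test_that("gradient flows into the offset predictor after one backward", {
  m <- tiny_model_offsets(out_channels = 8L)
  x <- random_batch(N = 2, seed = 21)
  fw <- msdam_forward(m, x, train = TRUE, keep_cache = TRUE)
  lg <- msdam:::loss_and_grad(fw$scores, c(1L, 2L), 0.1)
  bw <- msdam_backward(m, fw$cache, lg$grad)
  expect_gt(sqrt(sum(bw$grads$off$w^2)), 0)
  # every parameter group receives some gradient
  gnorms <- vapply(bw$grads[names(m$params)],
                   function(g) sqrt(sum(unlist(g)^2)), numeric(1))
  expect_true(all(gnorms > 0))
})

test_that("batch dimension is preserved through every level", {
  m <- tiny_model()
  x <- random_batch(N = 2)
  fw <- msdam_forward(m, x, train = FALSE)
  expect_equal(dim(fw$probs), c(3L, 2L))
  expect_equal(dim(fw$fused)[4L], 2L)
})

test_that("parameter count report covers all submodules", {
  m <- tiny_model()
  pc <- msdam_param_count(m)
  expect_setequal(pc$submodule, names(m$params))
  expect_equal(sum(pc$parameters), length(msdam:::flatten_tree(m$params)))
})
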