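# Shared fixtures: tiny models and synthetic trees, built once per test run.

tiny_model <- function(n_classes = 3L, channels = c(4L, 8L, 8L, 8L),
                       out_channels = 8L, input_size = 32L, seed = 7L,
                       dropout = 0, ...) {
  msdam_model(n_classes = n_classes, backbone = tiny_backbone(channels),
              out_channels = out_channels, se_ratio = 4L,
              dropout = dropout, input_size = input_size, seed = seed, ...)
}

# a model whose offset predictor is perturbed off the zero-init point so
# that sampling sits away from the lattice kinks (needed by the
# finite-difference checks)
tiny_model_offsets <- function(..., off_sd = 0.05, off_seed = 3L) {
  m <- tiny_model(...)
  set.seed(off_seed)
  m$params$off$w <- array(stats::rnorm(length(m$params$off$w), 0, off_sd),
                          dim(m$params$off$w))
  m$params$off$b <- stats::rnorm(length(m$params$off$b), 0, off_sd)
  m
}

random_batch <- function(H = 32L, W = 32L, N = 2L, seed = 1L) {
  set.seed(seed)
  array(stats::runif(H * W * 3L * N), c(H, W, 3L, N))
}

# synthetic tree in a session temp dir, cached across tests
demo_tree <- local({
  cache <- new.env()
  function(n_classes = 3L, patients = 4L, images = 2L, dup = 2L,
           size = 32L, seed = 11L) {
    key <- paste(n_classes, patients, images, dup, size, seed, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("msdam_tree_", key))
      spec <- synthetic_spec(n_classes, patients, images, c(size, size),
                             noise_std = 0.05, duplicate_count = dup,
                             seed = seed)
      generate_dataset(spec, dir)
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

# numeric loss of the tiny model as a function of the flat parameter vector
flat_loss_fn <- function(model, x, y, smoothing = 0.1) {
  function(pvec) {
    m <- model
    m$params <- msdam:::unflatten_tree(pvec, model$params)
    fw <- msdam_forward(m, x, train = TRUE)
    msdam:::loss_and_grad(fw$scores, y, smoothing)$loss
  }
}
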