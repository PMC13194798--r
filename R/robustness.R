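# Perturbation operators and the accuracy-vs-degradation sweep.

#' Perturbation specification
#'
#' @param kind "gaussian_noise" (levels are noise standard deviations on
#'   the [0, 1] scale) or "resolution" (levels are downscale percentages in
#'   (0, 100]).
#' @param levels numeric vector of perturbation levels. Defaults: the noise
#'   grid {0, 0.005, 0.01, 0.05, 0.1} and the resolution grid
#'   {100, 75, 50, 25}.
#' @param seed integer seed for the noise draws.
#' @return object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(kind = c("gaussian_noise", "resolution"),
                              levels = NULL, seed = 42L) {
  kind <- match.arg(kind)
  if (is.null(levels))
    levels <- if (kind == "gaussian_noise") c(0, 0.005, 0.01, 0.05, 0.1)
              else c(100, 75, 50, 25)
  if (kind == "gaussian_noise" && any(levels < 0))
    stop("noise sigma must be >= 0", call. = FALSE)
  if (kind == "resolution" && any(levels <= 0 | levels > 100))
    stop("resolution percentage must lie in (0, 100]", call. = FALSE)
  structure(list(kind = kind, levels = levels, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply one perturbation to an image
#'
#' Gaussian noise adds seeded N(0, sigma^2) per pixel and clips back to
#' [0, 1]; resolution degradation bilinearly downscales to \code{level}
#' percent of the original size and upscales back. Both operate on the raw
#' [0, 1] intensity scale, i.e. before normalization.
#'
#' @param img H x W x 3 array on [0, 1].
#' @param kind "gaussian_noise" or "resolution".
#' @param level noise sigma, or downscale percentage.
#' @return perturbed image of the original shape.
#' @export
perturb <- function(img, kind = c("gaussian_noise", "resolution"), level) {
  kind <- match.arg(kind)
  if (kind == "gaussian_noise") {
    if (level < 0) stop("noise sigma must be >= 0", call. = FALSE)
    if (level == 0) return(img)
    pmin(pmax(img + array(stats::rnorm(length(img), 0, level), dim(img)),
              0), 1)
  } else {
    if (level <= 0 || level > 100)
      stop("resolution percentage must lie in (0, 100]", call. = FALSE)
    if (level == 100) return(img)
    H <- dim(img)[1L]; W <- dim(img)[2L]
    h2 <- max(2L, round(H * level / 100))
    w2 <- max(2L, round(W * level / 100))
    resize_image(resize_image(img, h2, w2), H, W)
  }
}

#' Accuracy under increasing degradation
#'
#' Evaluates test-split accuracy at each perturbation level, applying the
#' perturbation to the raw image before normalization.
#'
#' @param fit an \code{msdam_fit}.
#' @param manifest a \code{split_manifest} with a non-empty test split.
#' @param spec a [perturbation_spec()].
#' @param split which split to evaluate (default "test").
#' @return data.frame with columns kind, level, accuracy.
#' @export
robustness_sweep <- function(fit, manifest, spec = perturbation_spec(),
                             split = "test") {
  stopifnot(inherits(spec, "perturbation_spec"))
  rows <- lapply(spec$levels, function(lv) {
    set.seed(spec$seed)
    ev <- evaluate_split(fit, manifest, split,
                         transform = function(im) perturb(im, spec$kind, lv))
    data.frame(kind = spec$kind, level = lv, accuracy = ev$accuracy)
  })
  do.call(rbind, rows)
}

#' Bar plot of a robustness sweep
#' @param sweep data.frame from [robustness_sweep()].
#' @param ... passed to \code{barplot}.
#' @export
plot_robustness <- function(sweep, ...) {
  graphics::barplot(sweep$accuracy, names.arg = sweep$level,
                    xlab = paste("level (", sweep$kind[1L], ")"),
                    ylab = "accuracy", ylim = c(0, 1), ...)
  invisible(sweep)
}
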