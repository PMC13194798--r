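# Image input/output. Internal representation is a numeric H x W x 3 array
# on the [0, 1] intensity scale.

#' Load an image as an H x W x 3 array on [0, 1]
#'
#' PNG files are decoded with \pkg{png}; other formats (e.g. JPEG) require
#' \pkg{EBImage}. Grayscale images are replicated to three channels and any
#' alpha channel is dropped, matching the RGB-conversion step of the scanning
#' pipeline.
#'
#' @param path path to an image file.
#' @return numeric array of dim \code{c(H, W, 3)} with values in [0, 1].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading non-PNG images requires the EBImage package",
           call. = FALSE)
    e <- EBImage::readImage(path)
    img <- as.array(e)
    # EBImage stores x (width) first; transpose to rows x columns
    img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] != 3L)
    stop("unsupported channel count in ", path, call. = FALSE)
  storage.mode(img) <- "double"
  pmin(pmax(img, 0), 1)
}

#' @keywords internal
save_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
}

# quantize to the 8-bit buffer used for hashing and PNG encoding
quantize8 <- function(img) {
  as.integer(round(pmin(pmax(img, 0), 1) * 255))
}
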