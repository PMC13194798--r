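# Synthetic image-tree generator and the built-in brain-tumor confusion
# fixture used throughout the tests and worked examples.

#' Specification for a synthetic image dataset
#'
#' Describes a directory tree of class-labelled synthetic images with the
#' structure the data pipeline assumes: one folder per class, filenames of
#' the form \code{<patient>_<index>.png}, several images per patient,
#' optional byte-identical duplicate files, and class imbalance if desired.
#'
#' Each class carries a distinct deterministic geometric signature (number
#' of bright Gaussian blobs and their ring radius on a dark background), so
#' the classes are separable by simple models; the generator makes no
#' attempt to mimic MRI contrast physics or anatomy.
#'
#' @param n_classes number of classes (>= 2).
#' @param patients_per_class patients per class (>= 1).
#' @param images_per_patient images per patient (>= 1).
#' @param image_size integer vector \code{c(H, W)} in pixels.
#' @param noise_std standard deviation of additive Gaussian pixel noise on
#'   the [0, 1] intensity scale.
#' @param duplicate_count number of injected exact-duplicate files (>= 0).
#' @param seed integer seed; the generated tree is fully reproducible.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_classes = 3L, patients_per_class = 4L,
                           images_per_patient = 2L, image_size = c(64L, 64L),
                           noise_std = 0.05, duplicate_count = 2L,
                           seed = 42L) {
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (patients_per_class < 1L) stop("patients_per_class must be >= 1", call. = FALSE)
  if (images_per_patient < 1L) stop("images_per_patient must be >= 1", call. = FALSE)
  if (length(image_size) != 2L || any(image_size < 8L))
    stop("image_size must be c(H, W) with H, W >= 8", call. = FALSE)
  if (noise_std < 0 || noise_std > 1)
    stop("noise_std must lie in [0, 1]", call. = FALSE)
  if (duplicate_count < 0L) stop("duplicate_count must be >= 0", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 patients_per_class = as.integer(patients_per_class),
                 images_per_patient = as.integer(images_per_patient),
                 image_size = as.integer(image_size),
                 noise_std = noise_std,
                 duplicate_count = as.integer(duplicate_count),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic per-class geometric signature: blob count cycles over 5,
# ring radius over 3 (coprime, so the first 15 classes are all distinct)
class_signature <- function(k) {
  list(n_blobs = ((k - 1L) %% 5L) + 1L,
       radius = 0.2 + 0.22 * ((k - 1L) %% 3L),
       sigma = 0.07 + 0.02 * ((k - 1L) %% 4L),
       phase = 2 * pi * (k * 0.618))
}

render_class_image <- function(k, H, W, jitter_x, jitter_y, jitter_phase,
                               noise_std) {
  sig <- class_signature(k)
  xs <- matrix(base_axis(W), H, W, byrow = TRUE)
  ys <- matrix(base_axis(H), H, W)
  base <- matrix(0.08, H, W)
  for (b in seq_len(sig$n_blobs)) {
    ang <- sig$phase + jitter_phase + 2 * pi * (b - 1) / sig$n_blobs
    cx <- sig$radius * cos(ang) + jitter_x
    cy <- sig$radius * sin(ang) + jitter_y
    base <- base + 0.85 * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sig$sigma^2))
  }
  img <- array(0, c(H, W, 3L))
  # mild per-channel tinting keeps the RGB path honest without adding class info
  img[, , 1L] <- base
  img[, , 2L] <- base * 0.95
  img[, , 3L] <- base * 0.9
  if (noise_std > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_std), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic class-labelled image tree
#'
#' Writes \code{<out_dir>/<class_k>/<pid>_<idx>.png} files according to a
#' [synthetic_spec()]. Duplicate files are byte-identical copies of already
#' written images, stored under a new index for the same patient, so they
#' are detected by the content-hash deduplication of [build_manifest()].
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir writable output directory (created if missing).
#' @return invisibly, a data.frame with columns path, class, patient_id and
#'   a logical \code{duplicate} flag; row count equals
#'   \code{n_classes * patients_per_class * images_per_patient + duplicate_count}.
#' @export
generate_dataset <- function(spec, out_dir) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be a synthetic_spec object", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  set.seed(spec$seed)
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  rows <- list()
  pid_no <- 0L
  for (k in seq_len(spec$n_classes)) {
    cls <- sprintf("class_%02d", k)
    cdir <- file.path(out_dir, cls)
    dir.create(cdir, showWarnings = FALSE)
    for (p in seq_len(spec$patients_per_class)) {
      pid_no <- pid_no + 1L
      pid <- sprintf("P%04d", pid_no)
      jx <- stats::runif(1, -0.08, 0.08)
      jy <- stats::runif(1, -0.08, 0.08)
      for (i in seq_len(spec$images_per_patient)) {
        jphase <- stats::runif(1, -0.25, 0.25)
        img <- render_class_image(k, H, W, jx, jy, jphase, spec$noise_std)
        path <- file.path(cdir, sprintf("%s_%03d.png", pid, i))
        save_png(img, path)
        rows[[length(rows) + 1L]] <-
          data.frame(path = path, class = cls, patient_id = pid,
                     duplicate = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  base <- do.call(rbind, rows)
  if (spec$duplicate_count > 0L) {
    src <- base[sample.int(nrow(base), spec$duplicate_count, replace = TRUE), ]
    for (j in seq_len(spec$duplicate_count)) {
      dst <- file.path(dirname(src$path[j]),
                       sprintf("%s_dup%03d.png", src$patient_id[j], j))
      file.copy(src$path[j], dst, overwrite = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(path = dst, class = src$class[j],
                   patient_id = src$patient_id[j], duplicate = TRUE,
                   stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, rows))
}

#' Built-in 15-class brain-tumor test confusion matrix
#'
#' The held-out-test confusion matrix of a published 15-class brain-MRI
#' tumor classifier (14 tumor types plus normal tissue, 508 test images,
#' 4 misclassifications), encoded exactly. Rows are actual classes, columns
#' predicted. The four errors are one schwannoma and one carcinoma predicted
#' as meningioma, one neurocytoma predicted as astrocytoma, and one
#' ganglioglioma predicted as normal. Used as the worked-example fixture
#' for the metric suite.
#'
#' @return a \code{confusion_matrix} object (see [build_confusion()]).
#' @export
brain_tumor_confusion <- function() {
  cls <- c("AST", "CAR", "EPE", "GAN", "GER", "GLI", "GRA", "MED",
           "MEN", "NEU", "NOR", "OLI", "PAP", "SCH", "TUB")
  support <- c(AST = 78L, CAR = 38L, EPE = 18L, GAN = 6L, GER = 12L,
               GLI = 24L, GRA = 11L, MED = 25L, MEN = 62L, NEU = 39L,
               NOR = 55L, OLI = 27L, PAP = 12L, SCH = 81L, TUB = 20L)
  counts <- diag(support)
  dimnames(counts) <- list(actual = cls, predicted = cls)
  miss <- rbind(c("SCH", "MEN"), c("NEU", "AST"),
                c("CAR", "MEN"), c("GAN", "NOR"))
  for (r in seq_len(nrow(miss))) {
    counts[miss[r, 1L], miss[r, 1L]] <- counts[miss[r, 1L], miss[r, 1L]] - 1L
    counts[miss[r, 1L], miss[r, 2L]] <- counts[miss[r, 1L], miss[r, 2L]] + 1L
  }
  new_confusion(counts, cls)
}

#' Expand a confusion matrix to paired label vectors
#'
#' Returns (actual, predicted) factor vectors whose cross-tabulation
#' reproduces the matrix; ordering is row-major over cells, deterministic.
#'
#' @param cm a \code{confusion_matrix}.
#' @return list with factors \code{actual} and \code{predicted} and the
#'   logical vector \code{correct}.
#' @export
confusion_to_labels <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cls <- cm$class_names
  K <- length(cls)
  idx <- which(cm$counts > 0, arr.ind = TRUE)
  n <- cm$counts[idx]
  actual <- factor(rep(cls[idx[, 1L]], n), levels = cls)
  predicted <- factor(rep(cls[idx[, 2L]], n), levels = cls)
  list(actual = actual, predicted = predicted,
       correct = as.integer(actual) == as.integer(predicted))
}

#' Write a confusion matrix as CSV (label column + one count column per class)
#' @param cm a \code{confusion_matrix}.
#' @param path output file.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(class = cm$class_names, unclass(cm$counts),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
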