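# Dataset scanning, content-hash deduplication, and patient-wise splitting.
#
# The guiding constraint is subject-level leakage: every image of a patient
# must land in exactly one of train/val/test, and no two retained images may
# share a content hash.

IMG_EXTS <- c("png", "jpg", "jpeg", "bmp", "tif", "tiff")

#' Extract the patient identifier from a filename
#'
#' The patient ID is the filename stem up to (not including) the first
#' underscore; a stem without an underscore is returned whole. This is a
#' total function: it never errors on non-empty input.
#'
#' @param filename file name or path.
#' @return character vector of patient IDs.
#' @export
#' @examples
#' extract_patient_id("P0123_slice04.jpg")  # "P0123"
#' extract_patient_id("scan.png")           # "scan"
extract_patient_id <- function(filename) {
  if (any(!nzchar(filename))) stop("empty filename", call. = FALSE)
  stem <- tools::file_path_sans_ext(basename(filename))
  sub("_.*$", "", stem)
}

# MD5 of the decoded 8-bit RGB pixel buffer in fixed (row, column, channel)
# byte order. Hashing the decoded buffer rather than the file bytes makes
# the duplicate set independent of PNG/JPEG container details.
hash_pixels <- function(img) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(as.raw(quantize8(img)), tmp)
  unname(tools::md5sum(tmp))
}

#' Scan an image tree into a deduplicated record table
#'
#' Recursively scans \code{root} expecting one sub-directory per class. Each
#' image is decoded, converted to RGB, and hashed on its raw 8-bit pixel
#' buffer; among hash-identical files only the lexicographically first path
#' (C-locale ordering) is retained. Unreadable files are skipped with a
#' warning and counted in \code{attr(, "skipped")}.
#'
#' @param root directory containing class sub-directories.
#' @return data.frame with columns path, class_label, patient_id,
#'   content_hash, sorted by path; attribute \code{skipped} holds the number
#'   of unreadable files.
#' @export
build_manifest <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE),
                  method = "radix")
  files <- character(0); labels <- character(0)
  for (cls in classes) {
    fs <- list.files(file.path(root, cls), full.names = TRUE,
                     pattern = paste0("\\.(", paste(IMG_EXTS, collapse = "|"),
                                      ")$"), ignore.case = TRUE)
    files <- c(files, fs)
    labels <- c(labels, rep(cls, length(fs)))
  }
  if (length(files) == 0L)
    stop("no images found under ", root, call. = FALSE)
  ord <- order(files, method = "radix")
  files <- files[ord]; labels <- labels[ord]
  hashes <- character(length(files))
  ok <- logical(length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(load_image(files[i]), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", files[i], call. = FALSE)
      next
    }
    hashes[i] <- hash_pixels(img)
    ok[i] <- TRUE
  }
  skipped <- sum(!ok)
  files <- files[ok]; labels <- labels[ok]; hashes <- hashes[ok]
  keep <- !duplicated(hashes)  # files already in lexicographic order
  out <- data.frame(path = files[keep],
                    class_label = labels[keep],
                    patient_id = extract_patient_id(files[keep]),
                    content_hash = hashes[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Patient-wise train/val/test split
#'
#' Groups records by patient, shuffles the patient groups with the seed, and
#' assigns whole groups greedily: train is filled until its image-count
#' target is reached, then validation, and test receives the remainder. The
#' zero-overlap invariant (no patient in more than one split) is verified
#' before returning.
#'
#' @param records record data.frame from [build_manifest()].
#' @param fractions numeric length-3 vector (train, val, test) of positive
#'   image fractions summing to 1.
#' @param seed integer shuffle seed.
#' @return object of class \code{split_manifest}: list with per-split record
#'   data.frames (\code{train}, \code{val}, \code{test}), \code{fractions},
#'   \code{seed}, and per-split image/patient counts.
#' @export
patient_split <- function(records, fractions = c(0.7, 0.15, 0.15),
                          seed = 42L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 positive numbers summing to 1", call. = FALSE)
  if (anyDuplicated(records$content_hash))
    stop("records contain duplicated content hashes; deduplicate first",
         call. = FALSE)
  pids <- unique(records$patient_id)
  if (length(pids) < 3L)
    stop("need at least 3 distinct patients to form 3 splits", call. = FALSE)
  n <- nrow(records)
  set.seed(seed)
  pids <- sample(pids)
  sizes <- vapply(pids, function(p) sum(records$patient_id == p), integer(1))
  target_train <- fractions[1L] * n
  target_val <- fractions[2L] * n
  assign <- character(length(pids))
  acc_train <- 0L; acc_val <- 0L
  for (i in seq_along(pids)) {
    if (acc_train < target_train - 1e-9) {
      assign[i] <- "train"; acc_train <- acc_train + sizes[i]
    } else if (acc_val < target_val - 1e-9) {
      assign[i] <- "val"; acc_val <- acc_val + sizes[i]
    } else {
      assign[i] <- "test"
    }
  }
  split_of <- stats::setNames(assign, pids)
  parts <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    r <- records[split_of[records$patient_id] == s, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  ps <- lapply(parts, function(r) unique(r$patient_id))
  if (length(intersect(ps$train, ps$val)) ||
      length(intersect(ps$train, ps$test)) ||
      length(intersect(ps$val, ps$test)))
    stop("internal error: patient overlap after assignment", call. = FALSE)
  structure(list(train = parts$train, val = parts$val, test = parts$test,
                 fractions = fractions, seed = as.integer(seed),
                 image_counts = vapply(parts, nrow, integer(1)),
                 patient_counts = vapply(ps, length, integer(1))),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("Patient-wise split manifest\n")
  cat(sprintf("  fractions: %.2f / %.2f / %.2f   seed: %d\n",
              x$fractions[1L], x$fractions[2L], x$fractions[3L], x$seed))
  for (s in c("train", "val", "test"))
    cat(sprintf("  %-5s %5d images  %5d patients\n",
                s, nrow(x[[s]]), length(unique(x[[s]]$patient_id))))
  invisible(x)
}

#' Serialize a split manifest to JSON
#' @param manifest a \code{split_manifest}.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "split_manifest"))
  obj <- list(fractions = manifest$fractions, seed = manifest$seed,
              image_counts = as.list(manifest$image_counts),
              patient_counts = as.list(manifest$patient_counts),
              splits = lapply(manifest[c("train", "val", "test")], function(r)
                list(path = r$path, class = r$class_label,
                     patient_id = r$patient_id, hash = r$content_hash)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split manifest written by [write_manifest()]
#' @param path JSON file.
#' @return a \code{split_manifest}.
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parts <- lapply(obj$splits, function(s)
    data.frame(path = s$path, class_label = s$class,
               patient_id = s$patient_id, content_hash = s$hash,
               stringsAsFactors = FALSE))
  structure(list(train = parts$train, val = parts$val, test = parts$test,
                 fractions = as.numeric(obj$fractions),
                 seed = as.integer(obj$seed),
                 image_counts = vapply(parts, nrow, integer(1)),
                 patient_counts = vapply(parts, function(r)
                   length(unique(r$patient_id)), integer(1))),
            class = "split_manifest")
}
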