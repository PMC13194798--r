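# Scanning, deduplication, patient-ID extraction, patient-wise splitting.

test_that("patient IDs are the stem before the first underscore", {
  expect_identical(extract_patient_id("P0123_slice04.jpg"), "P0123")
  expect_identical(extract_patient_id("scan.png"), "scan")
  expect_identical(extract_patient_id("a_b_c.jpeg"), "a")
  expect_identical(extract_patient_id("/some/dir/Q7_x_1.png"), "Q7")
  expect_error(extract_patient_id(""), "empty")
})

test_that("manifest deduplicates by pixel hash and keeps the first path", {
  dir <- demo_tree()  # 3*4*2 originals + 2 duplicates
  rec <- build_manifest(dir)
  expect_equal(nrow(rec), 24L)
  expect_false(anyDuplicated(rec$content_hash) > 0)
  expect_identical(rec$path, sort(rec$path, method = "radix"))
  expect_identical(rec$class_label, basename(dirname(rec$path)))
})

test_that("cross-class duplicate keeps the lexicographically first path", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "a")); dir.create(file.path(dir, "b"))
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  msdam:::save_png(img, file.path(dir, "b", "p1_1.png"))
  file.copy(file.path(dir, "b", "p1_1.png"), file.path(dir, "a", "p2_1.png"))
  rec <- build_manifest(dir)
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$class_label, "a")  # "a/..." sorts before "b/..."
})

test_that("manifest build is idempotent and deterministic", {
  dir <- demo_tree()
  r1 <- build_manifest(dir)
  r2 <- build_manifest(dir)
  expect_identical(r1, r2)
  # copying only the retained files elsewhere changes nothing but paths
  dir2 <- withr::local_tempdir()
  for (i in seq_len(nrow(r1))) {
    d <- file.path(dir2, r1$class_label[i])
    dir.create(d, showWarnings = FALSE)
    file.copy(r1$path[i], file.path(d, basename(r1$path[i])))
  }
  r3 <- build_manifest(dir2)
  expect_equal(nrow(r3), nrow(r1))
  expect_setequal(r3$content_hash, r1$content_hash)
})

test_that("unreadable images are skipped with a warning and counted", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "a"))
  msdam:::save_png(array(runif(16 * 16 * 3), c(16, 16, 3)),
                   file.path(dir, "a", "p1_1.png"))
  writeLines("not a png", file.path(dir, "a", "p2_1.png"))
  expect_warning(rec <- build_manifest(dir), "unreadable")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "skipped"), 1L)
})

test_that("empty root is a validation error", {
  dir <- withr::local_tempdir()
  expect_error(build_manifest(dir), "no images")
  expect_error(build_manifest(file.path(dir, "missing")), "no such")
})

fake_records <- function(n_patients, images_each = 1L) {
  pid <- rep(sprintf("P%03d", seq_len(n_patients)), each = images_each)
  data.frame(path = sprintf("%s_%03d.png", pid,
                            sequence(rep(images_each, n_patients))),
             class_label = "a", patient_id = pid,
             content_hash = sprintf("h%05d", seq_len(n_patients * images_each)),
             stringsAsFactors = FALSE)
}

test_that("split hits exact targets under exact divisibility", {
  rec <- fake_records(100L)
  man <- patient_split(rec, c(0.7, 0.15, 0.15), seed = 1L)
  expect_equal(unname(man$image_counts), c(70L, 15L, 15L))
  expect_equal(unname(man$patient_counts), c(70L, 15L, 15L))
})

test_that("patient sets never overlap across splits", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    nimg <- sample(1:5, 30, replace = TRUE)
    pid <- rep(sprintf("P%03d", 1:30), nimg)
    rec <- data.frame(path = sprintf("%s_%03d.png", pid, sequence(nimg)),
                      class_label = "a", patient_id = pid,
                      content_hash = sprintf("h%04d", seq_along(pid)),
                      stringsAsFactors = FALSE)
    man <- patient_split(rec, c(0.6, 0.2, 0.2), seed = seed)
    ps <- lapply(man[c("train", "val", "test")],
                 function(r) unique(r$patient_id))
    expect_length(intersect(ps$train, ps$val), 0)
    expect_length(intersect(ps$train, ps$test), 0)
    expect_length(intersect(ps$val, ps$test), 0)
    expect_equal(sum(man$image_counts), nrow(rec))
  }
})

test_that("a dominant patient lands wholly in one split", {
  pid <- c(rep("BIG", 6), "S1", "S2", "S3", "S4", "S5", "S6")
  rec <- data.frame(path = sprintf("%s_%03d.png", pid, seq_along(pid)),
                    class_label = "a", patient_id = pid,
                    content_hash = sprintf("h%03d", seq_along(pid)),
                    stringsAsFactors = FALSE)
  for (seed in 1:8) {
    man <- patient_split(rec, c(0.5, 0.25, 0.25), seed = seed)
    in_split <- vapply(man[c("train", "val", "test")],
                       function(r) "BIG" %in% r$patient_id, logical(1))
    expect_equal(sum(in_split), 1L)
  }
})

test_that("split is deterministic in (records, fractions, seed)", {
  rec <- fake_records(20L, 2L)
  m1 <- patient_split(rec, c(0.7, 0.15, 0.15), seed = 9L)
  m2 <- patient_split(rec, c(0.7, 0.15, 0.15), seed = 9L)
  expect_identical(m1, m2)
})

test_that("split input validation", {
  rec <- fake_records(2L)
  expect_error(patient_split(rec, c(0.7, 0.15, 0.15), 1L), "3 distinct")
  rec5 <- fake_records(5L)
  expect_error(patient_split(rec5, c(0.7, 0.3), 1L), "fractions")
  expect_error(patient_split(rec5, c(0.5, 0.4, 0.2), 1L), "fractions")
  dup <- rbind(rec5, rec5[1L, ])
  expect_error(patient_split(dup, c(0.7, 0.15, 0.15), 1L), "hash")
})

test_that("manifest JSON round-trips", {
  dir <- demo_tree()
  man <- patient_split(build_manifest(dir), c(0.5, 0.25, 0.25), seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$train$content_hash, man$train$content_hash)
  expect_equal(back$fractions, man$fractions)
  expect_equal(back$image_counts, man$image_counts)
})
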