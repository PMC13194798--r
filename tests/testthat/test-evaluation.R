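# Confusion tabulation, one-vs-rest metrics, aggregates, curves, KS,
# bootstrap resampling.

test_that("confusion tabulation and validation", {
  cm <- build_confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 1)))
  # perfect predictions give a diagonal matrix with supports on the diagonal
  y <- rep(c("a", "b", "c"), c(5, 2, 3))
  cmp <- build_confusion(y, y, c("a", "b", "c"))
  expect_equal(unname(diag(cmp$counts)), c(5, 2, 3))
  expect_equal(sum(cmp$counts) - sum(diag(cmp$counts)), 0)
  expect_error(build_confusion(character(0), character(0)), "empty")
  expect_error(build_confusion("a", "z", class_names = c("a", "b")),
               "outside")
})

test_that("per-class identities hold exactly on random matrices", {
  set.seed(31)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    counts <- matrix(rpois(K * K, 3), K, K)
    counts[1, 1] <- counts[1, 1] + 5L
    cm <- msdam:::new_confusion(counts, letters[1:K])
    pc <- class_metrics(cm)
    expect_equal(pc$fdr, 1 - pc$precision, tolerance = 1e-12)
    expect_equal(pc$fnr, 1 - pc$recall, tolerance = 1e-12)
    expect_equal(pc$dice, pc$f1, tolerance = 1e-12)
    expect_true(all(pc$specificity >= 0 & pc$specificity <= 1))
  }
})

test_that("one-vs-rest kappa matches a brute-force tabulation oracle", {
  set.seed(32)
  for (rep in 1:10) {
    counts <- matrix(rpois(9, 4), 3, 3)
    counts[2, 2] <- counts[2, 2] + 3L
    cm <- msdam:::new_confusion(counts, c("x", "y", "z"))
    lab <- confusion_to_labels(cm)
    pc <- class_metrics(cm)
    for (k in 1:3) {
      # independent oracle: binarize the label vectors and tabulate
      a <- as.integer(lab$actual) == k
      p <- as.integer(lab$predicted) == k
      n <- length(a)
      po <- mean(a == p)
      pe <- mean(a) * mean(p) + mean(!a) * mean(!p)
      kappa_bf <- (po - pe) / (1 - pe)
      expect_equal(pc$kappa[k], kappa_bf, tolerance = 1e-12)
    }
  }
})

test_that("fixture metrics reproduce the published per-class values", {
  rep <- metrics_report(brain_tumor_confusion())
  pc <- rep$per_class
  g <- function(cls, col) pc[[col]][pc$class == cls]
  r3 <- function(x) round(x, 3)
  expect_equal(r3(g("MEN", "precision")), 0.969)
  expect_equal(r3(g("GAN", "recall")), 0.833)
  expect_equal(r3(g("GAN", "f1")), 0.909)
  expect_equal(r3(g("GAN", "kappa")), 0.908)
  expect_equal(r3(g("AST", "precision")), 0.987)
  expect_equal(r3(g("AST", "accuracy")), 0.998)
  expect_equal(r3(g("AST", "kappa")), 0.992)
  expect_equal(r3(g("CAR", "recall")), 0.974)
  expect_equal(r3(g("NEU", "recall")), 0.974)
  expect_equal(r3(g("NOR", "precision")), 0.982)
  expect_equal(r3(g("SCH", "recall")), 0.988)
  expect_equal(r3(g("SCH", "kappa")), 0.993)
  # perfect classes
  for (cls in c("EPE", "GER", "GLI", "GRA", "MED", "OLI", "PAP", "TUB")) {
    expect_equal(g(cls, "precision"), 1)
    expect_equal(g(cls, "recall"), 1)
    expect_equal(g(cls, "kappa"), 1)
  }
})

test_that("aggregates: overall, macro, micro identities", {
  cm <- brain_tumor_confusion()
  rep <- metrics_report(cm)
  expect_equal(rep$overall_accuracy, 504 / 508)
  expect_equal(round(rep$macro[["precision"]], 3), 0.996)
  expect_equal(round(rep$macro[["recall"]], 3), 0.985)
  # micro precision = micro recall = overall accuracy for single-label data
  expect_equal(rep$micro[["precision"]], rep$overall_accuracy)
  expect_equal(rep$micro[["recall"]], rep$overall_accuracy)
  # degenerate single-class matrix: macro equals the class row
  cm1 <- msdam:::new_confusion(matrix(7, 1, 1), "only")
  r1 <- metrics_report(cm1)
  expect_equal(unname(r1$macro["precision"]), 1)
  expect_equal(r1$overall_accuracy, 1)
})

test_that("ROC/PR sweep: perfect, null, monotone-invariant, matches pROC", {
  set.seed(33)
  n <- 400
  cls <- c("a", "b", "c")
  actual <- sample(cls, n, TRUE)
  # perfectly separated scores
  sp <- matrix(0.01, n, 3, dimnames = list(NULL, cls))
  sp[cbind(seq_len(n), match(actual, cls))] <- 0.98
  cu <- ovr_curves(actual, sp)
  expect_equal(vapply(cu, function(z) z$auc, numeric(1)),
               c(a = 1, b = 1, c = 1))
  # label-independent scores -> AUC near 0.5
  s0 <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, cls))
  s0 <- s0 / rowSums(s0)
  cu0 <- ovr_curves(actual, s0)
  for (z in cu0) expect_lt(abs(z$auc - 0.5), 0.08)
  # AUC invariant under strictly monotone transforms of the scores
  s1 <- s0; s1[] <- qlogis(pmin(pmax(s0, 1e-6), 1 - 1e-6)) * 3 + 1
  cu1 <- ovr_curves(actual, s1, cls)
  expect_equal(vapply(cu1, function(z) z$auc, numeric(1)),
               vapply(cu0, function(z) z$auc, numeric(1)), tolerance = 1e-12)
  # cross-check against pROC on the same data
  skip_if_not_installed("pROC")
  for (k in 1:3) {
    ref <- suppressMessages(pROC::auc(pROC::roc(actual == cls[k], s0[, k],
                                                levels = c(FALSE, TRUE),
                                                direction = "<",
                                                quiet = TRUE)))
    expect_equal(cu0[[k]]$auc, as.numeric(ref), tolerance = 1e-10)
  }
  # absent class flagged undefined
  cuu <- ovr_curves(rep("a", 10), matrix(runif(20), 10, 2,
                                         dimnames = list(NULL, c("a", "b"))))
  expect_true(cuu$b$undefined)
})

test_that("KS statistic: extremes and the ROC identity", {
  set.seed(34)
  n <- 200
  actual <- sample(c("a", "b"), n, TRUE)
  sp <- matrix(0, n, 2, dimnames = list(NULL, c("a", "b")))
  sp[cbind(seq_len(n), match(actual, c("a", "b")))] <- 1
  ks <- ks_one_vs_rest(actual, sp)
  expect_equal(unname(ks$ks), c(1, 1))
  # identical distributions for positives and negatives -> KS = 0
  same <- matrix(0.5, n, 2, dimnames = list(NULL, c("a", "b")))
  ks0 <- ks_one_vs_rest(actual, same)
  expect_equal(unname(ks0$ks), c(0, 0))
  # KS = max over the ROC curve of TPR - FPR, against a direct ECDF oracle
  sc <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  sc[actual == "a", 1] <- sc[actual == "a", 1] + 0.3
  ksr <- ks_one_vs_rest(actual, sc)
  pos <- sc[actual == "a", 1]; neg <- sc[actual != "a", 1]
  thr <- sort(unique(sc[, 1]))
  gap <- max(abs(vapply(thr, function(t) mean(pos >= t) - mean(neg >= t),
                        numeric(1))))
  expect_equal(unname(ksr$ks["a"]), gap, tolerance = 1e-12)
  expect_equal(unname(ksr$summary["max"]), max(ksr$ks))
})

test_that("bootstrap accuracy: extremes, SE, and consistency", {
  all1 <- rep(1L, 50)
  bt1 <- bootstrap_accuracy(all1, 200L, seed = 1L)
  expect_equal(bt1$mean_accuracy, 1)
  expect_equal(c(bt1$ci_low, bt1$ci_high), c(1, 1))
  expect_equal(bt1$standard_error, 0)
  set.seed(2)
  v <- rbinom(300, 1, 0.8)
  bt <- bootstrap_accuracy(v, 2000L, seed = 3L)
  expect_true(bt$ci_low <= bt$mean_accuracy && bt$mean_accuracy <= bt$ci_high)
  # bootstrap mean close to the sample mean; SE near sqrt(p(1-p)/n)
  expect_lt(abs(bt$mean_accuracy - mean(v)), 3 * bt$standard_error + 1e-9)
  expect_equal(bt$standard_error, sqrt(mean(v) * (1 - mean(v)) / 300),
               tolerance = 0.1)
  expect_error(bootstrap_accuracy(numeric(0)), "empty")
})

test_that("round trip: fixture expansion re-tabulates to the fixture", {
  cm <- brain_tumor_confusion()
  lab <- confusion_to_labels(cm)
  back <- build_confusion(as.character(lab$actual),
                          as.character(lab$predicted), cm$class_names)
  expect_equal(back$counts, cm$counts)
})
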