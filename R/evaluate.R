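# Confusion-matrix construction and the multi-class metric suite:
# per-class one-vs-rest metrics, macro/micro aggregates, ROC/PR/AUC,
# one-vs-rest Kolmogorov-Smirnov statistics, and bootstrap accuracy CIs.

new_confusion <- function(counts, class_names) {
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

#' Tabulate a confusion matrix
#'
#' \code{counts[a, p]} is the number of samples with actual class a and
#' predicted class p.
#'
#' @param actual,predicted equal-length label vectors; every label must be
#'   one of \code{class_names}.
#' @param class_names ordered class labels; defaults to the sorted union of
#'   observed labels.
#' @return object of class \code{confusion_matrix}.
#' @export
build_confusion <- function(actual, predicted, class_names = NULL) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (is.null(class_names))
    class_names <- sort(unique(c(actual, predicted)), method = "radix")
  if (!all(actual %in% class_names) || !all(predicted %in% class_names))
    stop("labels outside class_names", call. = FALSE)
  a <- factor(actual, levels = class_names)
  p <- factor(predicted, levels = class_names)
  counts <- unclass(table(actual = a, predicted = p))
  new_confusion(counts, class_names)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: %d classes, %d samples, accuracy %.4f\n",
              length(x$class_names), sum(x$counts),
              sum(diag(x$counts)) / sum(x$counts)))
  print(x$counts)
  invisible(x)
}

# guarded ratio: 0 (flagged by caller) instead of NaN on empty denominators
safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Per-class one-vs-rest metrics
#'
#' For each class, the one-vs-rest TP/FP/FN/TN are derived from the matrix
#' and ten metrics computed: accuracy (TP+TN)/N, precision, recall, F1,
#' Dice (2TP/(2TP+FP+FN), identical to F1 in the binary case), specificity,
#' FDR (1 - precision), FOR, FNR (1 - recall), and one-vs-rest Cohen's
#' kappa with p_o = (TP+TN)/N and p_e from the marginal products.
#' Division-by-zero cases yield 0 and are flagged in the \code{degenerate}
#' column rather than NaN.
#'
#' @param cm a \code{confusion_matrix} with at least one sample.
#' @return data.frame, one row per class, plus a \code{support} column.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  N <- sum(counts)
  if (N == 0L) stop("empty confusion matrix", call. = FALSE)
  K <- length(cm$class_names)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    tp <- counts[k, k]
    fn <- sum(counts[k, ]) - tp
    fp <- sum(counts[, k]) - tp
    tn <- N - tp - fn - fp
    prec <- safe_div(tp, tp + fp)
    rec <- safe_div(tp, tp + fn)
    p_act <- tp + fn; p_pred <- tp + fp
    po <- (tp + tn) / N
    pe <- (p_act * p_pred + (N - p_act) * (N - p_pred)) / N^2
    out[[k]] <- data.frame(
      class = cm$class_names[k],
      support = as.integer(p_act),
      accuracy = (tp + tn) / N,
      precision = prec,
      recall = rec,
      f1 = safe_div(2 * prec * rec, prec + rec),
      dice = safe_div(2 * tp, 2 * tp + fp + fn),
      specificity = safe_div(tn, tn + fp),
      fdr = 1 - prec,
      for_rate = safe_div(fn, tn + fn),
      fnr = 1 - rec,
      kappa = if (pe < 1) (po - pe) / (1 - pe) else 0,
      degenerate = (tp + fp) == 0 || (tp + fn) == 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Aggregate per-class metrics into a report
#'
#' Macro averages are unweighted means of the per-class metrics; micro
#' averages pool the one-vs-rest counts before computing each metric;
#' overall accuracy is trace/total.
#'
#' @param per_class output of [class_metrics()].
#' @param cm the \code{confusion_matrix} the metrics came from.
#' @return object of class \code{metrics_report}: list with
#'   \code{per_class}, \code{macro}, \code{micro}, \code{overall_accuracy}.
#' @export
aggregate_metrics <- function(per_class, cm) {
  stopifnot(nrow(per_class) > 0L, inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  N <- sum(counts)
  cols <- c("accuracy", "precision", "recall", "f1", "dice", "specificity",
            "fdr", "for_rate", "fnr", "kappa")
  macro <- colMeans(per_class[cols])
  # pooled one-vs-rest counts
  tp <- sum(diag(counts))
  fp <- N - tp   # every error is one FP and one FN in the pooled view
  fn <- N - tp
  tn <- N * nrow(per_class) - N - 2 * (N - tp)  # complement over K binarizations
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  NN <- N * nrow(per_class)
  po <- (tp + tn) / NN
  micro <- c(accuracy = (tp + tn) / NN,
             precision = prec, recall = rec,
             f1 = safe_div(2 * prec * rec, prec + rec),
             dice = safe_div(2 * tp, 2 * tp + fp + fn),
             specificity = safe_div(tn, tn + fp),
             fdr = 1 - prec, for_rate = safe_div(fn, tn + fn),
             fnr = 1 - rec, kappa = NA_real_)
  structure(list(per_class = per_class, macro = macro, micro = micro,
                 overall_accuracy = tp / N),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  cat(sprintf("Overall accuracy: %.4f (%.2f%%)\n",
              x$overall_accuracy, 100 * x$overall_accuracy))
  tab <- x$per_class
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("macro: "); print(round(x$macro, digits))
  invisible(x)
}

#' Full metric report in one call
#' @param cm a \code{confusion_matrix}.
#' @return a \code{metrics_report}.
#' @export
metrics_report <- function(cm) {
  aggregate_metrics(class_metrics(cm), cm)
}

# ---- threshold-sweep curves --------------------------------------------

#' One-vs-rest ROC and precision-recall curves with trapezoid AUC
#'
#' For each class, scores for that class are swept over all observed
#' thresholds against the binary positive indicator; ROC AUC and PR curves
#' are computed by the trapezoid rule. A class absent from \code{actual} is
#' flagged \code{undefined}.
#'
#' @param actual label vector of length N.
#' @param scores N x K probability matrix, columns ordered as
#'   \code{class_names}; rows should lie on the simplex.
#' @param class_names ordered class labels.
#' @return list per class: \code{roc} (fpr, tpr), \code{pr}
#'   (recall, precision), \code{auc}, \code{pr_auc}, \code{undefined}.
#' @export
ovr_curves <- function(actual, scores, class_names = colnames(scores)) {
  actual <- as.character(actual)
  stopifnot(length(actual) == nrow(scores), length(class_names) == ncol(scores))
  out <- vector("list", length(class_names))
  names(out) <- class_names
  for (k in seq_along(class_names)) {
    pos <- actual == class_names[k]
    if (!any(pos)) {
      out[[k]] <- list(undefined = TRUE)
      next
    }
    s <- scores[, k]
    ord <- order(s, decreasing = TRUE)
    posn <- pos[ord]
    tps <- cumsum(posn)
    fps <- cumsum(!posn)
    # collapse ties: keep the last index of each run of equal scores
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tps[keep]) / sum(pos)
    fpr <- c(0, fps[keep]) / max(1L, sum(!pos))
    prec <- c(1, tps[keep] / (tps[keep] + fps[keep]))
    rec <- tpr
    out[[k]] <- list(
      roc = data.frame(fpr = fpr, tpr = tpr),
      pr = data.frame(recall = rec, precision = prec),
      auc = trapezoid(fpr, tpr),
      pr_auc = trapezoid(rec, prec),
      undefined = FALSE)
  }
  out
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' One-vs-rest Kolmogorov-Smirnov separability statistics
#'
#' Per class, the KS statistic is the maximum over thresholds of the gap
#' between the cumulative score distributions of positives and negatives
#' (equivalently, the maximum of TPR - FPR along the ROC curve).
#'
#' @inheritParams ovr_curves
#' @return list with per-class \code{ks} vector and \code{summary}
#'   (mean, max, min over defined classes).
#' @export
ks_one_vs_rest <- function(actual, scores, class_names = colnames(scores)) {
  curves <- ovr_curves(actual, scores, class_names)
  ks <- vapply(curves, function(cu) {
    if (isTRUE(cu$undefined)) return(NA_real_)
    max(cu$roc$tpr - cu$roc$fpr)
  }, numeric(1))
  ok <- !is.na(ks)
  list(ks = ks,
       summary = c(mean = mean(ks[ok]), max = max(ks[ok]), min = min(ks[ok])))
}

#' Bootstrap resampling of classification accuracy
#'
#' Resamples a binary correctness vector with replacement and reports the
#' bootstrap mean accuracy, the standard deviation of the bootstrap means
#' (the standard error), and the percentile 95% confidence interval
#' (2.5th / 97.5th percentiles).
#'
#' @param correct binary (0/1 or logical) vector, one entry per evaluated
#'   sample.
#' @param n_resamples number of bootstrap resamples (>= 1); the published
#'   protocol uses 10,000.
#' @param seed integer seed.
#' @return object of class \code{bootstrap_result} with fields
#'   \code{mean_accuracy}, \code{standard_error}, \code{ci_low},
#'   \code{ci_high}, \code{n_resamples}, \code{seed}.
#' @export
bootstrap_accuracy <- function(correct, n_resamples = 10000L, seed = 42L) {
  correct <- as.numeric(correct)
  if (length(correct) == 0L) stop("empty correctness vector", call. = FALSE)
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- length(correct)
  means <- vapply(seq_len(n_resamples), function(i)
    mean(correct[sample.int(n, n, replace = TRUE)]), numeric(1))
  ci <- unname(stats::quantile(means, c(0.025, 0.975)))
  structure(list(mean_accuracy = mean(means),
                 standard_error = stats::sd(means),
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed),
                 means = means),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap accuracy: %.4f +/- %.5f (SE), 95%% CI [%.4f, %.4f], %d resamples\n",
              x$mean_accuracy, x$standard_error, x$ci_low, x$ci_high,
              x$n_resamples))
  invisible(x)
}

#' Evaluate a fitted model on one manifest split
#'
#' @param fit an \code{msdam_fit}.
#' @param manifest a \code{split_manifest}.
#' @param split one of "train", "val", "test".
#' @param transform optional function applied to each raw [0, 1] image
#'   before normalization (used by the robustness protocol).
#' @return list with \code{actual}, \code{predicted}, \code{probs} (N x K),
#'   \code{accuracy}, \code{cm}.
#' @export
evaluate_split <- function(fit, manifest, split = "test", transform = NULL) {
  records <- manifest[[match.arg(split, c("train", "val", "test"))]]
  if (nrow(records) == 0L) stop("split is empty", call. = FALSE)
  cfg <- fit$config
  imgs <- lapply(records$path, function(p)
    resize_image(load_image(p), cfg$input_size, cfg$input_size))
  if (!is.null(transform)) imgs <- lapply(imgs, transform)
  batch <- stack_images(imgs)
  probs <- t(predict(fit, batch, type = "prob"))
  predicted <- factor(fit$class_names[max.col(probs, ties.method = "first")],
                      levels = fit$class_names)
  actual <- factor(records$class_label, levels = fit$class_names)
  cm <- build_confusion(actual, predicted, fit$class_names)
  list(actual = actual, predicted = predicted, probs = probs,
       accuracy = mean(actual == predicted), cm = cm)
}
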