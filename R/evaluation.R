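#' Confusion matrix of true versus predicted labels
#'
#' Rows are true classes, columns predicted classes, both in `class_order`
#' (the treatment enum order throughout the package).
#'
#' @param truth,predicted Equal-length label vectors; every label must appear
#'   in `class_order`.
#' @param class_order Class labels fixing the axes.
#' @return A `confusion_matrix`: integer K x K matrix with `class_order`
#'   dimnames.
#' @export
confusion_matrix <- function(truth, predicted, class_order) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    vs_abort("truth and predicted must have equal length",
             "valvespectra_label_error")
  }
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad)) {
    vs_abort(sprintf("labels not in class_order: %s", paste(bad, collapse = ", ")),
             "valvespectra_label_error")
  }
  counts <- table(factor(truth, levels = class_order),
                  factor(predicted, levels = class_order))
  m <- matrix(as.integer(counts), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Exact binomial confidence interval for a classification proportion
#'
#' Clopper-Pearson interval from beta quantiles (default), or Wilson's score
#' interval, reported in percent.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`.
#' @param level Confidence level, default 0.95.
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @return `c(low, high)` in percent.
#' @export
metric_ci <- function(successes, trials, level = 0.95,
                      method = c("clopper_pearson", "wilson")) {
  method <- match.arg(method)
  if (trials < 1 || successes < 0 || successes > trials) {
    vs_abort("need 0 <= successes <= trials with trials >= 1",
             "valvespectra_value_error")
  }
  a <- 1 - level
  if (method == "clopper_pearson") {
    low <- if (successes == 0) 0 else qbeta(a / 2, successes, trials - successes + 1)
    high <- if (successes == trials) 1 else
      qbeta(1 - a / 2, successes + 1, trials - successes)
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- successes / trials
    den <- 1 + z^2 / trials
    ctr <- (p + z^2 / (2 * trials)) / den
    hw <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
    low <- max(0, ctr - hw); high <- min(1, ctr + hw)
  }
  c(low = 100 * low, high = 100 * high)
}

#' Per-class performance metrics with confidence intervals
#'
#' One-vs-rest TP/TN/FP/FN for every class, then
#' sensitivity = TP/(TP+FN) x 100, specificity = TN/(TN+FP) x 100,
#' PPV = TP/(TP+FP) x 100 and NPV = TN/(TN+FN) x 100, each with a
#' [metric_ci()] confidence interval on its defining proportion. A zero
#' denominator makes the metric (and its CI) `NA` — flagged undefined, never
#' silently 0. Overall accuracy is trace/total.
#'
#' @param cm A [confusion_matrix()].
#' @param level Confidence level for the intervals.
#' @param ci_method Passed to [metric_ci()].
#' @return A `class_metrics` list: `per_class` tibble (class, TP, TN, FP, FN,
#'   the four metrics in percent with `_low`/`_high` CI bounds),
#'   `overall_accuracy` (percent), `accuracy_ci`, `total`.
#' @export
class_metrics <- function(cm, level = 0.95, ci_method = "clopper_pearson") {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total < 1) vs_abort("empty confusion matrix", "valvespectra_size_error")
  classes <- rownames(cm)
  rows <- lapply(seq_along(classes), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- total - TP - FN - FP
    met <- function(num, den) {
      if (den == 0) {
        c(NA_real_, NA_real_, NA_real_)
      } else {
        ci <- metric_ci(num, den, level = level, method = ci_method)
        unname(c(100 * num / den, ci[1], ci[2]))
      }
    }
    sens_m <- met(TP, TP + FN)
    spec_m <- met(TN, TN + FP)
    ppv_m <- met(TP, TP + FP)
    npv_m <- met(TN, TN + FN)
    tibble::tibble(class = classes[i],
                   TP = as.integer(TP), TN = as.integer(TN),
                   FP = as.integer(FP), FN = as.integer(FN),
                   sensitivity = sens_m[1], sensitivity_low = sens_m[2],
                   sensitivity_high = sens_m[3],
                   specificity = spec_m[1], specificity_low = spec_m[2],
                   specificity_high = spec_m[3],
                   ppv = ppv_m[1], ppv_low = ppv_m[2], ppv_high = ppv_m[3],
                   npv = npv_m[1], npv_low = npv_m[2], npv_high = npv_m[3])
  })
  acc_ci <- metric_ci(sum(diag(cm)), total, level = level, method = ci_method)
  structure(list(per_class = do.call(rbind, rows),
                 overall_accuracy = 100 * sum(diag(cm)) / total,
                 accuracy_ci = acc_ci,
                 total = as.integer(total)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> overall accuracy %.1f%% [%.1f, %.1f], n = %d\n",
              x$overall_accuracy, x$accuracy_ci[1], x$accuracy_ci[2], x$total))
  print(x$per_class)
  invisible(x)
}

#' Chord-diagram edge list from a confusion matrix
#'
#' One edge per nonzero cell, directed true -> predicted, weighted by the
#' count; the weights sum to the number of specimens. This is the data
#' product a chord-diagram renderer consumes.
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with columns `source`, `target`, `weight`.
#' @export
chord_export <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  idx <- which(cm > 0, arr.ind = TRUE)
  tb <- tibble::tibble(source = rownames(cm)[idx[, 1]],
                       target = colnames(cm)[idx[, 2]],
                       weight = as.integer(cm[idx]))
  tb[order(match(tb$source, rownames(cm)), match(tb$target, colnames(cm))), ]
}

#' Write per-class metrics and the confusion matrix as CSV
#'
#' Undefined metrics are rendered as `NA`, never as 0 or 100.
#'
#' @param metrics A [class_metrics()] result.
#' @param cm The corresponding [confusion_matrix()].
#' @param prefix Output path prefix; writes `<prefix>_confusion.csv`,
#'   `<prefix>_metrics.csv`, `<prefix>_chord.csv`.
#' @return Character vector of paths written, invisibly.
#' @export
write_evaluation_csv <- function(metrics, cm, prefix) {
  p1 <- paste0(prefix, "_confusion.csv")
  p2 <- paste0(prefix, "_metrics.csv")
  p3 <- paste0(prefix, "_chord.csv")
  write.csv(data.frame(true = rownames(cm), unclass(cm), check.names = FALSE),
            p1, row.names = FALSE)
  df <- as.data.frame(metrics$per_class)
  df$overall_accuracy <- metrics$overall_accuracy
  write.csv(df, p2, row.names = FALSE, na = "NA")
  write.csv(as.data.frame(chord_export(cm)), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
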