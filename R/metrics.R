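# Confusion-matrix metrics, macro/weighted averaging, fold aggregation and
# improvement deltas for the benign/malignant classification task.
# All metric values are reported in percent; display rounding is 3 decimals
# for table-style output and 2 decimals for improvement deltas, with the
# unrounded values always retained.

#' Confusion matrix
#'
#' 2x2 count table with rows = true class and columns = predicted class over
#' `{benign, malignant}`.
#'
#' @param y_true,y_pred character vectors of equal length with values in
#'   `{"benign", "malignant"}`.
#' @return Integer matrix of class `lwunet_confusion`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  lw_assert(length(y_true) == length(y_pred) && length(y_true) > 0,
            "y_true and y_pred must be non-empty and of equal length",
            class = "lwunet_input_error")
  lw_assert(all(c(y_true, y_pred) %in% LWUNET_LABELS),
            "labels must be 'benign' or 'malignant'",
            class = "lwunet_input_error")
  t <- table(factor(y_true, levels = LWUNET_LABELS),
             factor(y_pred, levels = LWUNET_LABELS))
  m <- matrix(as.integer(t), 2, 2, dimnames = list(true = LWUNET_LABELS,
                                                   predicted = LWUNET_LABELS))
  structure(m, class = c("lwunet_confusion", class(m)))
}

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest precision, recall and F1 per class, plus overall accuracy,
#' all in percent. When a denominator is zero the metric is reported as 0
#' with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return List with `per_class` (data frame: class, precision, recall, f1,
#'   support) and `accuracy`.
#' @export
class_metrics <- function(cm) {
  lw_assert(inherits(cm, "lwunet_confusion") ||
              (is.matrix(cm) && all(dim(cm) == 2)),
            "cm must be a 2x2 confusion matrix", class = "lwunet_input_error")
  total <- sum(cm)
  lw_assert(total > 0, "empty confusion matrix", class = "lwunet_input_error")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_len(2), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    precision <- 100 * safe_div(tp, tp + fp, "precision")
    recall <- 100 * safe_div(tp, tp + fn, "recall")
    f1 <- if (precision + recall == 0) {
      warning("zero denominator in f1; reporting 0", call. = FALSE)
      0
    } else 2 * precision * recall / (precision + recall)
    data.frame(class = LWUNET_LABELS[i], precision = precision,
               recall = recall, f1 = f1, support = sum(cm[i, ]),
               stringsAsFactors = FALSE)
  })
  list(per_class = do.call(rbind, rows),
       accuracy = 100 * sum(diag(cm)) / total)
}

#' Macro / weighted averaging of per-class metrics
#'
#' Weighted: `sum_i (n_i / N) * metric_i`; macro: unweighted mean. The two
#' coincide when supports are equal.
#'
#' @param values numeric per-class metric values.
#' @param supports per-class sample counts (>= 0, not all zero).
#' @param mode `"macro"` or `"weighted"`.
#' @return Scalar averaged metric.
#' @export
average_metrics <- function(values, supports, mode = c("macro", "weighted")) {
  mode <- match.arg(mode)
  lw_assert(length(values) == length(supports) && all(supports >= 0) &&
              sum(supports) > 0,
            "supports must be non-negative and not all zero",
            class = "lwunet_input_error")
  if (mode == "macro") mean(values) else sum(values * supports) / sum(supports)
}

#' Build a metrics report
#'
#' The per-fold reporting unit: per-class precision/recall/F1 with supports,
#' overall accuracy, and macro and weighted averages.
#'
#' @param cm a [confusion_matrix()].
#' @param fold fold identifier (or `NA`).
#' @return A `lwunet_metrics_report` list with elements `fold`, `per_class`
#'   (named per-class lists), `accuracy`, `macro`, `weighted`.
#' @export
metrics_report <- function(cm, fold = NA) {
  m <- class_metrics(cm)
  pc <- m$per_class
  avg <- function(mode) {
    list(precision = average_metrics(pc$precision, pc$support, mode),
         recall = average_metrics(pc$recall, pc$support, mode),
         f1 = average_metrics(pc$f1, pc$support, mode))
  }
  per_class <- lapply(seq_len(nrow(pc)), function(i) {
    list(precision = pc$precision[i], recall = pc$recall[i], f1 = pc$f1[i],
         support = pc$support[i])
  })
  names(per_class) <- pc$class
  structure(list(fold = fold, per_class = per_class, accuracy = m$accuracy,
                 macro = avg("macro"), weighted = avg("weighted")),
            class = "lwunet_metrics_report")
}

#' Metrics report from already-computed values
#'
#' Builds a report directly from per-class precision/recall/F1 percentages —
#' e.g. cells of a published fold-wise results table — so aggregation and
#' delta arithmetic can be exercised on printed values.
#'
#' @param fold fold identifier.
#' @param benign,malignant numeric `(precision, recall, f1)` in percent.
#' @param accuracy overall accuracy in percent.
#' @param support per-class support (default 1300 per class).
#' @return A `lwunet_metrics_report`.
#' @export
metrics_report_from_values <- function(fold, benign, malignant, accuracy,
                                       support = 1300) {
  as_cls <- function(v) list(precision = v[1], recall = v[2], f1 = v[3],
                             support = support)
  pc <- list(benign = as_cls(benign), malignant = as_cls(malignant))
  mk_avg <- function() {
    list(precision = mean(c(benign[1], malignant[1])),
         recall = mean(c(benign[2], malignant[2])),
         f1 = mean(c(benign[3], malignant[3])))
  }
  structure(list(fold = fold, per_class = pc, accuracy = accuracy,
                 macro = mk_avg(), weighted = mk_avg()),
            class = "lwunet_metrics_report")
}

#' Aggregate fold reports
#'
#' Arithmetic mean of every per-class metric across folds; the overall row is
#' the mean of the two per-class averages, and overall accuracy is the mean
#' of the fold accuracies. Values are unrounded; use [round()] at 3 decimals
#' for table-style display.
#'
#' @param reports list of `lwunet_metrics_report` with identical class sets.
#' @return A `lwunet_metrics_aggregate` list with `per_class`, `overall`,
#'   `accuracy`, `n_folds`, `fold_accuracies`.
#' @export
aggregate_folds <- function(reports) {
  lw_assert(length(reports) >= 1, "need at least one report",
            class = "lwunet_input_error")
  classes <- names(reports[[1]]$per_class)
  for (r in reports) {
    lw_assert(identical(names(r$per_class), classes),
              "inconsistent class sets across fold reports",
              class = "lwunet_input_error")
  }
  metric_names <- c("precision", "recall", "f1")
  per_class <- lapply(classes, function(cl) {
    out <- lapply(metric_names, function(mn) {
      mean(vapply(reports, function(r) r$per_class[[cl]][[mn]], 0))
    })
    names(out) <- metric_names
    out
  })
  names(per_class) <- classes
  overall <- lapply(metric_names, function(mn) {
    mean(vapply(classes, function(cl) per_class[[cl]][[mn]], 0))
  })
  names(overall) <- metric_names
  accs <- vapply(reports, function(r) r$accuracy, 0)
  structure(list(per_class = per_class, overall = overall,
                 accuracy = mean(accs), n_folds = length(reports),
                 fold_accuracies = accs),
            class = "lwunet_metrics_aggregate")
}

#' Improvement deltas between two aggregated results
#'
#' Per-metric differences `b - a` in percentage points (e.g. between a run on
#' real data alone and a run on augmented data), rounded to 2 decimals for
#' display with raw values retained.
#'
#' @param a,b `lwunet_metrics_aggregate` objects with matching class sets.
#' @return A `lwunet_improvement` list with `per_class`, `overall`,
#'   `accuracy` deltas (each `raw` and `rounded`).
#' @export
improvement_report <- function(a, b) {
  lw_assert(inherits(a, "lwunet_metrics_aggregate") &&
              inherits(b, "lwunet_metrics_aggregate"),
            "a and b must be aggregated metrics", class = "lwunet_input_error")
  lw_assert(identical(names(a$per_class), names(b$per_class)),
            "structure mismatch between reports", class = "lwunet_input_error")
  metric_names <- c("precision", "recall", "f1")
  d_block <- function(xa, xb) {
    raw <- vapply(metric_names, function(mn) xb[[mn]] - xa[[mn]], 0)
    list(raw = raw, rounded = round(raw, 2))
  }
  per_class <- lapply(names(a$per_class), function(cl) {
    d_block(a$per_class[[cl]], b$per_class[[cl]])
  })
  names(per_class) <- names(a$per_class)
  structure(list(per_class = per_class,
                 overall = d_block(a$overall, b$overall),
                 accuracy = list(raw = b$accuracy - a$accuracy,
                                 rounded = round(b$accuracy - a$accuracy, 2))),
            class = "lwunet_improvement")
}

#' Serialize a metrics report to JSON
#'
#' @param report a `lwunet_metrics_report` or `lwunet_metrics_aggregate`.
#' @param path output JSON file.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fold-metrics table
#'
#' Reads a CSV of per-fold metric cells (columns `fold`, `type` in
#' `{Benign, Malignant}` plus `precision`, `recall`, `f1`, `accuracy`) into a
#' list of [metrics_report_from_values()] reports ready for
#' [aggregate_folds()].
#'
#' @param path CSV file.
#' @param support per-class test support (default 1300).
#' @return List of `lwunet_metrics_report`.
#' @export
read_fold_table <- function(path, support = 1300) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(sort(unique(df$fold)), function(f) {
    b <- df[df$fold == f & df$type == "Benign", ]
    m <- df[df$fold == f & df$type == "Malignant", ]
    metrics_report_from_values(
      fold = f,
      benign = c(b$precision, b$recall, b$f1),
      malignant = c(m$precision, m$recall, m$f1),
      accuracy = b$accuracy, support = support)
  })
}
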