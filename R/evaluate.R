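## Evaluation: confusion-matrix metrics (accuracy, sensitivity,
## specificity, balanced accuracy, MCC) and paired significance
## testing between classifiers on a common test set. The positive
## class is "inhibitor" throughout.

#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth Equal-length binary label vectors using
#'   [cyp_labels()] values.
#' @param positive The positive class (default `"inhibitor"`).
#' @return A `confusion_matrix` (fields `tp`, `fn`, `tn`, `fp`).
#' @export
#' @examples
#' confusion(c("inhibitor", "non_inhibitor"), c("inhibitor", "inhibitor"))
confusion <- function(predicted, truth, positive = cyp_labels()[1]) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) abort("length mismatch.")
  lab_set <- unique(c(predicted, truth))
  if (length(lab_set) > 2L) {
    abort(sprintf("labels must be binary; got: %s", paste(lab_set, collapse = ", ")))
  }
  structure(
    list(
      tp = sum(predicted == positive & truth == positive),
      fn = sum(predicted != positive & truth == positive),
      tn = sum(predicted != positive & truth != positive),
      fp = sum(predicted == positive & truth != positive),
      positive = positive
    ),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers.")
  }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 positive = cyp_labels()[1]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: positive = %s>\n", x$positive))
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(truth = c("pos", "neg"),
                               predicted = c("pos", "neg"))))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, balanced accuracy = mean of sensitivity and
#' specificity, and the Matthews correlation coefficient by its
#' closed form. All values are reported on the percent scale
#' (MCC x 100, so perfect classification scores 100). When any MCC
#' marginal is zero the coefficient is defined as 0.
#'
#' @param cm A [confusion_matrix][confusion()] (both classes must be
#'   represented in the truth).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `mcc` (percent scale).
#' @export
#' @examples
#' metrics(confusion_counts(tp = 90, fn = 10, tn = 75, fp = 25))
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; tn <- cm$tn; fp <- cm$fp
  if (tp + fn == 0 || tn + fp == 0) {
    abort("both classes must be present in the truth labels.")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fn + tn + fp)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble::tibble(
    accuracy = 100 * acc,
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    balanced_accuracy = 100 * (sens + spec) / 2,
    mcc = 100 * mcc
  )
}

#' Evaluate a trained bundle on a labeled test set
#'
#' @param model A `cyp_model`.
#' @param matrix Descriptor tibble.
#' @param labels True labels aligned with `matrix` rows.
#' @return One-row metrics tibble (see [metrics()]).
#' @export
evaluate_model <- function(model, matrix, labels) {
  preds <- predict(model, matrix)
  metrics(confusion(preds$.pred_label, as.character(labels)))
}

#' Paired comparison of two classifiers on one test set
#'
#' Default method: exact McNemar test on the discordant pairs (cases
#' where exactly one classifier is correct), with two-sided binomial
#' p-value 2 * P(X <= min(b, c) | b + c, 1/2), capped at 1. A
#' two-proportion z-test (unpaired accuracy comparison) is available
#' for sensitivity analysis.
#'
#' @param preds_a,preds_b Predicted label vectors of the two models.
#' @param truth True labels.
#' @param method `"mcnemar"` (default, paired exact) or `"ztest"`.
#' @return One-row tibble: `b` (A correct only), `c` (B correct only),
#'   `statistic`, `p_value`, `method`.
#' @export
#' @examples
#' compare_classifiers(
#'   c("inhibitor", "inhibitor"), c("inhibitor", "non_inhibitor"),
#'   c("inhibitor", "inhibitor")
#' )
compare_classifiers <- function(preds_a, preds_b, truth,
                                method = c("mcnemar", "ztest")) {
  method <- match.arg(method)
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth)) {
    abort("length mismatch between predictions and truth.")
  }
  ok_a <- as.character(preds_a) == as.character(truth)
  ok_b <- as.character(preds_b) == as.character(truth)
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (method == "mcnemar") {
    n <- b + cc
    p <- if (n == 0) 1 else min(1, 2 * pbinom(min(b, cc), n, 0.5))
    stat <- min(b, cc)
  } else {
    p1 <- mean(ok_a); p2 <- mean(ok_b); n <- length(truth)
    pool <- (sum(ok_a) + sum(ok_b)) / (2 * n)
    se <- sqrt(pool * (1 - pool) * 2 / n)
    stat <- if (se == 0) 0 else (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(stat))
  }
  tibble::tibble(b = b, c = cc, statistic = stat, p_value = p, method = method)
}

#' Write a metrics report table
#'
#' Mirrors the standard report layout: one row per model / descriptor
#' set, columns Accuracy, Sensitivity, Specificity, MCC (percent, 2
#' decimals).
#'
#' @param reports Named list of one-row metrics tibbles.
#' @param path Output file (CSV).
#' @return The assembled tibble, invisibly.
#' @export
write_metrics_report <- function(reports, path) {
  tab <- purrr::imap(reports, function(m, nm) {
    dplyr::mutate(m, model = nm, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))
  readr::write_csv(tab, path)
  invisible(tab)
}
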