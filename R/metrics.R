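#' Peak signal-to-noise ratio
#'
#' `10 * log10((L - 1)^2 / MSE)` between a clean reference and a distorted
#' version, in dB. `L` is the number of representable intensity levels;
#' for real-valued ECG it defaults so that `L - 1` equals the dynamic
#' range (max minus min) of the reference. Identical signals give `Inf`.
#'
#' @param reference Clean signal.
#' @param test Distorted signal, same length.
#' @param L Number of intensity levels (> 1), or `NULL` for the
#'   dynamic-range default.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, L = NULL) {
  if (length(reference) != length(test)) {
    ecg_abort("reference and test signals must have equal length", "ecgkit_length_mismatch")
  }
  peak <- if (is.null(L)) {
    diff(range(reference))
  } else {
    if (L <= 1) ecg_abort("L must be > 1", "ecgkit_invalid_config")
    L - 1
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Confusion counts for binary labels
#'
#' Tallies true/false positives and negatives with class 1 (abnormal) as
#' the positive class.
#'
#' @param y_true,y_pred Equal-length vectors of 0/1 labels.
#' @return A list of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    ecg_abort("labels must be non-empty and of equal length", "ecgkit_length_mismatch")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    ecg_abort("labels must be binary 0/1", "ecgkit_invalid_input")
  }
  structure(
    list(
      TP = sum(y_true == 1 & y_pred == 1),
      FP = sum(y_true == 0 & y_pred == 1),
      TN = sum(y_true == 0 & y_pred == 0),
      FN = sum(y_true == 1 & y_pred == 0)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# 0/0 ratios surface as NA (undefined), never as silent zeros
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP + TN) / (TP + FP + FN + TN)`, sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, precision
#' `TP / (TP + FP)`, recall (identical to sensitivity) and
#' `F1 = 2 * precision * recall / (precision + recall)`. Ratios with a
#' zero denominator are reported as `NA` (undefined), not 0.
#'
#' @param counts A [confusion()] result.
#' @return One-row tibble with the metric columns.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0) ecg_abort("confusion counts are all zero", "ecgkit_invalid_input")
  sens <- safe_ratio(counts$TP, counts$TP + counts$FN)
  spec <- safe_ratio(counts$TN, counts$TN + counts$FP)
  prec <- safe_ratio(counts$TP, counts$TP + counts$FP)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble(
    accuracy = (counts$TP + counts$TN) / total,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    recall = sens,
    f1 = f1
  )
}

#' Mean binary cross-entropy
#'
#' @param y_true 0/1 labels.
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param eps Probability clamp to avoid infinite loss.
#' @return Mean negative log-likelihood.
#' @export
bce_loss <- function(y_true, scores, eps = 1e-7) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold across the unique scores (plus an
#' above-everything sentinel), computing the true-positive rate
#' `TP / (TP + FN)` and false-positive rate `FP / (FP + TN)` at each, and
#' integrates the area under the curve by the trapezoidal rule. Both rates
#' are non-decreasing as the threshold falls; the curve runs from (0, 0)
#' to (1, 1).
#'
#' @param y_true 0/1 labels with both classes present.
#' @param scores Real-valued scores (higher = more abnormal).
#' @return A list of class `ecg_roc` with `points` (tibble of `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    ecg_abort("labels and scores must have equal length", "ecgkit_length_mismatch")
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    ecg_abort("ROC needs both classes present", "ecgkit_single_class")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  # cumulative counts at each distinct score (ties collapse to one point)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last_of_tie]
  fp <- cumsum(y == 0)[last_of_tie]
  points <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "ecg_roc")
}

#' @export
print.ecg_roc <- function(x, ...) {
  cat(sprintf("<ecg_roc> %d threshold points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @rdname roc_curve
#' @param object An `ecg_roc` object.
#' @param ... Unused.
#' @export
autoplot.ecg_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Evaluate scored predictions against labels
#'
#' Thresholds scores at 0.5 to obtain hard labels, then reports the full
#' metric suite (confusion counts, accuracy, sensitivity, specificity,
#' precision, recall, F1, binary cross-entropy loss and AUC).
#'
#' @param y_true 0/1 labels.
#' @param scores Predicted probabilities.
#' @param threshold Decision threshold.
#' @return List of class `metrics_report` with `counts`, `metrics`
#'   (one-row tibble including `loss` and `auc`) and `roc`.
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5) {
  counts <- confusion(y_true, as.integer(scores >= threshold))
  metrics <- classification_metrics(counts)
  roc <- if (length(unique(y_true)) == 2L) roc_curve(y_true, scores) else NULL
  metrics$loss <- bce_loss(y_true, scores)
  metrics$auc <- if (is.null(roc)) NA_real_ else roc$auc
  structure(list(counts = counts, metrics = metrics, roc = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$counts)
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
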