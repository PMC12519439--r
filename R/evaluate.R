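#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Classification metrics and confusion matrix
#'
#' Accuracy, precision/recall/F1 with respect to a positive class, and
#' ROC-AUC by the trapezoidal rule over score thresholds, plus the 2x2
#' confusion matrix (rows = true, columns = predicted).
#'
#' @param y_true,y_pred Label vectors of equal length (two classes).
#' @param y_score Optional numeric scores for the positive class (needed
#'   for AUC).
#' @param positive Positive class name.
#' @return A `metrics` object: `accuracy`, `precision`, `recall`, `f1`,
#'   `roc_auc` (`NA` without scores), `positive`, `confusion` (2x2 matrix).
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL,
                            positive = levels(factor(y_true))[1]) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1) stop("need at least one observation", call. = FALSE)
  classes <- union(positive, unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(y_true, levels = classes)
  yp <- factor(y_pred, levels = classes)
  cm <- table(true = yt, predicted = yp)
  tp <- cm[positive, positive]
  fp <- sum(cm[, positive]) - tp
  fn <- sum(cm[positive, ]) - tp
  accuracy <- sum(diag(cm)) / sum(cm)
  if (tp + fp == 0) {
    warning("no positive predictions; precision reported as 0", call. = FALSE)
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  auc <- if (!is.null(y_score)) roc_auc(yt == positive, y_score) else NA_real_
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1_score(precision, recall), roc_auc = auc,
                 positive = positive, confusion = unclass(cm)),
            class = "metrics")
}

# Trapezoidal-rule area under the ROC curve.
roc_auc <- function(is_pos, score) {
  stopifnot(length(is_pos) == length(score))
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  P <- sum(is_pos); N <- sum(!is_pos)
  if (P == 0 || N == 0) return(NA_real_)
  tpr <- vapply(thr, function(t) sum(score >= t & is_pos) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !is_pos) / N, numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("<metrics (positive = %s): acc %.3f, P %.3f, R %.3f, F1 %.3f, AUC %s>\n",
              x$positive, x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$roc_auc)) "NA" else sprintf("%.3f", x$roc_auc)))
  print(x$confusion)
  invisible(x)
}

#' Normal-approximation confidence interval for an accuracy
#'
#' `acc +/- z * sqrt(acc (1 - acc) / n)`, clipped to `[0, 1]`.
#'
#' @param accuracy Point estimate in `[0, 1]`.
#' @param n Test-set size (>= 1).
#' @param level Confidence level (default 0.95).
#' @return An `interval_report`: `metric`, `point`, `lower`, `upper`,
#'   `level`, `method`.
#' @examples
#' accuracy_ci(0.92, 3000)  # lower endpoint 0.910 at 3 d.p.
#' @export
accuracy_ci <- function(accuracy, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (accuracy < 0 || accuracy > 1) stop("accuracy must lie in [0, 1]",
                                         call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(accuracy * (1 - accuracy) / n)
  structure(list(metric = "accuracy", point = accuracy,
                 lower = max(0, accuracy - half),
                 upper = min(1, accuracy + half),
                 level = level, method = "normal approximation"),
            class = "interval_report")
}

#' @export
print.interval_report <- function(x, ...) {
  cat(sprintf("<%s = %.3f, %g%% CI [%.3f, %.3f] (%s)>\n", x$metric, x$point,
              100 * x$level, x$lower, x$upper, x$method))
  invisible(x)
}

#' Exact binomial test against a chance baseline
#'
#' One-sided upper tail `P(X >= correct | n, chance)` — the probability that
#' a chance-rate classifier matches or beats the observed number of correct
#' predictions. Computed in log space so p-values far below double underflow
#' are still represented through `log10_p`.
#'
#' @param correct Number of correct predictions, `0 <= correct <= n`.
#' @param n Number of predictions.
#' @param chance Chance success rate in (0, 1); default 0.5 (two balanced
#'   classes).
#' @return A `baseline_test`: `p_value`, `log10_p`, `correct`, `n`, `chance`.
#' @export
random_baseline_test <- function(correct, n, chance = 0.5) {
  if (chance <= 0 || chance >= 1) stop("chance must lie in (0, 1)", call. = FALSE)
  if (correct < 0 || correct > n) stop("correct must lie in [0, n]", call. = FALSE)
  log_p <- stats::pbinom(correct - 1, n, chance, lower.tail = FALSE,
                         log.p = TRUE)
  structure(list(p_value = exp(log_p), log10_p = log_p / log(10),
                 correct = correct, n = n, chance = chance),
            class = "baseline_test")
}

#' @export
print.baseline_test <- function(x, ...) {
  cat(sprintf("<baseline test: %d/%d correct vs chance %.2f -> p = %.3g (log10 p = %.1f)>\n",
              x$correct, x$n, x$chance, x$p_value, x$log10_p))
  invisible(x)
}
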