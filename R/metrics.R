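# Discrimination and calibration metrics, implemented from first
# principles so every quantity reported by the evaluation harness is
# auditable against its textbook definition.

#' Confusion counts from labels and class predictions
#'
#' @param labels Binary 0/1 vector of true outcomes.
#' @param predictions Binary 0/1 vector of predicted classes.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop2("labels and predictions lengths differ")
  }
  structure(
    list(
      TP = sum(labels == 1 & predictions == 1),
      FP = sum(labels == 0 & predictions == 1),
      TN = sum(labels == 0 & predictions == 0),
      FN = sum(labels == 1 & predictions == 0)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`.
#' When any factor of the denominator is zero (e.g. all predictions in
#' one class) the coefficient is defined as 0 — a prediction no better
#' than random.
#'
#' @param c A `confusion_counts` object.
#' @return The MCC.
#' @export
mcc <- function(c) {
  with(c, {
    if (TP + FP + TN + FN == 0) stop2("empty confusion matrix")
    denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (denom == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  })
}

#' F1 score
#'
#' Harmonic mean of precision and recall; defined as 0 when there are no
#' true positives.
#'
#' @param c A `confusion_counts` object.
#' @return The F1 score in `[0, 1]`.
#' @export
f1 <- function(c) {
  with(c, {
    if (TP + FP + TN + FN == 0) stop2("empty confusion matrix")
    if (TP == 0) return(0)
    precision <- TP / (TP + FP)
    recall <- TP / (TP + FN)
    2 * precision * recall / (precision + recall)
  })
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive
#' scores above a random negative, with ties counted one half. Equals the
#' area under the ROC curve.
#'
#' @param probabilities Numeric scores.
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    stop2("probabilities and labels lengths differ")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop2("AUC requires both outcome classes in the labels")
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Expected calibration error with a reliability report
#'
#' Partitions `[0, 1]` into `n_bins` equal-width bins (right-closed
#' except the first, which includes 0). Per bin: confidence = mean
#' predicted probability, accuracy = observed event fraction. ECE is the
#' count-weighted mean absolute confidence-accuracy gap; empty bins
#' contribute 0. This is the event-probability (reliability-diagram)
#' formulation: accuracy is the fraction of events, not of correct class
#' predictions. Set `variant = "class"` for the predicted-class
#' confidence variant.
#'
#' @param probabilities Predicted event probabilities in `[0, 1]`.
#' @param labels Binary 0/1 outcomes.
#' @param n_bins Number of bins (>= 1). Default 10.
#' @param variant `"event"` (default) or `"class"`.
#' @return An object of class `calibration_report`: list with `ece`,
#'   `bins` (data.frame: lower, upper, count, confidence, accuracy), and
#'   `n_bins`.
#' @export
ece <- function(probabilities, labels, n_bins = 10L,
                variant = c("event", "class")) {
  variant <- match.arg(variant)
  if (n_bins < 1) stop2("n_bins must be at least 1")
  if (length(probabilities) != length(labels)) {
    stop2("probabilities and labels lengths differ")
  }
  n <- length(probabilities)
  if (variant == "class") {
    pred_class <- as.integer(probabilities >= 0.5)
    conf_val <- ifelse(pred_class == 1, probabilities, 1 - probabilities)
    acc_val <- as.numeric(pred_class == labels)
  } else {
    conf_val <- probabilities
    acc_val <- as.numeric(labels)
  }
  bin <- pmin(pmax(ceiling(probabilities * n_bins), 1L), n_bins)
  lower <- (seq_len(n_bins) - 1) / n_bins
  upper <- seq_len(n_bins) / n_bins
  count <- tabulate(bin, nbins = n_bins)
  confidence <- rep(NA_real_, n_bins)
  accuracy <- rep(NA_real_, n_bins)
  for (b in which(count > 0)) {
    confidence[b] <- mean(conf_val[bin == b])
    accuracy[b] <- mean(acc_val[bin == b])
  }
  gaps <- ifelse(count > 0, abs(accuracy - confidence), 0)
  structure(
    list(
      ece = sum(count / n * gaps, na.rm = TRUE),
      bins = data.frame(lower = lower, upper = upper, count = count,
                        confidence = confidence, accuracy = accuracy),
      n_bins = as.integer(n_bins), variant = variant
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> ECE = %.4f over %d bins (%s variant)\n",
              x$ece, x$n_bins, x$variant))
  invisible(x)
}

#' Two-sided paired t-test on per-iteration metrics
#'
#' Wraps `stats::t.test(paired = TRUE)`. Zero-variance difference vectors
#' (where the t statistic is undefined) are flagged rather than erroring:
#' if every difference is exactly 0 the comparison is an exact tie
#' (p = 1); a constant nonzero shift is flagged as degenerate with p = 0.
#'
#' @param metric_a,metric_b Equal-length (>= 2) paired metric vectors.
#' @return List with `t`, `p_value`, `mean_difference`,
#'   `zero_variance` flag.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop2("paired vectors differ in length")
  if (length(metric_a) < 2) stop2("need at least 2 pairs")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    tie <- all(d == 0)
    return(list(
      t = if (tie) 0 else sign(d[1]) * Inf,
      p_value = if (tie) 1 else 0,
      mean_difference = mean(d),
      zero_variance = TRUE
    ))
  }
  ht <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(
    t = unname(ht$statistic),
    p_value = ht$p.value,
    mean_difference = unname(ht$estimate),
    zero_variance = FALSE
  )
}

# Empirical ROC curve of one iteration as step-function points, then
# linearly interpolated TPR at the requested FPR grid.
roc_tpr_at <- function(probabilities, labels, fpr_grid) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop2("ROC requires both classes")
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  prob <- probabilities[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # collapse tied scores: keep the last point of each tie group
  keep <- c(prob[-1] != prob[-length(prob)], TRUE)
  fpr <- c(0, fp[keep] / n_neg)
  tpr <- c(0, tp[keep] / n_pos)
  # vertical steps share an FPR; keep the highest TPR at each FPR, then
  # evaluate the ROC staircase (step function) at the grid points
  last <- !duplicated(fpr, fromLast = TRUE)
  stats::approx(fpr[last], tpr[last], xout = fpr_grid, method = "constant",
                f = 0, rule = 2)$y
}

#' Vertically averaged ROC curve over repeated iterations
#'
#' Interpolates each iteration's empirical ROC onto a fixed grid of
#' false-positive rates (101 points by default) and reports the mean and
#' standard deviation of the true-positive rate at every grid point —
#' the standard vertical-averaging construction for repeated-split ROC
#' display.
#'
#' @param scores List of per-iteration probability vectors.
#' @param labels List of matching per-iteration 0/1 label vectors.
#' @param grid_points Number of FPR grid points. Default 101.
#' @return Data.frame with columns `fpr`, `tpr_mean`, `tpr_sd`.
#' @export
averaged_roc <- function(scores, labels, grid_points = 101L) {
  if (length(scores) == 0) stop2("need at least one iteration")
  if (length(scores) != length(labels)) {
    stop2("scores and labels lists differ in length")
  }
  fpr_grid <- seq(0, 1, length.out = grid_points)
  curves <- mapply(roc_tpr_at, scores, labels,
                   MoreArgs = list(fpr_grid = fpr_grid))
  curves <- matrix(curves, nrow = grid_points)
  data.frame(
    fpr = fpr_grid,
    tpr_mean = rowMeans(curves),
    tpr_sd = apply(curves, 1, function(x) {
      if (length(x) > 1) stats::sd(x) else 0
    })
  )
}
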