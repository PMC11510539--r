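# Evaluation metrics: precision, recall, F1, AUPR, AUC, accuracy.
#
# AUC uses the Mann-Whitney rank formulation (ties count 1/2); AUPR is the
# step integral of the precision-recall curve over distinct score thresholds
# (average-precision convention). Ratios with a zero denominator are reported
# as 0 and recorded in the `undefined` flag rather than returned as NaN.

#' Compute the six-metric report for binary scores
#'
#' @param labels Binary 0/1 vector.
#' @param scores Probability vector in [0, 1], same length.
#' @param threshold Decision threshold for precision/recall/F1/accuracy
#'   (score >= threshold predicts the positive class). Default 0.5.
#' @return An object of class `metrics_report`: list with `precision`,
#'   `recall`, `f1`, `aupr`, `auc`, `accuracy`, `threshold` and `undefined`
#'   (character vector naming any metric whose defining ratio had a zero
#'   denominator and was reported as 0).
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), length(labels) >= 1,
            all(labels %in% c(0L, 1L)),
            all(is.finite(scores)), all(scores >= 0), all(scores <= 1))
  undefined <- character(0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  accuracy <- mean(pred == labels)

  if (tp + fp > 0L) {
    precision <- tp / (tp + fp)
  } else {
    precision <- 0; undefined <- c(undefined, "precision")
  }
  if (tp + fn > 0L) {
    recall <- tp / (tp + fn)
  } else {
    recall <- 0; undefined <- c(undefined, "recall")
  }
  if (precision + recall > 0) {
    f1 <- 2 * precision * recall / (precision + recall)
  } else {
    f1 <- 0; undefined <- c(undefined, "f1")
  }

  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 > 0L && n0 > 0L) {
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    aupr <- .average_precision(labels, scores)
  } else {
    auc <- 0; aupr <- 0
    undefined <- c(undefined, "auc", "aupr")
  }

  structure(list(precision = precision, recall = recall, f1 = f1,
                 aupr = aupr, auc = auc, accuracy = accuracy,
                 threshold = threshold, undefined = undefined),
            class = "metrics_report")
}

# step-integrated PR curve over distinct thresholds, descending
.average_precision <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group ties: confusion counts change only between distinct score values
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp_cum <- cumsum(lab)[keep]
  n_cum <- seq_along(lab)[keep]
  n1 <- sum(lab)
  prec <- tp_cum / n_cum
  rec <- tp_cum / n1
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report @%.2f> Pre %.3f Rec %.3f F1 %.3f AUPR %.3f AUC %.3f Acc %.3f\n",
    x$threshold, x$precision, x$recall, x$f1, x$aupr, x$auc, x$accuracy))
  if (length(x$undefined) > 0) {
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

metrics_row <- function(report) {
  data.frame(Pre = report$precision, Rec = report$recall, F1 = report$f1,
             AUPR = report$aupr, AUC = report$auc, Acc = report$accuracy)
}

#' Write metrics reports as a TSV table
#'
#' Column order follows the ablation table convention:
#' Pre, Rec, F1, AUPR, AUC, Acc.
#'
#' @param reports A named list of `metrics_report` (names become the first
#'   column) or a single report.
#' @param path Output TSV path.
#' @export
write_metrics_tsv <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(model = reports)
  tab <- do.call(rbind, lapply(reports, metrics_row))
  tab <- cbind(data.frame(strategy = names(reports)), tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ROC and PR curve points for plotting
#'
#' @param labels,scores As in [compute_metrics()].
#' @return List of two data.frames: `roc` (fpr, tpr, threshold) and
#'   `pr` (recall, precision, threshold), one row per distinct score.
#' @export
curve_points <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(lab)[keep]
  fp <- (seq_along(lab) - cumsum(lab))[keep]
  n1 <- sum(lab); n0 <- length(lab) - n1
  list(
    roc = data.frame(fpr = fp / max(n0, 1L), tpr = tp / max(n1, 1L),
                     threshold = sc[keep]),
    pr = data.frame(recall = tp / max(n1, 1L), precision = tp / (tp + fp),
                    threshold = sc[keep])
  )
}
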