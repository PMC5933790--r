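#' ROC curve and AUC
#'
#' AUC is computed with the rank statistic (the normalised Mann-Whitney U,
#' midranks for ties), which equals trapezoidal integration of the ROC
#' curve; the ROC points themselves are returned for plotting.
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param truth character (or factor) truth labels.
#' @param positive the positive class. Default `"AIA"`.
#' @return list with `auc` and `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, truth, positive = "AIA") {
  truth <- as.character(truth)
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    validation_error("both classes must be present in the truth labels")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- !duplicated(scores[ord][seq_along(ord)], fromLast = TRUE)
  roc <- data.frame(threshold = c(Inf, scores[ord][keep]),
                    fpr = c(0, fp[keep] / n0),
                    tpr = c(0, tp[keep] / n1))
  list(auc = auc, roc = roc)
}

#' Per-class precision, recall and F1 with weighted averages
#'
#' Standard one-vs-rest definitions per class plus a support-weighted
#' average row. Undefined ratios (empty denominators) are reported as 0.
#'
#' @param predictions character vector of predicted labels.
#' @param truth character vector of true labels.
#' @param classes label set; defaults to the classes present in `truth`.
#' @return data.frame with rows per class plus `"weighted_avg"`, columns
#'   `class`, `precision`, `recall`, `f1`, `support`.
#' @export
classification_report <- function(predictions, truth, classes = NULL) {
  truth <- as.character(truth); predictions <- as.character(predictions)
  stopifnot(length(predictions) == length(truth))
  classes <- classes %||% sort(unique(truth))
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  rows <- lapply(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    prec <- safe_div(tp, sum(predictions == cl))
    rec <- safe_div(tp, sum(truth == cl))
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(truth == cl), stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  w <- rep$support / sum(rep$support)
  rbind(rep, data.frame(class = "weighted_avg",
                        precision = sum(w * rep$precision),
                        recall = sum(w * rep$recall),
                        f1 = sum(w * rep$f1),
                        support = sum(rep$support)))
}
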