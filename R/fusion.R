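#' Decision fusion with cross-validated reliability weights
#'
#' The three sensing groups' class scores (G1 physiological threshold
#' score, G2 participant-specific HMM posterior, G3 multi-occupancy HMM
#' posterior) are combined by reliability weighting: each group's
#' class-specific precision, estimated by stratified k-fold
#' cross-validation, is normalised over classes into reliability scores Rs,
#' and the fused class score is `sum_j Rs_ij * P_j(i)` with the argmax
#' class reported.
#'
#' @name fusion
NULL

#' Class-specific precision of a group's hard predictions
#'
#' `p_i = TP_i / (TP_i + FP_i)` per class, where the group's hard
#' prediction for a window is its argmax class. A class the group never
#' predicts gets precision 0 with a warning.
#'
#' @param predictions character vector of predicted class labels.
#' @param truth character vector of true labels.
#' @param classes class label set. Default `c("AIA", "normal")`.
#' @param quiet suppress the no-prediction warning (used inside
#'   cross-validation folds).
#' @return named numeric vector of per-class precisions.
#' @export
group_precision <- function(predictions, truth, classes = c("AIA", "normal"),
                            quiet = FALSE) {
  if (!length(predictions)) validation_error("empty predictions")
  stopifnot(length(predictions) == length(truth))
  p <- vapply(classes, function(cl) {
    pred_cl <- predictions == cl
    if (!any(pred_cl)) {
      if (!quiet) warning("no predictions for class ", cl, "; precision set to 0")
      return(0)
    }
    sum(pred_cl & truth == cl) / sum(pred_cl)
  }, numeric(1))
  p
}

#' Reliability scores from per-class precisions
#'
#' Normalises each group's class precisions over the classes:
#' `Rs_ij = p_ij / sum_i p_ij`. A group with all-zero precisions gets a
#' uniform column with a warning.
#'
#' @param precisions numeric matrix, classes x groups (a single group may
#'   be given as a vector).
#' @return matrix of the same shape with each column summing to 1, class
#'   `reliability_matrix`.
#' @export
reliability_scores <- function(precisions) {
  p <- as.matrix(precisions)
  cs <- colSums(p)
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero precisions for group(s) ",
            paste(colnames(p)[zero] %||% which(zero), collapse = ", "),
            "; uniform reliability assigned")
    p[, zero] <- 1
    cs[zero] <- nrow(p)
  }
  rs <- sweep(p, 2, cs, "/")
  class(rs) <- c("reliability_matrix", class(rs))
  rs
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled and dealt to folds round-robin.
stratified_folds <- function(truth, k, seed) {
  classes <- unique(truth)
  min_count <- min(table(truth))
  if (min_count < k) {
    warning("smallest class has ", min_count, " samples; reducing k from ",
            k, " to ", min_count)
    k <- min_count
  }
  folds <- integer(length(truth))
  with_seed(derive_seed(seed, 21L), {
    for (cl in classes) {
      idx <- sample(which(truth == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated reliability matrix
#'
#' Stratified k-fold estimation of each group's class-specific precision:
#' per fold, precisions are computed on the held-out fold (the group's hard
#' prediction being its argmax class, ties toward normal); fold precisions
#' are averaged and normalised into reliability scores.
#'
#' @param group_probs numeric matrix of P(AIA) per window (rows) and group
#'   (columns, named e.g. G1/G2/G3).
#' @param truth character vector of true labels per window.
#' @param k number of folds. Default 10 (reduced with a warning when the
#'   smaller class cannot populate every fold).
#' @param seed integer seed for the fold assignment.
#' @param classes class labels. Default `c("AIA", "normal")`.
#' @return `reliability_matrix` (classes x groups) with attributes
#'   `fold_precisions` and `k`.
#' @export
crossval_reliability <- function(group_probs, truth, k = 10, seed = 1,
                                 classes = c("AIA", "normal")) {
  gp <- as.matrix(group_probs)
  stopifnot(nrow(gp) == length(truth))
  if (length(unique(truth)) < 2)
    validation_error("both classes must be present")
  folds <- stratified_folds(truth, k, seed)
  k <- max(folds)
  hard <- ifelse(gp > 0.5, classes[1], classes[2])  # tie -> normal
  per_fold <- lapply(seq_len(k), function(f) {
    held <- folds == f
    vapply(seq_len(ncol(gp)), function(j)
      group_precision(hard[held, j], truth[held], classes, quiet = TRUE),
      numeric(length(classes)))
  })
  p_avg <- Reduce(`+`, per_fold) / k
  dimnames(p_avg) <- list(classes, colnames(gp))
  rs <- reliability_scores(p_avg)
  attr(rs, "fold_precisions") <- per_fold
  attr(rs, "k") <- k
  rs
}

#' Fuse group scores into a final class decision
#'
#' Fused score for class i is `sum_j Rs_ij * P_j(i)` over the available
#' groups; the label is the argmax class, ties broken toward "normal". A
#' missing group (NULL entry) is omitted and the remaining reliability
#' weights renormalised per class.
#'
#' @param scores named list (one entry per group, same order as the
#'   reliability columns) of named class-probability vectors, e.g.
#'   `list(G1 = c(AIA = .2, normal = .8), ...)`; NULL entries mark missing
#'   groups.
#' @param rs reliability matrix (classes x groups).
#' @return list with `class_scores` (named numeric), `label`, and
#'   `contributing` (names of the groups used).
#' @export
fuse <- function(scores, rs) {
  rs <- as.matrix(rs)
  groups <- colnames(rs) %||% names(scores)
  present <- !vapply(scores, is.null, logical(1))
  if (!any(present)) validation_error("no group scores available")
  if (!all(present))
    message("missing group(s) ", paste(groups[!present], collapse = ", "),
            "; weights renormalised over the rest")
  classes <- rownames(rs)
  w <- rs[, present, drop = FALSE]
  if (!all(present)) w <- w / rowSums(w)
  pm <- vapply(scores[present], function(s) {
    if (!is.null(names(s)) && all(classes %in% names(s))) s <- s[classes]
    as.numeric(s)
  }, numeric(length(classes)))
  pm <- matrix(pm, nrow = length(classes))
  class_scores <- rowSums(w * pm)
  names(class_scores) <- classes
  best <- max(class_scores)
  contenders <- classes[class_scores >= best - 1e-12]
  label <- if ("normal" %in% contenders) "normal" else contenders[1]
  list(class_scores = class_scores, label = label,
       contributing = groups[present])
}
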