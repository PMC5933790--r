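test_that("group precision is confusion-matrix arithmetic", {
  truth <- c("AIA", "AIA", "normal", "normal")
  expect_equal(unname(group_precision(truth, truth)), c(1, 1))
  expect_warning(
    p <- group_precision(rep("AIA", 4), truth),
    "no predictions")
  expect_equal(unname(p), c(0.5, 0))
  # order invariance
  set.seed(41)
  pred <- sample(c("AIA", "normal"), 30, replace = TRUE)
  tr <- sample(c("AIA", "normal"), 30, replace = TRUE)
  o <- sample(30)
  expect_equal(group_precision(pred, tr), group_precision(pred[o], tr[o]))
})

test_that("reliability scores normalise precisions over classes", {
  expect_equal(unname(reliability_scores(c(0.8, 0.2))[, 1]), c(0.8, 0.2))
  expect_equal(unname(reliability_scores(c(0.6, 0.6))[, 1]), c(0.5, 0.5))
  expect_equal(unname(reliability_scores(c(0.9, 0.3))[, 1]), c(0.75, 0.25))
  p <- cbind(G1 = c(0.9, 0.3), G2 = c(0, 0))
  expect_warning(rs <- reliability_scores(p), "all-zero")
  expect_equal(unname(rs[, "G2"]), c(0.5, 0.5))
  expect_equal(unname(colSums(rs)), c(1, 1), tolerance = 1e-12)
})

test_that("cross-validated reliability rewards the informative group", {
  set.seed(42)
  truth <- rep(c("AIA", "normal"), each = 30)
  # G2 always right; G3 right on normal days but predicts AIA at random
  probs <- cbind(
    G2 = ifelse(truth == "AIA", 0.9, 0.1),
    G3 = ifelse(truth == "AIA", 0.5 + 0.4 * rbinom(60, 1, 0.5), 0.3))
  rs <- crossval_reliability(probs, truth, k = 10, seed = 3)
  # both of G2's class precisions are 1, so its column is balanced
  expect_equal(unname(rs[, "G2"]), c(0.5, 0.5), tolerance = 1e-9)
  # G3's AIA precision (1 here: it only ever predicts AIA when true) and
  # its diluted normal precision shift its column weight toward AIA
  expect_gt(rs["AIA", "G3"], 0.5)

  # a group with zero precision for both classes falls back to uniform
  wrong <- cbind(G3 = ifelse(truth == "AIA", 0.1, 0.9))
  expect_warning(rsw <- crossval_reliability(wrong, truth, k = 10, seed = 3),
                 "all-zero")
  expect_equal(unname(rsw[, 1]), c(0.5, 0.5))

  # determinism under a fixed seed
  rs2 <- suppressWarnings(crossval_reliability(probs, truth, k = 10, seed = 3))
  expect_identical(unclass(rs), unclass(rs2))

  # k is reduced with a warning when a class cannot fill the folds
  small_truth <- c(rep("AIA", 3), rep("normal", 20))
  small_probs <- cbind(G2 = runif(23))
  expect_warning(rs3 <- crossval_reliability(small_probs, small_truth,
                                             k = 10, seed = 1),
                 "reducing k")
  expect_equal(attr(rs3, "k"), 3)
})

test_that("fusion is the reliability-weighted vote with normal tie-break", {
  rs <- reliability_scores(cbind(G1 = c(0.5, 0.5), G2 = c(0.5, 0.5),
                                 G3 = c(0.5, 0.5)))
  rownames(rs) <- c("AIA", "normal")
  # unanimity
  f <- fuse(list(G1 = c(AIA = 1, normal = 0), G2 = c(AIA = 1, normal = 0),
                 G3 = c(AIA = 1, normal = 0)), rs)
  expect_equal(f$label, "AIA")
  expect_equal(unname(f$class_scores["AIA"]), sum(rs["AIA", ]))

  # weighted-mean arithmetic: (0.6,0.4) vs two (0.4,0.6) -> normal
  f2 <- fuse(list(G1 = c(AIA = 0.6, normal = 0.4),
                  G2 = c(AIA = 0.4, normal = 0.6),
                  G3 = c(AIA = 0.4, normal = 0.6)), rs)
  expect_equal(f2$label, "normal")
  expect_equal(unname(f2$class_scores), c(0.7, 0.8), tolerance = 1e-12)

  # ties go to normal
  ftie <- fuse(list(G1 = c(AIA = 0.5, normal = 0.5),
                    G2 = c(AIA = 0.5, normal = 0.5),
                    G3 = c(AIA = 0.5, normal = 0.5)), rs)
  expect_equal(ftie$label, "normal")

  # missing group: weights renormalised over the remaining groups
  rs2 <- reliability_scores(cbind(G1 = c(0.9, 0.1), G2 = c(0.2, 0.8),
                                  G3 = c(0.5, 0.5)))
  rownames(rs2) <- c("AIA", "normal")
  expect_message(
    fm <- fuse(list(G1 = NULL, G2 = c(AIA = 0.7, normal = 0.3),
                    G3 = c(AIA = 0.2, normal = 0.8)), rs2),
    "missing group")
  w <- rs2[, c("G2", "G3")]
  w <- w / rowSums(w)
  expect_equal(unname(fm$class_scores["AIA"]),
               unname(w["AIA", "G2"] * 0.7 + w["AIA", "G3"] * 0.2),
               tolerance = 1e-12)

  # random instances match an independently computed weighted vote
  set.seed(43)
  for (i in 1:200) {
    p <- matrix(runif(6), 2, 3)
    rs_i <- reliability_scores(matrix(runif(6), 2, 3,
                                      dimnames = list(c("AIA", "normal"),
                                                      c("G1", "G2", "G3"))))
    f <- fuse(list(G1 = c(AIA = p[1, 1], normal = p[2, 1]),
                   G2 = c(AIA = p[1, 2], normal = p[2, 2]),
                   G3 = c(AIA = p[1, 3], normal = p[2, 3])), rs_i)
    manual <- as.numeric(rowSums(rs_i * p))
    expect_equal(unname(f$class_scores), manual, tolerance = 1e-12)
    expect_equal(f$label, c("AIA", "normal")[which.max(manual)])
  }
})

test_that("AUC equals the rank statistic and external references", {
  truth <- c(rep("AIA", 5), rep("normal", 5))
  perfect <- c(6:10, 1:5) / 10
  expect_equal(roc_auc(perfect, truth)$auc, 1)
  expect_equal(roc_auc(1 - perfect, truth)$auc, 0)

  set.seed(44)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    tr <- sample(c("AIA", "normal"), n, replace = TRUE,
                 prob = c(0.4, 0.6))
    if (length(unique(tr)) < 2) next
    sc <- round(runif(n), 2)  # rounding forces some ties
    expect_equal(roc_auc(sc, tr)$auc, oracle_auc(sc, tr), tolerance = 1e-12)
  }

  # label-independent scores hover near 1/2
  set.seed(45)
  aucs <- replicate(200, {
    tr <- rep(c("AIA", "normal"), each = 20)
    roc_auc(runif(40), tr)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  # agreement with an independent ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(46)
    tr <- sample(c("AIA", "normal"), 50, replace = TRUE)
    sc <- runif(50)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = tr, predictor = sc, levels = c("normal", "AIA"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(sc, tr)$auc, ref, tolerance = 1e-12)
  }

  expect_error(roc_auc(runif(5), rep("AIA", 5)), "both classes")
})

test_that("classification report computes standard per-class metrics", {
  truth <- rep(c("AIA", "normal"), each = 4)
  rep1 <- classification_report(truth, truth)
  expect_true(all(rep1$precision == 1 & rep1$recall == 1 & rep1$f1 == 1))

  # TP = 7, FP = 3, FN = 7 for the AIA class
  truth2 <- c(rep("AIA", 14), rep("normal", 6))
  pred2 <- c(rep("AIA", 7), rep("normal", 7), rep("AIA", 3), rep("normal", 3))
  r <- classification_report(pred2, truth2)
  aia <- r[r$class == "AIA", ]
  expect_equal(aia$precision, 0.7)
  expect_equal(aia$recall, 0.5)
  expect_equal(aia$f1, 2 * 0.7 * 0.5 / 1.2, tolerance = 1e-12)
  # harmonic mean sits between min and max of precision/recall
  expect_gte(aia$f1, min(aia$precision, aia$recall))
  expect_lte(aia$f1, max(aia$precision, aia$recall))
  # weighted average uses support weights
  w <- r$support[1:2] / sum(r$support[1:2])
  expect_equal(r$precision[r$class == "weighted_avg"],
               sum(w * r$precision[1:2]), tolerance = 1e-12)
})
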