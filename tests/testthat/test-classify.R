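test_that("one-vs-rest counts match the published worked example", {
  cms <- reference_confusions()
  ct <- onevsrest_counts(cms$DT, "BH")
  expect_equal(ct, c(TP = 9L, TN = 17L, FP = 1L, FN = 0L))
  # perfect classifier
  perfect <- diag(9L, 3)
  dimnames(perfect) <- dimnames(cms$DT)
  for (cl in rownames(perfect)) {
    ctp <- onevsrest_counts(perfect, cl)
    expect_equal(unname(ctp[c("FP", "FN")]), c(0L, 0L))
  }
  # counts always partition the cohort
  for (cm in cms) for (cl in rownames(cm)) {
    expect_equal(sum(onevsrest_counts(cm, cl)), sum(cm))
  }
})

test_that("metrics reproduce the published accuracy, specificity, F-scores", {
  cms <- reference_confusions()
  dt <- report_metrics(cms$DT, "DT")
  expect_equal(dt$accuracy, 25 / 27)
  expect_equal(dt$accuracy_pct, 92.59)
  bh <- dt$per_class[dt$per_class$class == "BH", ]
  expect_equal(bh$sensitivity, 1)                  # 100% sensitivity
  expect_equal(bh$specificity, 17 / 18)            # 94.44% specificity
  inr <- dt$per_class[dt$per_class$class == "IN", ]
  expect_equal(inr$fscore, 14 / 16)                # 87.50%

  # all nine published F-scores (percent, printed truncated to 2 decimals)
  published <- rbind(DT = c(94.73, 87.50, 94.73),
                     NN = c(72.72, 57.14, 100),
                     NB = c(94.73, 94.11, 100))
  for (clf in rownames(published)) {
    rep <- report_metrics(cms[[clf]], clf)
    got <- rep$per_class$fscore_pct[match(c("BH", "IN", "Ca"),
                                          rep$per_class$class)]
    expect_true(all(abs(got - published[clf, ]) <= 0.011),
                info = paste(clf, paste(got, collapse = " ")))
  }
  expect_error(report_metrics(matrix(0, 3, 3)), "nonempty")
})

test_that("rates stay in range on random confusion matrices", {
  set.seed(8)
  for (k in 1:50) {
    cm <- matrix(rpois(9, 4), 3, 3)
    if (sum(cm) == 0) next
    rep <- report_metrics(cm)
    expect_equal(rep$accuracy, sum(diag(cm)) / sum(cm))
    expect_true(all(rep$per_class$sensitivity >= 0 &
                      rep$per_class$sensitivity <= 1, na.rm = TRUE))
    expect_true(all(rep$per_class$specificity >= 0 &
                      rep$per_class$specificity <= 1, na.rm = TRUE))
  }
})

make_separable <- function(n_per_class = 9, p = 10, gap = 8, seed = 1) {
  set.seed(seed)
  labels <- rep(c("BH", "IN", "Ca"), each = n_per_class)
  shift <- (match(labels, c("BH", "IN", "Ca")) - 1) * gap
  x <- matrix(rnorm(length(labels) * p), length(labels), p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1:3] <- x[, 1:3] + shift
  list(x = x, labels = labels)
}

test_that("all three classifiers solve a linearly separable cohort", {
  d <- make_separable()
  for (clf in c("DT", "NB", "NN")) {
    rep <- loocv_run(d$x, d$labels, classifier = clf)
    expect_equal(rep$accuracy, 1, info = clf)
    expect_true(all(rep$auc == 1), info = clf)
  }
})

test_that("loocv is deterministic and validates inputs", {
  d <- make_separable(n_per_class = 4)
  r1 <- loocv_run(d$x, d$labels, classifier = "DT")
  r2 <- loocv_run(d$x, d$labels, classifier = "DT")
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$auc, r2$auc)
  expect_error(loocv_run(d$x, d$labels, classifier = "SVM"), "arg")
  expect_error(loocv_run(d$x, rep("BH", nrow(d$x))), "2 classes")
})

test_that("paper-mode (fit-once) selection also runs", {
  d <- make_separable(n_per_class = 5)
  rep <- loocv_run(d$x, d$labels, classifier = "NB", refit = FALSE)
  expect_equal(rep$accuracy, 1)
})

test_that("AUC is 1 for perfect ranking and 0.5 for constant scores", {
  labels <- factor(rep(c("BH", "IN"), each = 5), levels = c("BH", "IN"))
  scores <- cbind(BH = c(5:1, -(1:5)), IN = 0)
  auc <- celltex3d:::pairwise_auc(scores, labels)
  expect_equal(unname(auc["BH_vs_IN"]), 1)
  flat <- cbind(BH = rep(1, 10), IN = rep(1, 10))
  expect_equal(unname(celltex3d:::pairwise_auc(flat, labels)["BH_vs_IN"]),
               0.5)
})
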