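#' One-vs-rest counts for one class of a multiclass confusion matrix
#'
#' For class `c` of a confusion matrix with rows = true class and columns =
#' predicted class: TP is the diagonal entry, FN the rest of the row, FP the
#' rest of the column, and TN everything else (off-class samples not
#' predicted as `c`, including off-class samples confused among themselves).
#'
#' @param cm Square integer confusion matrix with matching row/column names.
#' @param class Class name or index.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @examples
#' cm <- matrix(c(9, 1, 0, 0, 7, 0, 0, 1, 9), 3, 3,
#'              dimnames = list(c("BH", "IN", "Ca"), c("BH", "IN", "Ca")))
#' onevsrest_counts(cm, "BH")
#' @export
onevsrest_counts <- function(cm, class) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  if (is.character(class)) class <- match(class, rownames(cm))
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Performance metrics of a multiclass confusion matrix
#'
#' Overall accuracy is `trace / total`. Per class (one-vs-rest):
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, F-score
#' `2 TP / (2 TP + FP + FN)`. Percentages are rounded to 2 decimals for
#' display; the raw fractions are kept alongside.
#'
#' @param cm Square confusion matrix, rows = true class, columns = predicted.
#' @param classifier Optional classifier id recorded in the report.
#' @return A list of class `"classifier_report"`: `confusion`,
#'   `accuracy` (fraction), `accuracy_pct`, `per_class` (data frame with both
#'   fraction and percentage columns), `classifier`, and `auc` (filled by
#'   [loocv_run()]).
#' @export
report_metrics <- function(cm, classifier = NA_character_) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("confusion matrix must be square and nonempty", call. = FALSE)
  }
  if (is.null(rownames(cm))) {
    rownames(cm) <- colnames(cm) <- paste0("class", seq_len(nrow(cm)))
  }
  acc <- sum(diag(cm)) / sum(cm)
  per <- do.call(rbind, lapply(rownames(cm), function(cl) {
    ct <- onevsrest_counts(cm, cl)
    data.frame(class = cl,
               sensitivity = unname(ct["TP"] / (ct["TP"] + ct["FN"])),
               specificity = unname(ct["TN"] / (ct["TN"] + ct["FP"])),
               fscore = unname(2 * ct["TP"] /
                                 (2 * ct["TP"] + ct["FP"] + ct["FN"])))
  }))
  per$sensitivity_pct <- round(100 * per$sensitivity, 2)
  per$specificity_pct <- round(100 * per$specificity, 2)
  per$fscore_pct <- round(100 * per$fscore, 2)
  structure(list(confusion = cm, accuracy = acc,
                 accuracy_pct = round(100 * acc, 2),
                 per_class = per, classifier = classifier, auc = NULL),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Classifier: %s  accuracy %.2f%%\n",
              x$classifier, x$accuracy_pct))
  print(x$confusion)
  print(x$per_class[, c("class", "sensitivity_pct", "specificity_pct",
                        "fscore_pct")], row.names = FALSE)
  if (!is.null(x$auc)) {
    cat("Pairwise AUC:\n")
    print(round(x$auc, 4))
  }
  invisible(x)
}

# Train one classifier and return held-out class probabilities/scores.
fit_predict <- function(classifier, train_x, train_y, test_x, nn_k = 1L) {
  lev <- levels(train_y)
  test_x <- as.matrix(test_x)
  if (classifier == "DT") {
    df <- data.frame(train_x)
    df$.y <- train_y
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                          maxcompete = 0, maxsurrogate = 0))
    prob <- predict(fit, data.frame(test_x), type = "prob")
    prob <- prob[, lev, drop = FALSE]
  } else if (classifier == "NB") {
    fit <- e1071::naiveBayes(train_x, train_y)
    prob <- predict(fit, test_x, type = "raw")[, lev, drop = FALSE]
  } else if (classifier == "NN") {
    # k-NN with a negative-distance score per class for ROC ranking
    prob <- t(apply(test_x, 1, function(r) {
      d <- sqrt(colSums((t(train_x) - r)^2))
      vapply(lev, function(cl) {
        dc <- sort(d[train_y == cl])
        -mean(head(dc, min(nn_k, length(dc))))
      }, numeric(1))
    }))
    colnames(prob) <- lev
  } else {
    stop("unknown classifier: ", classifier, call. = FALSE)
  }
  pred <- lev[max.col(prob, ties.method = "first")]
  list(pred = pred, scores = prob)
}

# Pairwise AUC (mid-rank tie handling via pROC) from per-sample class scores.
pairwise_auc <- function(scores, labels) {
  lev <- levels(labels)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    sel <- labels %in% pr
    resp <- factor(labels[sel], levels = pr)
    predictor <- scores[sel, pr[1]] - scores[sel, pr[2]]
    if (length(unique(predictor)) == 1) return(0.5)
    as.numeric(pROC::auc(pROC::roc(resp, predictor, levels = pr,
                                   direction = ">", quiet = TRUE)))
  })
  names(out) <- paste(pairs[1, ], pairs[2, ], sep = "_vs_")
  out
}

#' Leave-one-out cross-validated classification
#'
#' Each sample is predicted by a model trained on all others. By default the
#' whole feature preparation (z-score, ANOVA filter at `alpha`, PCA to
#' `variance_target`) is refit inside every fold on the training samples only
#' and then applied to the held-out sample, avoiding selection leakage;
#' `refit = FALSE` fits the preparation once on all samples, matching
#' protocols that select features before cross-validation. If no feature
#' passes the ANOVA cutoff in a fold, the `fallback_top` smallest-p features
#' are used with a warning.
#'
#' @param features Numeric feature matrix, rows = samples (e.g. from
#'   [assemble_group()]).
#' @param labels Class label per row, >= 2 samples per class.
#' @param classifier `"DT"` (CART, Gini splits), `"NB"` (Gaussian naive
#'   Bayes) or `"NN"` (k-nearest-neighbor, Euclidean, `nn_k = 1` default).
#' @param alpha ANOVA cutoff. Default 0.01.
#' @param variance_target PCA cumulative-variance target. Default 0.97.
#' @param max_components Optional cap on retained components.
#' @param refit Refit selection per fold (default `TRUE`).
#' @param nn_k Neighbors for `"NN"`.
#' @param fallback_top Features to keep when none is significant. Default 5.
#' @return A `"classifier_report"` (see [report_metrics()]) with `auc` set to
#'   the pairwise one-vs-one AUCs and `predictions` (held-out predicted
#'   label and class scores per sample).
#' @export
loocv_run <- function(features, labels,
                      classifier = c("DT", "NB", "NN"),
                      alpha = 0.01, variance_target = 0.97,
                      max_components = NULL, refit = TRUE, nn_k = 1L,
                      fallback_top = 5L) {
  classifier <- toupper(classifier)
  classifier <- match.arg(classifier, c("DT", "NB", "NN"))
  lev <- intersect(CELL_CLASSES, unique(labels))   # canonical class order
  lev <- c(lev, sort(setdiff(unique(labels), lev)))
  labels <- factor(labels, levels = lev)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need >= 2 classes with >= 2 samples each", call. = FALSE)
  }
  n <- nrow(features)
  if (n != length(labels)) stop("one label per row required", call. = FALSE)

  prepare <- function(train_idx) {
    zf <- suppressWarnings(zscore_fit(features[train_idx, , drop = FALSE]))
    tr <- zscore_apply(zf, features[train_idx, , drop = FALSE])
    sel <- anova_select(tr, labels[train_idx], alpha = alpha)
    keep <- sel$selected
    if (length(keep) < 1) {
      warning("no feature passed the ANOVA cutoff; using the ",
              fallback_top, " smallest p-values")
      keep <- names(sort(sel$pvalues))[seq_len(min(fallback_top,
                                                   length(sel$pvalues)))]
    }
    pca <- pca_reduce(tr[, keep, drop = FALSE],
                      variance_target = variance_target,
                      max_components = max_components)
    list(zf = zf, keep = keep, pca = pca,
         train_scores = pca$scores)
  }
  project <- function(prep, idx) {
    z <- zscore_apply(prep$zf, features[idx, , drop = FALSE])
    pca_project(prep$pca, z[, prep$keep, drop = FALSE])
  }

  prep_all <- if (!refit) prepare(seq_len(n)) else NULL
  preds <- character(n)
  scores <- matrix(NA_real_, n, nlevels(labels),
                   dimnames = list(rownames(features), levels(labels)))
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    if (nlevels(droplevels(labels[tr_idx])) < nlevels(labels)) {
      warning("fold ", i, ": a class is absent from training data")
    }
    prep <- if (refit) prepare(tr_idx) else prep_all
    tr_x <- if (refit) prep$train_scores else project(prep, tr_idx)
    te_x <- project(prep, i)
    fp <- fit_predict(classifier, tr_x, droplevels(labels[tr_idx]),
                      te_x, nn_k = nn_k)
    preds[i] <- fp$pred
    scores[i, colnames(fp$scores)] <- fp$scores
  }
  cm <- table(true = labels, pred = factor(preds, levels = levels(labels)))
  cm <- matrix(as.integer(cm), nlevels(labels), nlevels(labels),
               dimnames = list(levels(labels), levels(labels)))
  rep <- report_metrics(cm, classifier = classifier)
  rep$auc <- pairwise_auc(scores, labels)
  rep$predictions <- data.frame(true = labels, pred = preds, scores)
  rep
}
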