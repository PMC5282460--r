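#' Z-score standardization of a feature matrix
#'
#' Each feature is centered and scaled to unit standard deviation,
#' `r_n = (r - mean) / sigma`, with the sample SD (n - 1 denominator).
#' Zero-variance features carry no class information and would produce NaNs,
#' so they are dropped with a warning before scaling.
#'
#' @param x Numeric matrix, rows = samples (>= 2), columns = features.
#' @return The standardized matrix with attributes `center`, `scale` and
#'   `dropped` (names of removed constant features).
#' @export
zscore <- function(x) {
  fit <- zscore_fit(x)
  out <- zscore_apply(fit, x)
  attr(out, "center") <- fit$center
  attr(out, "scale") <- fit$scale
  attr(out, "dropped") <- fit$dropped
  out
}

zscore_fit <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) {
    stop("need a matrix with at least 2 rows", call. = FALSE)
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped before scaling")
  }
  list(center = ctr[keep], scale = scl[keep],
       keep = colnames(x)[keep] %||% which(keep),
       dropped = colnames(x)[!keep] %||% which(!keep))
}

zscore_apply <- function(fit, x) {
  x <- x[, fit$keep, drop = FALSE]
  sweep(sweep(x, 2, fit$center), 2, fit$scale, `/`)
}

#' ANOVA feature filter
#'
#' Tests every feature with a one-way fixed-effects ANOVA F-test across the
#' class labels and keeps those with `p < alpha` (strict). No
#' multiple-testing correction is applied by default, matching the raw
#' cutoff convention; `adjust = "BH"` switches to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param x Numeric feature matrix, rows = samples.
#' @param labels Class label per row; every class needs >= 2 samples.
#' @param alpha Significance cutoff. Default 0.01.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `"anova_selection"`: `selected` (column names),
#'   `pvalues`, `fstat`, `alpha`.
#' @export
anova_select <- function(x, labels, alpha = 0.01,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("every class needs >= 2 samples", call. = FALSE)
  }
  if (nrow(x) != length(labels)) {
    stop("one label per row required", call. = FALSE)
  }
  n <- nrow(x)
  k <- nlevels(labels)
  grand <- colMeans(x)
  ssb <- numeric(ncol(x))
  ssw <- numeric(ncol(x))
  for (g in levels(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    ssb <- ssb + nrow(xg) * (mg - grand)^2
    ssw <- ssw + colSums(sweep(xg, 2, mg)^2)
  }
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  # zero within-group variance with a between-group difference: infinitely
  # significant; with no difference at all: uninformative
  p[ssw == 0 & ssb > 0] <- 0
  p[ssw == 0 & ssb == 0] <- 1
  names(p) <- names(fstat) <- colnames(x)
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  structure(list(selected = colnames(x)[padj < alpha],
                 pvalues = p, fstat = fstat, alpha = alpha,
                 adjust = adjust),
            class = "anova_selection")
}

#' PCA reduction to a cumulative-variance target
#'
#' Principal components of the (already standardized) selected features;
#' retains the smallest number of components whose cumulative explained
#' variance reaches `variance_target` (97% by default, which on the original
#' 27-sample study compressed 158 significant features into 5 components).
#' Component signs are fixed so each retained loading vector's
#' largest-magnitude entry is positive.
#'
#' @param x Standardized feature matrix.
#' @param variance_target Cumulative explained-variance fraction in (0, 1].
#' @param max_components Optional cap on the retained components.
#' @return A list of class `"pca_reduction"`: `scores` (n x k), `loadings`,
#'   `center`, `cumvar`, `k`.
#' @export
pca_reduce <- function(x, variance_target = 0.97, max_components = NULL) {
  if (!is.numeric(variance_target) || variance_target <= 0 ||
      variance_target > 1) {
    stop("variance_target must be in (0, 1]", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= variance_target - 1e-12)[1]
  if (!is.null(max_components)) k <- min(k, max_components)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(c) {
    v <- load[, c]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(x, 2, pc$center) %*% load
  structure(list(scores = scores, loadings = load, center = pc$center,
                 cumvar = cumvar, k = k),
            class = "pca_reduction")
}

pca_project <- function(fit, x) {
  sweep(x, 2, fit$center) %*% fit$loadings
}

#' Class-blocked feature correlation
#'
#' Pearson correlation matrix of the features within each class block (the
#' heat-map utility for spotting redundant texture features between lesion
#' types). Constant features yield `NA` entries and are reported in the
#' `undefined` attribute rather than raising an error.
#'
#' @param x Feature matrix.
#' @param labels Class label per row (>= 3 samples overall).
#' @return Named list, one correlation matrix per class.
#' @export
feature_correlation <- function(x, labels) {
  if (nrow(x) < 3) stop("need >= 3 samples", call. = FALSE)
  labels <- factor(labels)
  out <- lapply(levels(labels), function(g) {
    block <- x[labels == g, , drop = FALSE]
    cc <- suppressWarnings(stats::cor(block))
    const <- colnames(block)[apply(block, 2, stats::sd) == 0]
    if (length(const)) attr(cc, "undefined") <- const
    cc
  })
  names(out) <- levels(labels)
  out
}
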