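haralick_names <- c(
  "f01_energy", "f02_entropy", "f03_correlation", "f04_contrast",
  "f05_homogeneity", "f06_variance", "f07_sum_mean", "f08_inertia",
  "f09_cluster_shade", "f10_cluster_tendency", "f11_max_prob", "f12_idm"
)

group_offsets <- list(G1 = 1L, G2 = 2L, G3 = 4L, G4 = 8L,
                      G5 = c(1L, 2L, 4L, 8L))

#' Twelve Haralick statistics of one co-occurrence matrix
#'
#' Computes, on the probability form `p(i, j)` with 1-based gray levels
#' `i, j = 1 ... Ng` and marginals `px`, `py` with means `mux`, `muy` and SDs
#' `sx`, `sy`:
#' energy `sum(p^2)`; entropy `-sum(p log p)` (natural log, `0 log 0 = 0`);
#' correlation `(sum(i j p) - mux muy) / (sx sy)`; contrast
#' `sum_n n^2 sum_{|i-j|=n} p`; homogeneity and inverse difference moment
#' `sum(p / (1 + (i - j)^2))`; variance
#' `sum((i - mux)^2 p + (j - muy)^2 p)`; sum-mean `sum_{n=2}^{2Ng} n
#' sum_{i+j=n} p`; inertia `sum((i - j)^2 p)`; cluster shade and tendency
#' `sum((i + j - mux - muy)^k p)` for k = 3, 2; maximum probability `max(p)`.
#' Contrast and inertia are the same quantity written two ways, as are
#' homogeneity and the inverse difference moment; both members of each pair
#' are reported to keep the conventional 12-feature layout.
#'
#' If a marginal is degenerate (`sx` or `sy` zero) the correlation is
#' returned as 0 and the result carries attribute `degenerate = TRUE`.
#'
#' @param P A `"glcm"` object (its probability form is used) or a numeric
#'   probability matrix summing to 1.
#' @return Named numeric vector of the 12 features.
#' @examples
#' features_from_glcm(diag(2) / 2)
#' @export
features_from_glcm <- function(P) {
  if (inherits(P, "glcm")) {
    if (P$n_pairs == 0) {
      stop("empty GLCM (no valid in-mask pairs): features are undefined",
           call. = FALSE)
    }
    P <- P$prob
  }
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("P must be a square matrix", call. = FALSE)
  }
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8) {
    stop("P must be in probability form (non-negative, summing to 1)",
         call. = FALSE)
  }
  ng <- nrow(P)
  lv <- seq_len(ng)
  i <- row(P)
  j <- col(P)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(lv * px)
  muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px))
  sy <- sqrt(sum((lv - muy)^2 * py))

  f1 <- sum(P^2)
  f2 <- -sum(P[P > 0] * log(P[P > 0]))
  degenerate <- sx == 0 || sy == 0
  f3 <- if (degenerate) 0 else (sum(i * j * P) - mux * muy) / (sx * sy)
  # contrast as the n-indexed sum over |i - j| = n
  adiff <- abs(i - j)
  f4 <- sum(vapply(0:(ng - 1),
                   function(n) n^2 * sum(P[adiff == n]), numeric(1)))
  f5 <- sum(P / (1 + (i - j)^2))
  f6 <- sum((i - mux)^2 * P + (j - muy)^2 * P)
  f7 <- sum((i + j) * P)
  f8 <- sum((i - j)^2 * P)
  f9 <- sum((i + j - mux - muy)^3 * P)
  f10 <- sum((i + j - mux - muy)^2 * P)
  f11 <- max(P)
  f12 <- sum(P / (1 + (i - j)^2))

  out <- c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12)
  names(out) <- haralick_names
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Assemble a grouped 3D texture feature matrix
#'
#' For each sample, one GLCM is computed per (offset, direction) with the 13
#' half-space directions of [directions_3d()] and the group's offsets
#' (G1 = \{1\}, G2 = \{2\}, G3 = \{4\}, G4 = \{8\}, G5 = \{1, 2, 4, 8\}),
#' then summarized by [features_from_glcm()]. Columns are laid out
#' offset-major, then direction, then the 12 features, named
#' `o<offset>_<direction>_<feature>`; G1-G4 have 12 x 13 = 156 columns and
#' G5 has 624.
#'
#' @param samples List where each element has `$quant` (a quantized volume
#'   from [equalize_to_levels()]) and `$mask` (logical matrix). Element names
#'   become row names.
#' @param group One of `"G1" ... "G5"`.
#' @param Ng Gray levels shared by all samples. Default 32.
#' @return Numeric matrix, rows = samples, with attribute `"group"`.
#' @export
assemble_group <- function(samples, group = "G5", Ng = 32L) {
  group <- match.arg(group, names(group_offsets))
  offsets <- group_offsets[[group]]
  dirs <- directions_3d()
  cols <- as.vector(outer(
    paste0(dirs$id, "_"), paste0("o", offsets, "_"),
    function(d, o) paste0(o, d)
  ))
  cols <- as.vector(vapply(cols, function(b) paste0(b, haralick_names),
                           character(12)))
  Ng <- as.integer(Ng)
  rows <- lapply(seq_along(samples), function(k) {
    s <- samples[[k]]
    quant <- s$quant
    if (is.matrix(quant)) dim(quant) <- c(dim(quant), 1L)
    storage.mode(quant) <- "integer"
    mask <- validate_mask(s$mask, quant)
    if (max(quant) >= Ng || min(quant) < 0) {
      stop("levels must lie in [0, Ng - 1]", call. = FALSE)
    }
    d <- dim(quant)
    vals <- numeric(length(cols))
    pos <- 0L
    for (off in offsets) {
      for (r in seq_len(nrow(dirs))) {
        counts <- .glcm_count_pairs(quant, mask, d[1], d[2], d[3],
                                    off * dirs$dx[r], off * dirs$dy[r],
                                    off * dirs$dz[r], Ng)
        n <- sum(counts)
        if (n == 0) {
          stop(sprintf(
            "sample %s: no valid pairs for direction %s at offset %d",
            names(samples)[k] %||% k, dirs$id[r], off), call. = FALSE)
        }
        vals[pos + seq_len(12L)] <- features_from_glcm(counts / n)
        pos <- pos + 12L
      }
    }
    vals
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(samples), cols)
  attr(m, "group") <- group
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class summary of the 12 texture functions
#'
#' Averages each of the 12 Haralick functions over all (direction, offset)
#' blocks of a G5 feature matrix within each sample, then reports the mean
#' and standard deviation per class — the texture profile that orders the
#' lesion classes (e.g. entropy rising from BH to Ca).
#'
#' @param features Feature matrix from [assemble_group()] (any group).
#' @param labels Class label per row.
#' @return Data frame: one row per feature function, `mean`/`sd` column pair
#'   per class.
#' @export
mean_feature_table <- function(features, labels) {
  if (length(labels) != nrow(features)) {
    stop("need one label per feature-matrix row", call. = FALSE)
  }
  lev <- intersect(CELL_CLASSES, unique(labels))
  labels <- factor(labels, levels = c(lev, sort(setdiff(unique(labels), lev))))
  nblock <- ncol(features) / 12L
  fidx <- rep(seq_len(12L), nblock)
  per_sample <- vapply(seq_len(12L), function(f) {
    rowMeans(features[, fidx == f, drop = FALSE])
  }, numeric(nrow(features)))
  out <- data.frame(feature = haralick_names)
  for (cl in levels(labels)) {
    block <- per_sample[labels == cl, , drop = FALSE]
    out[[paste0("mean_", cl)]] <- colMeans(block)
    out[[paste0("sd_", cl)]] <- apply(block, 2, stats::sd)
  }
  out
}
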