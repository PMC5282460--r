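#' @noRd
# Nearest-neighbor resample of a matrix to ny x nx.
resize_nn <- function(m, ny, nx) {
  yi <- pmin(floor((seq_len(ny) - 0.5) * nrow(m) / ny) + 1L, nrow(m))
  xi <- pmin(floor((seq_len(nx) - 0.5) * ncol(m) / nx) + 1L, ncol(m))
  m[yi, xi, drop = FALSE]
}

# Block-mean downscale when the source size is a multiple of the target,
# else nearest-neighbor.
resize_down <- function(m, n) {
  if (nrow(m) %% n == 0 && ncol(m) %% n == 0) {
    fy <- nrow(m) / n
    fx <- ncol(m) / n
    gy <- (seq_len(nrow(m)) - 1L) %/% fy
    gx <- (seq_len(ncol(m)) - 1L) %/% fx
    rs <- rowsum(m, gy)                     # sum rows within blocks
    cs <- t(rowsum(t(rs), gx)) / (fy * fx)  # then columns
    unname(cs)
  } else {
    resize_nn(m, n, n)
  }
}

# Chan-Vese two-region piecewise-constant level-set evolution on a matrix
# scaled to [0, 1]. Returns the final logical mask (phi > 0).
chan_vese <- function(img, max_iter = 200L, mu = 0.2, dt = 0.5,
                      eps = 1, tol = 1e-3, init_radius = 0.3) {
  n <- nrow(img)
  cx <- (ncol(img) + 1) / 2
  cy <- (n + 1) / 2
  xs <- matrix(seq_len(ncol(img)), n, ncol(img), byrow = TRUE)
  ys <- matrix(seq_len(n), n, ncol(img))
  phi <- init_radius * n - sqrt((xs - cx)^2 + (ys - cy)^2)

  shift <- function(m, dy, dx) {
    yi <- pmin(pmax(seq_len(nrow(m)) + dy, 1L), nrow(m))
    xi <- pmin(pmax(seq_len(ncol(m)) + dx, 1L), ncol(m))
    m[yi, xi]
  }
  for (it in seq_len(max_iter)) {
    inside <- phi > 0
    if (all(inside) || !any(inside)) break
    c1 <- mean(img[inside])
    c2 <- mean(img[!inside])
    # curvature of phi via central differences
    px <- (shift(phi, 0, 1) - shift(phi, 0, -1)) / 2
    py <- (shift(phi, 1, 0) - shift(phi, -1, 0)) / 2
    pxx <- shift(phi, 0, 1) - 2 * phi + shift(phi, 0, -1)
    pyy <- shift(phi, 1, 0) - 2 * phi + shift(phi, -1, 0)
    pxy <- (shift(shift(phi, 1, 0), 0, 1) - shift(shift(phi, 1, 0), 0, -1) -
            shift(shift(phi, -1, 0), 0, 1) +
            shift(shift(phi, -1, 0), 0, -1)) / 4
    grad2 <- px^2 + py^2
    kappa <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
      (grad2^1.5 + 1e-8)
    delta <- eps / (pi * (eps^2 + phi^2))
    force <- delta * (mu * kappa - (img - c1)^2 + (img - c2)^2)
    step <- dt * force / (max(abs(force)) + 1e-12)
    phi <- phi + step
    if (mean(abs(step)) < tol) break
  }
  phi > 0
}

#' Segment the cell in a multispectral volume
#'
#' Runs a region-based (Chan-Vese) active contour with a downscale/upscale
#' acceleration: the reference image (by default the mean across bands) is
#' mean-filtered, decreased to `work_size` x `work_size` pixels, the contour
#' is evolved there from a centered circular initialization, and the
#' resulting mask — not the image — is resized back to the original
#' resolution with nearest-neighbor interpolation. The largest connected
#' component is kept, standing in for the expert's selection among multiple
#' detected cells.
#'
#' @param volume Integer array `[y, x, z]`, 8-bit.
#' @param work_size Working resolution for the contour evolution (<= image
#'   size). Default 64.
#' @param max_iter Iteration cap; evolution also stops when the mean
#'   level-set change drops below `1e-3`. Default 200.
#' @param band_policy `"mean"` (default) segments once on the band-mean
#'   image; `"per_band"` segments every band and votes by majority.
#' @param kernel Mean-filter kernel applied before downscaling. Default 3.
#' @return Logical mask at the volume's spatial size (single connected
#'   component). Errors on a blank (zero-variance) reference image; if the
#'   contour finds no foreground, an error of class `"celltex3d_empty_result"`
#'   is raised so callers can distinguish it from success.
#' @export
segment_cell <- function(volume, work_size = 64L, max_iter = 200L,
                         band_policy = c("mean", "per_band"), kernel = 3L) {
  volume <- as_volume(volume)
  band_policy <- match.arg(band_policy)
  if (work_size > min(dim(volume)[1:2])) {
    stop("work_size must not exceed the image size", call. = FALSE)
  }
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)

  seg_one <- function(ref) {
    if (stats::sd(as.vector(ref)) == 0) {
      stop("reference image has zero variance: nothing to segment",
           call. = FALSE)
    }
    ref <- My %*% ref %*% t(Mx)  # mean filter the reference only
    small <- resize_down(ref, work_size)
    small <- (small - min(small)) / (max(small) - min(small))
    inside <- chan_vese(small, max_iter = max_iter)
    if (!any(inside)) return(matrix(FALSE, nrow(ref), ncol(ref)))
    # the contour marks the region around the initialization; if it drifted
    # to the background (brighter majority region), take the complement of
    # the dominant region touching the border
    if (mean(inside) > 0.5) inside <- !inside
    resize_nn(inside, nrow(ref), ncol(ref))
  }

  if (kernel > 1L) {
    box <- rep(1 / kernel, kernel)
    My <- smooth_matrix(dim(volume)[1], box)
    Mx <- smooth_matrix(dim(volume)[2], box)
  } else {
    My <- diag(dim(volume)[1])
    Mx <- diag(dim(volume)[2])
  }
  mask <- if (band_policy == "mean") {
    seg_one(rowMeans(volume, dims = 2))
  } else {
    votes <- Reduce(`+`, lapply(seq_len(dim(volume)[3]), function(b) {
      seg_one(volume[, , b]) * 1L
    }))
    votes > dim(volume)[3] / 2
  }
  if (!any(mask)) {
    stop(structure(class = c("celltex3d_empty_result", "error", "condition"),
                   list(message = "active contour found no foreground",
                        call = NULL)))
  }
  lab <- EBImage::bwlabel(mask)
  keep <- as.integer(names(which.max(table(lab[lab > 0]))))
  lab == keep
}

#' Segment a cohort and score against truth masks
#'
#' Applies [segment_cell()] to every sample and evaluates the predicted mask
#' against the sample's ground truth with [score_masks()].
#'
#' @param samples List of `labeled_sample` objects (each with `$volume` and
#'   `$truth_mask`).
#' @param ... Passed to [segment_cell()].
#' @return A list with `masks` (list of predicted masks), `scores` (data
#'   frame of per-sample jsc/dsc/fpr/fnr and label) and `summary` (the
#'   cohort means of the four metrics).
#' @export
segment_cohort <- function(samples, ...) {
  masks <- vector("list", length(samples))
  rows <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    masks[[k]] <- tryCatch(
      segment_cell(s$volume, ...),
      error = function(e) {
        stop(sprintf("segmentation failed for sample %s: %s",
                     names(samples)[k] %||% k, conditionMessage(e)),
             call. = FALSE)
      })
    sc <- score_masks(s$truth_mask, masks[[k]])
    rows[[k]] <- data.frame(sample_id = names(samples)[k] %||% k,
                            label = s$label, jsc = sc$jsc, dsc = sc$dsc,
                            fpr = sc$fpr, fnr = sc$fnr)
  }
  scores <- do.call(rbind, rows)
  list(masks = masks, scores = scores,
       summary = colMeans(scores[, c("jsc", "dsc", "fpr", "fnr")]))
}
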