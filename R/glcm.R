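#' Displacement direction sets for 2D and 3D co-occurrence
#'
#' `directions_2d()` returns the four classical in-plane unit directions
#' (0, 45, 90 and 135 degrees); the opposite four add nothing because
#' `P(d, theta) = t(P(d, theta + 180))`. `directions_3d()` returns the 13
#' unique half-space unit vectors of a voxel's 26-neighborhood (one of each
#' +/- pair), which together with its transposes cover all 26 neighbors.
#'
#' @return A data frame with columns `dx`, `dy`, `dz` (components in
#'   \{-1, 0, 1\}) and `id`.
#' @export
directions_2d <- function() {
  data.frame(dx = c(1L, 1L, 0L, -1L),
             dy = c(0L, 1L, 1L, 1L),
             dz = 0L,
             id = sprintf("d2_%02d", 1:4))
}

#' @rdname directions_2d
#' @export
directions_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  # canonical half-space: keep one of each antipodal pair
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  g <- g[keep, ]
  g <- g[order(g$dz, g$dy, g$dx), ]
  rownames(g) <- NULL
  g$id <- sprintf("d3_%02d", seq_len(nrow(g)))
  g
}

#' Masked gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(p, p + disp)` whose endpoints both lie inside
#' the volume and inside the cell mask (the mask is applied at every band),
#' tabulated by their quantized levels. Row `i`, column `j` of the table is
#' the number of pairs with level `i` at `p` and level `j` at `p + disp`
#' (1-based gray levels `1 ... Ng`). The probability form divides by the
#' total pair count and is what the Haralick statistics consume.
#'
#' @param quant Quantized volume from [equalize_to_levels()] (levels
#'   `0 ... Ng - 1`), or any integer array/matrix of levels.
#' @param mask Logical matrix matching the volume's spatial size.
#' @param disp Integer displacement `c(dx, dy, dz)`: columns, rows, bands.
#' @param Ng Number of gray levels; taken from `attr(quant, "Ng")` when
#'   present, else `max(quant) + 1`.
#' @return A list of class `"glcm"` with `counts` (integer Ng x Ng), `prob`
#'   (numeric, sums to 1), `n_pairs`, `disp` and `Ng`. When no valid pair
#'   exists `n_pairs` is 0 and `prob` is `NULL` (an "empty" GLCM; feature
#'   extraction refuses it).
#' @examples
#' q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
#' compute_glcm(q, matrix(TRUE, 2, 2), c(1, 0, 0), Ng = 2)$counts
#' @export
compute_glcm <- function(quant, mask, disp, Ng = NULL) {
  if (is.matrix(quant)) dim(quant) <- c(dim(quant), 1L)
  stopifnot(is.array(quant), length(dim(quant)) == 3L)
  storage.mode(quant) <- "integer"
  mask <- validate_mask(mask, quant)
  disp <- as.integer(round(disp))
  if (length(disp) != 3L || all(disp == 0L)) {
    stop("disp must be c(dx, dy, dz), not all zero", call. = FALSE)
  }
  d <- dim(quant)
  if (abs(disp[1]) >= d[2] || abs(disp[2]) >= d[1] || abs(disp[3]) >= d[3]) {
    stop(sprintf("displacement (%d, %d, %d) exceeds volume extent",
                 disp[1], disp[2], disp[3]), call. = FALSE)
  }
  if (is.null(Ng)) Ng <- attr(quant, "Ng")
  if (is.null(Ng)) Ng <- max(quant) + 1L
  Ng <- as.integer(Ng)
  if (max(quant) >= Ng || min(quant) < 0) {
    stop("levels must lie in [0, Ng - 1]", call. = FALSE)
  }
  counts <- .glcm_count_pairs(quant, mask, d[1], d[2], d[3],
                              disp[1], disp[2], disp[3], Ng)
  n <- sum(counts)
  structure(list(counts = counts,
                 prob = if (n > 0) counts / n else NULL,
                 n_pairs = n, disp = disp, Ng = Ng),
            class = "glcm")
}

#' How many co-occurrence matrices a geometry produces
#'
#' In 2D each slice contributes 4 directions per offset, so a stack of
#' `n_slices` slices analyzed slice-wise yields `n_slices * 4 * n_offsets`
#' GLCMs; the volumetric 3D treatment needs only `13 * n_offsets` regardless
#' of depth (e.g. 26 for two offsets, versus 80 for ten slices at two
#' offsets).
#'
#' @param n_slices Number of 2D slices (ignored in 3D mode).
#' @param n_offsets Number of offset magnitudes.
#' @param mode `"2d"` or `"3d"`.
#' @return Integer GLCM count.
#' @export
glcm_count <- function(n_slices, n_offsets, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  if (n_slices < 1 || n_offsets < 1) {
    stop("n_slices and n_offsets must be positive", call. = FALSE)
  }
  if (mode == "2d") as.integer(n_slices * 4L * n_offsets)
  else as.integer(13L * n_offsets)
}
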