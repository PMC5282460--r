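# One-dimensional smoothing as an n x n operator with edge replication:
# out-of-range taps are clamped to the border pixel, so row sums equal 1
# whenever `weights` does. Smoothing a matrix X along both axes is then
# M %*% X %*% t(M) (separable kernels only).
smooth_matrix <- function(n, weights) {
  r <- (length(weights) - 1L) / 2L
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in seq_along(weights)) {
    j <- pmin(pmax(idx + (k - 1L - r), 1L), n)
    M[cbind(idx, j)] <- M[cbind(idx, j)] + weights[k]
  }
  M
}

gauss_weights <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Mean (average) noise filter
#'
#' Replaces every pixel, per band, by the mean of its `kernel` x `kernel`
#' neighborhood (edge replication at borders), rounded to the nearest integer
#' and clipped to `[0, 255]`. Applied before segmentation to suppress
#' acquisition noise.
#'
#' @param volume Integer array `[y, x, z]` with 8-bit values (a matrix is
#'   treated as one band).
#' @param kernel Odd kernel side length; `1` is the identity. Default 3.
#' @return Filtered volume of the same dimensions.
#' @export
average_filter <- function(volume, kernel = 3L) {
  volume <- as_volume(volume)
  if (!is.numeric(kernel) || kernel < 1 || kernel %% 2 != 1) {
    stop("kernel must be a positive odd integer", call. = FALSE)
  }
  if (kernel == 1L) return(volume)
  box <- rep(1 / kernel, kernel)
  My <- smooth_matrix(dim(volume)[1], box)
  Mx <- smooth_matrix(dim(volume)[2], box)
  out <- volume
  for (b in seq_len(dim(volume)[3])) {
    sm <- My %*% volume[, , b] %*% t(Mx)
    out[, , b] <- as.integer(pmin(pmax(round(sm), 0), 255))
  }
  out
}

#' Histogram-equalize a segmented cell to Ng gray levels
#'
#' Quantizes the within-mask intensities to integer levels `0 ... Ng - 1` via
#' the empirical CDF: `level = floor(Ng * CDF(v))`, clipped to `Ng - 1`. By
#' default one CDF is pooled over all bands of the cell, so gray levels stay
#' comparable along the spectral axis for 3D pixel pairs; `scope =
#' "per_band"` equalizes each band independently. Pixels outside the mask are
#' assigned level 0 but are never paired into co-occurrence matrices (the
#' mask is enforced downstream). The mapping is monotone and, being
#' rank-based, invariant to strictly increasing intensity transforms.
#'
#' @param volume Integer array `[y, x, z]`, 8-bit.
#' @param mask Logical matrix matching the volume's spatial size; must select
#'   at least one pixel.
#' @param Ng Number of output gray levels (>= 2). Default 32.
#' @param scope `"pooled"` (one CDF across bands, default) or `"per_band"`.
#' @return Integer array of levels in `[0, Ng - 1]` with attribute `"Ng"`.
#' @export
equalize_to_levels <- function(volume, mask, Ng = 32L,
                               scope = c("pooled", "per_band")) {
  volume <- as_volume(volume)
  mask <- validate_mask(mask, volume)
  scope <- match.arg(scope)
  if (!is.numeric(Ng) || Ng < 2) stop("Ng must be >= 2", call. = FALSE)
  if (!any(mask)) stop("mask is empty: nothing to equalize", call. = FALSE)
  Ng <- as.integer(Ng)

  lut_from <- function(vals) {
    cdf <- cumsum(tabulate(vals + 1L, nbins = 256L)) / length(vals)
    pmin(as.integer(floor(Ng * cdf)), Ng - 1L)
  }
  out <- array(0L, dim = dim(volume))
  nb <- dim(volume)[3]
  if (scope == "pooled") {
    lut <- lut_from(volume[rep(mask, nb)])
    for (b in seq_len(nb)) {
      band <- array(0L, dim = dim(mask))
      band[mask] <- lut[volume[, , b][mask] + 1L]
      out[, , b] <- band
    }
  } else {
    for (b in seq_len(nb)) {
      lut <- lut_from(volume[, , b][mask])
      band <- array(0L, dim = dim(mask))
      band[mask] <- lut[volume[, , b][mask] + 1L]
      out[, , b] <- band
    }
  }
  attr(out, "Ng") <- Ng
  out
}
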