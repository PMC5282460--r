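#' Specify a synthetic multispectral cell phantom
#'
#' The generator emulates one abnormal-cell volume as acquired by a tunable
#' filter microscope: a roughly elliptical cell (a smooth random-star
#' polygon) on a bright smooth background, whose interior texture is a
#' band-correlated Gaussian random field. Texture heterogeneity is controlled
#' by two class-dependent knobs: the correlation length of the field (larger
#' is smoother; benign hyperplasia is the most homogeneous) and the contrast
#' amplitude (the within-cell intensity standard deviation in gray levels;
#' carcinoma is the most heterogeneous). Class defaults are
#' `correlation_length` (BH, IN, Ca) = (8, 4, 2) px and `contrast_amplitude`
#' = (20, 35, 50) gray levels, chosen so the population-level texture
#' ordering (entropy rising and energy falling from BH to Ca) mirrors what is
#' observed across the benign-to-malignant continuum.
#'
#' @param class_label One of `"BH"`, `"IN"`, `"Ca"`.
#' @param image_size Pixels per side (>= 16). Default 512.
#' @param n_bands Number of spectral bands (>= 1). Default 16.
#' @param correlation_length Gaussian-field correlation length in pixels;
#'   `NULL` uses the class default.
#' @param contrast_amplitude Within-cell intensity SD in gray levels; `NULL`
#'   uses the class default.
#' @param cell_radius_fraction Mean cell radius as a fraction of
#'   `image_size`, in (0, 0.5). Default 0.3.
#' @param jitter Relative between-sample variability of the two texture
#'   knobs (uniform, +/- `jitter`). Default 0.1.
#' @param seed Integer RNG seed; the same spec (including seed) always
#'   produces bit-identical output.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(class_label, image_size = 512L, n_bands = 16L,
                         correlation_length = NULL, contrast_amplitude = NULL,
                         cell_radius_fraction = 0.3, jitter = 0.1,
                         seed = 1L) {
  class_label <- match.arg(class_label, CELL_CLASSES)
  if (!is.numeric(n_bands) || n_bands < 1) {
    stop("n_bands must be >= 1", call. = FALSE)
  }
  if (!is.numeric(image_size) || image_size < 16) {
    stop("image_size must be >= 16", call. = FALSE)
  }
  if (!is.numeric(cell_radius_fraction) ||
      cell_radius_fraction <= 0 || cell_radius_fraction >= 0.5) {
    stop("cell_radius_fraction must be in (0, 0.5)", call. = FALSE)
  }
  if (!is.numeric(jitter) || jitter < 0 || jitter >= 1) {
    stop("jitter must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  defaults_len <- c(BH = 8, IN = 4, Ca = 2)
  defaults_amp <- c(BH = 20, IN = 35, Ca = 50)
  if (is.null(correlation_length)) {
    correlation_length <- unname(defaults_len[class_label])
  }
  if (is.null(contrast_amplitude)) {
    contrast_amplitude <- unname(defaults_amp[class_label])
  }
  if (correlation_length <= 0) {
    stop("correlation_length must be positive", call. = FALSE)
  }
  if (contrast_amplitude <= 0) {
    stop("contrast_amplitude must be positive", call. = FALSE)
  }
  structure(list(class_label = class_label,
                 image_size = as.integer(image_size),
                 n_bands = as.integer(n_bands),
                 correlation_length = correlation_length,
                 contrast_amplitude = contrast_amplitude,
                 cell_radius_fraction = cell_radius_fraction,
                 jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Zero-mean, unit-variance Gaussian random field with correlation length
# `len` px (Gaussian-smoothed white noise, renormalized). Smoothing uses the
# separable operator of smooth_matrix() for speed.
gaussian_field <- function(n, len, op = NULL) {
  x <- matrix(rnorm(n * n), n, n)
  if (len > 0.5) {
    if (is.null(op)) op <- smooth_matrix(n, gauss_weights(len))
    x <- op %*% x %*% t(op)
  }
  (x - mean(x)) / stats::sd(as.vector(x))
}

# Smooth star-shaped cell mask: radius(theta) = r0 * (1 + sum_k a_k cos(k
# theta + phi_k)), harmonics k = 2..5.
star_mask <- function(n, radius_fraction) {
  amp <- runif(4, -0.06, 0.06)
  phase <- runif(4, 0, 2 * pi)
  cx <- n / 2 + runif(1, -0.04, 0.04) * n
  cy <- n / 2 + runif(1, -0.04, 0.04) * n
  xs <- matrix(seq_len(n) - cx, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - cy, n, n)
  r <- sqrt(xs^2 + ys^2)
  theta <- atan2(ys, xs)
  rim <- radius_fraction * n *
    (1 + Reduce(`+`, lapply(1:4, function(k) {
      amp[k] * cos((k + 1) * theta + phase[k])
    })))
  r <= rim
}

#' Generate one labeled phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"labeled_sample"` with elements `volume` (integer
#'   array `[y, x, z]`, 8-bit), `truth_mask` (logical matrix) and `label`.
#' @examples
#' s <- generate_phantom(phantom_spec("BH", image_size = 64, n_bands = 4))
#' dim(s$volume)
#' mean(s$truth_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    spec <- do.call(phantom_spec, spec)
  }
  n <- spec$image_size
  nb <- spec$n_bands
  with_seed(spec$seed, {
    jit <- function(x) x * runif(1, 1 - spec$jitter, 1 + spec$jitter)
    len <- jit(spec$correlation_length)
    amp <- jit(spec$contrast_amplitude)
    mask <- star_mask(n, spec$cell_radius_fraction)

    # background: bright, smooth, with a mild brightness sweep along z
    bg <- 185 + 8 * gaussian_field(n, n / 8)

    # band-correlated texture: shared component + per-band component
    rho <- 0.6
    op <- smooth_matrix(n, gauss_weights(len))
    shared <- gaussian_field(n, len, op)
    vol <- array(0L, dim = c(n, n, nb))
    for (b in seq_len(nb)) {
      own <- gaussian_field(n, len, op)
      tex <- 100 + amp * (rho * shared + sqrt(1 - rho^2) * own)
      band <- ifelse(mask, tex, bg + (b - (nb + 1) / 2) * 0.5)
      vol[, , b] <- as.integer(pmin(pmax(round(band), 0), 255))
    }
    structure(list(volume = as_volume(vol), truth_mask = mask,
                   label = spec$class_label),
              class = "labeled_sample")
  })
}

#' Generate a balanced labeled cohort
#'
#' Produces `3 * n_per_class` phantoms, `n_per_class` per class, with
#' per-sample seeds derived deterministically as `base_seed + sample index`.
#' The default cohort (9 per class, 27 samples) mirrors a preliminary study
#' of 27 colorectal-cancer patients with nine volumes per lesion type.
#'
#' @param n_per_class Samples per class (>= 1). Default 9.
#' @param base_seed Integer seed for the whole cohort.
#' @param ... Further arguments forwarded to [phantom_spec()] (e.g.
#'   `image_size`, `n_bands`, `jitter`).
#' @return A list of `labeled_sample` objects with names `sample_01`, ...
#' @export
generate_cohort <- function(n_per_class = 9L, base_seed = 1L, ...) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("n_per_class must be >= 1", call. = FALSE)
  }
  labels <- rep(CELL_CLASSES, each = n_per_class)
  samples <- lapply(seq_along(labels), function(k) {
    generate_phantom(phantom_spec(labels[k], seed = base_seed + k, ...))
  })
  names(samples) <- sprintf("sample_%02d", seq_along(samples))
  samples
}

#' Write a cohort to disk with its manifest
#'
#' Volumes become multi-page TIFFs, truth masks single-page PNGs, and the
#' manifest a CSV (`sample_id`, `path_volume`, `path_mask`, `label`).
#'
#' @param cohort A list of `labeled_sample` objects from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly; the manifest file is
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(cohort)
  manifest <- data.frame(
    sample_id = ids,
    path_volume = paste0(ids, ".tif"),
    path_mask = paste0(ids, "_mask.png"),
    label = vapply(cohort, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(cohort)) {
    save_volume(cohort[[k]]$volume, file.path(dir, manifest$path_volume[k]))
    save_mask(cohort[[k]]$truth_mask, file.path(dir, manifest$path_mask[k]))
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
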