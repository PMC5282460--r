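#' Read and write multispectral volumes, cell masks and cohort manifests
#'
#' A multispectral volume is an integer array of dimension
#' `c(height, width, n_bands)` with 8-bit values in `[0, 255]`; on disk it is
#' a multi-page grayscale TIFF, one page per band, pages ordered by
#' increasing wavelength. A cell mask is a logical matrix of the same spatial
#' size; on disk it is a single-page PNG with 0 = outside, 255 = inside.
#'
#' @param path File path.
#' @return `load_volume()` returns an integer array `[y, x, z]`;
#'   `load_mask()` a logical matrix. The writers return `path` invisibly.
#' @examples
#' vol <- array(seq_len(4 * 4 * 2) %% 256L, dim = c(4, 4, 2))
#' f <- tempfile(fileext = ".tif")
#' save_volume(vol, f)
#' identical(load_volume(f), as_volume(vol))
#' @name imgio
NULL

#' Coerce and validate a multispectral volume
#'
#' @param x A numeric matrix (promoted to one band) or 3D array with values
#'   in `[0, 255]`.
#' @return An integer array of dimension `c(height, width, n_bands)`.
#' @export
as_volume <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("volume must be a matrix or 3D array [y, x, z]", call. = FALSE)
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop("volume values must be finite and within [0, 255]", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

validate_mask <- function(mask, volume = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("mask must be logical or 0/1", call. = FALSE)
    }
    mask <- mask > 0
  }
  if (!is.null(volume) && !identical(dim(mask), dim(volume)[1:2])) {
    stop("mask dimensions must match the volume's spatial dimensions",
         call. = FALSE)
  }
  mask
}

#' @rdname imgio
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF has no pages: ", path, call. = FALSE)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("TIFF pages have unequal sizes: ", path, call. = FALSE)
  }
  if (any(vapply(pages, function(p) length(dim(p)) > 2 && dim(p)[3] > 1,
                 logical(1)))) {
    stop("expected single-channel grayscale pages: ", path, call. = FALSE)
  }
  if (any(vapply(pages, max, numeric(1)) > 255)) {
    stop("expected 8-bit pages (values <= 255): ", path, call. = FALSE)
  }
  vol <- array(0L, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- as.integer(pages[[k]])
  as_volume(vol)
}

#' @param volume Integer array `[y, x, z]`, values 0-255.
#' @rdname imgio
#' @export
save_volume <- function(volume, path) {
  volume <- as_volume(volume)
  pages <- lapply(seq_len(dim(volume)[3]),
                  function(k) volume[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @param mask Logical matrix (`TRUE` = inside the cell).
#' @rdname imgio
#' @export
save_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname imgio
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  # grayscale PNGs load as [0, 1]; threshold at > 127 on the 8-bit scale
  round(img * 255) > 127
}

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with columns `sample_id`, `path_volume`,
#' `path_mask`, `label` linking each sample's volume and truth mask on disk
#' to its class label (BH, IN or Ca).
#'
#' @param manifest Data frame with the four columns above.
#' @param path CSV path. Relative `path_volume`/`path_mask` entries are
#'   resolved against the manifest's directory on read.
#' @return `read_manifest()` returns the data frame; `write_manifest()`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sample_id", "path_volume", "path_mask", "label")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  write.csv(manifest[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  for (col in c("path_volume", "path_mask")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}
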