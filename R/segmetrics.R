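#' Overlap metrics between a truth mask and a segmented mask
#'
#' With `A` the ground-truth region and `B` the segmented region:
#' \deqn{JSC = |A \cap B| / |A \cup B|, \quad DSC = 2|A \cap B| / (|A| + |B|),}
#' \deqn{FPR = |B \setminus A| / |A \cup B|, \quad FNR = |A \setminus B| / |A \cup B|.}
#' FPR and FNR quantify over- and under-segmentation normalized by the union,
#' so the identity `JSC = 1 - FPR - FNR` holds exactly.
#'
#' @param truth,pred Logical matrices of equal size; their union must be
#'   nonempty.
#' @return A list of class `"seg_score"` with elements `jsc`, `dsc`, `fpr`,
#'   `fnr`, all fractions in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[2:7, 2:7] <- TRUE
#' score_masks(a, a)  # perfect overlap
#' @export
score_masks <- function(truth, pred) {
  truth <- validate_mask(truth)
  pred <- validate_mask(pred)
  if (!identical(dim(truth), dim(pred))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  inter <- sum(truth & pred)
  uni <- sum(truth | pred)
  if (uni == 0) {
    stop("both masks are empty: overlap metrics are undefined",
         call. = FALSE)
  }
  structure(list(
    jsc = inter / uni,
    dsc = 2 * inter / (sum(truth) + sum(pred)),
    fpr = sum(pred & !truth) / uni,
    fnr = sum(truth & !pred) / uni
  ), class = "seg_score")
}

#' @export
print.seg_score <- function(x, ...) {
  cat(sprintf("JSC %.4f  DSC %.4f  FPR %.4f  FNR %.4f\n",
              x$jsc, x$dsc, x$fpr, x$fnr))
  invisible(x)
}
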