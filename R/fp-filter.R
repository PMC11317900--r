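#' Remove detections that do not overlap the receptacle mask
#'
#' Contact points occur only where florets meet the receptacle, so a detection
#' whose bounding box does not touch the segmented receptacle region is a
#' false positive. "Overlap" means at least one mask-true pixel centre lies
#' inside the half-open box: integer pixel (h, v) is inside iff
#' x_min <= h < x_max and y_min <= v < y_max. The split preserves the input
#' order and is idempotent.
#'
#' @param dets detection data.frame (see [detections()]); every row must carry
#'   the mask's `slice_id` (rows with `NA` slice_id are accepted when the mask
#'   id is `NA`).
#' @param mask a `mask_image` for the same slice.
#' @return list with data.frames `kept` and `removed` (disjoint, order
#'   preserved, union = `dets`).
#' @export
filter_detections <- function(dets, mask) {
  stopifnot(inherits(mask, "mask_image"))
  if (nrow(dets) > 0 && !is.null(dets$slice_id)) {
    same <- ifelse(is.na(dets$slice_id) & is.na(mask$slice_id), TRUE,
                   dets$slice_id == mask$slice_id)
    if (!all(same, na.rm = FALSE) || anyNA(same))
      stop("detections and mask have mismatched slice_id")
  }
  if (nrow(dets) == 0) return(list(kept = dets, removed = dets))
  on_idx <- which(mask$pixels, arr.ind = TRUE)
  hs <- on_idx[, 1] - 1  # 0-based pixel-centre coordinates
  vs <- on_idx[, 2] - 1
  keep <- vapply(seq_len(nrow(dets)), function(i) {
    if (length(hs) == 0) return(FALSE)
    any(hs >= dets$x_min[i] & hs < dets$x_max[i] &
        vs >= dets$y_min[i] & vs < dets$y_max[i])
  }, logical(1))
  list(kept = dets[keep, , drop = FALSE], removed = dets[!keep, , drop = FALSE])
}
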