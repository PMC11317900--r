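#' Axis-aligned bounding box
#'
#' Boxes are half-open in continuous pixel coordinates:
#' [x_min, x_max) x [y_min, y_max). The half-open convention makes areas and
#' intersections exact with no +/-1 ambiguity, and agrees with pixel-set
#' counting for integer-aligned boxes (a pixel belongs to the box iff its
#' centre does).
#'
#' @param x_min,y_min,x_max,y_max continuous coordinates; the box must have
#'   positive area.
#' @return an object of class `bbox` (named numeric vector).
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (!(x_max > x_min && y_max > y_min))
    stop("degenerate box: need x_max > x_min and y_max > y_min")
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bbox")
}

#' Per-slice binary mask
#'
#' A boolean grid aligned with a slice image: `pixels[i, j]` covers the pixel
#' centred at (h, v) = (i-1, j-1).
#'
#' @param pixels logical matrix (width x height).
#' @param theta_deg azimuth of the paired slice.
#' @param slice_id identifier shared with the paired slice/detections.
#' @return an object of class `mask_image`.
#' @export
mask_image <- function(pixels, theta_deg = NA_real_, slice_id = NA_character_) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, theta_deg = theta_deg,
                 slice_id = as.character(slice_id)),
            class = "mask_image")
}

#' Detection table constructor/validator
#'
#' Detections live in a plain data.frame with one row per detection:
#' `slice_id`, `theta_deg`, `x_min`, `y_min`, `x_max`, `y_max`, `confidence`.
#' Box coordinates follow the [bbox()] half-open convention; `x` is the slice
#' column h and `y` the row v.
#'
#' @param slice_id,theta_deg,x_min,y_min,x_max,y_max,confidence vectors,
#'   recycled to a common length.
#' @return a data.frame with the columns above.
#' @export
detections <- function(slice_id = character(), theta_deg = numeric(),
                       x_min = numeric(), y_min = numeric(),
                       x_max = numeric(), y_max = numeric(),
                       confidence = numeric()) {
  d <- data.frame(slice_id = as.character(slice_id), theta_deg = theta_deg,
                  x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                  confidence = confidence, stringsAsFactors = FALSE)
  if (nrow(d)) {
    if (any(d$x_max <= d$x_min | d$y_max <= d$y_min))
      stop("degenerate boxes in detection table")
    if (any(d$confidence < 0 | d$confidence > 1))
      stop("confidence must lie in [0, 1]")
  }
  d
}

#' Intersection over union
#'
#' IoU(P, G) = |P n G| / |P u G|, in [0, 1]; 0 when disjoint. For boxes the
#' areas are computed in closed form on the continuous half-open rectangles;
#' for masks by pixel counting. Both arguments must be the same kind (and, for
#' masks, the same dimensions).
#'
#' @param a,b two `bbox` objects or two `mask_image` objects.
#' @return scalar IoU.
#' @export
iou <- function(a, b) UseMethod("iou")

#' @export
iou.bbox <- function(a, b) {
  stopifnot(inherits(b, "bbox"))
  iw <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  ih <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- (a["x_max"] - a["x_min"]) * (a["y_max"] - a["y_min"])
  area_b <- (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"])
  unname(inter / (area_a + area_b - inter))
}

#' @export
iou.mask_image <- function(a, b) {
  stopifnot(inherits(b, "mask_image"), identical(dim(a$pixels), dim(b$pixels)))
  if (!any(a$pixels) && !any(b$pixels)) stop("both regions are empty")
  sum(a$pixels & b$pixels) / sum(a$pixels | b$pixels)
}

# IoU between one detection row and each row of a ground-truth box table
.row_iou <- function(det, gts) {
  iw <- pmin(det$x_max, gts$x_max) - pmax(det$x_min, gts$x_min)
  ih <- pmin(det$y_max, gts$y_max) - pmax(det$y_min, gts$y_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  aa <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  ab <- (gts$x_max - gts$x_min) * (gts$y_max - gts$y_min)
  inter / (aa + ab - inter)
}

#' Greedy matching of ranked detections against ground truth
#'
#' Detections are processed in descending confidence order (ties keep input
#' order); each is matched to the unmatched ground-truth box of the same
#' `slice_id` with the highest IoU, and labelled a true positive iff that IoU
#' is strictly greater than `iou_thresh`. Each ground truth is consumed at
#' most once. When either table lacks a `slice_id` column all boxes are
#' treated as one image.
#'
#' @param dets detection data.frame (see [detections()]).
#' @param gts ground-truth data.frame with the same box columns.
#' @param iou_thresh IoU threshold (strict inequality).
#' @return `dets` sorted in rank order, with logical column `tp` appended.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  if (nrow(dets) == 0) { dets$tp <- logical(0); return(dets) }
  ord <- order(-dets$confidence)  # stable: ties keep input order
  dets <- dets[ord, , drop = FALSE]
  same_image <- is.null(dets$slice_id) || is.null(gts$slice_id)
  gt_used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- if (same_image) !gt_used else !gt_used & gts$slice_id == dets$slice_id[i]
    if (!any(cand)) next
    idx <- which(cand)
    ious <- .row_iou(dets[i, ], gts[idx, , drop = FALSE])
    j <- idx[which.max(ious)]
    if (max(ious) > iou_thresh) {   # strict: IoU must exceed the threshold
      tp[i] <- TRUE
      gt_used[j] <- TRUE
    }
  }
  dets$tp <- tp
  rownames(dets) <- NULL
  dets
}

#' Cumulative precision-recall curve of a ranked TP/FP sequence
#'
#' @param tp logical vector of per-detection labels in rank order.
#' @param n_gt number of ground-truth objects (>= 1).
#' @return an object of class `pr_curve`: data.frame with `precision` (in
#'   [0, 1]) and non-decreasing `recall`, one row per ranked detection.
#' @export
pr_curve <- function(tp, n_gt) {
  stopifnot(n_gt >= 1)
  k <- seq_along(tp)
  ctp <- cumsum(tp)
  structure(data.frame(precision = ctp / k, recall = ctp / n_gt),
            class = c("pr_curve", "data.frame"))
}

#' COCO-style average precision (101-point interpolation)
#'
#' Builds the cumulative precision-recall curve from the ranked TP/FP labels,
#' interpolates precision at recall r as the maximum precision attained at any
#' recall >= r, and averages over the 101 recall points 0.00, 0.01, ..., 1.00.
#'
#' @param tp logical vector of per-detection labels, in descending-confidence
#'   rank order.
#' @param n_gt number of ground-truth objects (>= 1).
#' @return scalar AP in [0, 1].
#' @export
average_precision <- function(tp, n_gt) {
  stopifnot(n_gt >= 1)
  if (length(tp) == 0) return(0)
  pr <- pr_curve(tp, n_gt)
  rpts <- seq(0, 1, by = 0.01)
  # running max of precision from the tail gives the interpolated envelope
  penv <- rev(cummax(rev(pr$precision)))
  interp <- vapply(rpts, function(r) {
    ok <- pr$recall >= r - 1e-12
    if (any(ok)) max(penv[ok]) else 0
  }, numeric(1))
  mean(interp)
}

#' AP50, AP75 and AP(0.5:0.95) for a detection set
#'
#' AP50 and AP75 are the average precision at IoU thresholds 0.5 and 0.75;
#' AP(0.5:0.95) is the mean AP over thresholds 0.50, 0.55, ..., 0.95
#' (10 values). Detections are ranked by confidence pooled across slices.
#'
#' @param dets detection data.frame.
#' @param gts ground-truth box data.frame.
#' @return named list with `AP50`, `AP75` and `AP_50_95`.
#' @export
ap_suite <- function(dets, gts) {
  ap_at <- function(thr) {
    m <- match_detections(dets, gts, thr)
    average_precision(m$tp, nrow(gts))
  }
  list(AP50 = ap_at(0.5), AP75 = ap_at(0.75),
       AP_50_95 = mean(vapply(seq(0.5, 0.95, by = 0.05), ap_at, numeric(1))))
}

#' Dice similarity coefficient of two masks
#'
#' DSC(P, G) = 2|P n G| / (|P| + |G|), in [0, 1]. Related to IoU by
#' DSC = 2 IoU / (1 + IoU).
#'
#' @param p,g `mask_image` objects of the same dimensions.
#' @return scalar Dice coefficient.
#' @export
dice <- function(p, g) {
  stopifnot(inherits(p, "mask_image"), inherits(g, "mask_image"),
            identical(dim(p$pixels), dim(g$pixels)))
  np <- sum(p$pixels); ng <- sum(g$pixels)
  if (np + ng == 0) stop("both masks are empty")
  2 * sum(p$pixels & g$pixels) / (np + ng)
}
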