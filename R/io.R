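#' Read/write detection tables
#'
#' CSV with columns slice_id, theta_deg, x_min, y_min, x_max, y_max,
#' confidence (extra columns such as `kept` or `is_fp` pass through).
#'
#' @param path CSV file path.
#' @return for the reader, a detection data.frame.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_id", "theta_deg", "x_min", "y_min", "x_max", "y_max",
            "confidence")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detection file missing columns: ",
                         paste(miss, collapse = ", "))
  d$slice_id <- as.character(d$slice_id)
  d
}

#' @param dets detection data.frame.
#' @rdname read_detections
#' @export
write_detections <- function(dets, path) {
  utils::write.csv(dets, path, row.names = FALSE)
  invisible(path)
}

#' Read/write 3D point tables
#'
#' CSV with columns x, y, z and optionally cluster_id.
#'
#' @param path CSV file path.
#' @return for the reader, a matrix with columns x, y, z (cluster ids, if
#'   present, in attribute `cluster_id`).
#' @export
read_points <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("point file must have columns x, y, z")
  m <- as.matrix(d[, c("x", "y", "z")])
  if (!is.null(d$cluster_id)) attr(m, "cluster_id") <- d$cluster_id
  m
}

#' @param points n x 3 matrix.
#' @param cluster_id optional integer labels written alongside.
#' @rdname read_points
#' @export
write_points <- function(points, path, cluster_id = NULL) {
  d <- as.data.frame(points)
  names(d) <- c("x", "y", "z")
  if (!is.null(cluster_id)) d$cluster_id <- cluster_id
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export a point cloud as ASCII PLY
#'
#' For viewing or meshing the estimated contact points in external tools.
#'
#' @param points n x 3 matrix.
#' @param path output `.ply` path.
#' @export
write_ply <- function(points, path) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(points)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- apply(points, 1, function(p) paste(format(p, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write per-slice masks as grayscale TIFF
#'
#' Masks are stored one file per slice (value 1 = receptacle); the pixel
#' matrix is transposed to image row/column order on disk.
#'
#' @param path TIFF path.
#' @param theta_deg,slice_id metadata attached to the returned mask.
#' @return for the reader, a `mask_image`.
#' @export
read_mask <- function(path, theta_deg = NA_real_, slice_id = NA_character_) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  mask_image(t(m) > 0.5, theta_deg = theta_deg, slice_id = slice_id)
}

#' @param mask a `mask_image`.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(t(mask$pixels) * 1, path, bits.per.sample = 8)
  invisible(path)
}
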