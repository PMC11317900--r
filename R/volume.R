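#' CT volume container
#'
#' A `ct_volume` wraps a 3D grayscale grid together with its (isotropic) voxel
#' size in micrometres and a flag recording whether the bud rotation axis has
#' been aligned with the z grid axis. Voxel indices are 0-based throughout the
#' package, with voxel centres at integer coordinates; `data[x, y, z]` (1-based
#' R subscripts) holds the value of voxel (x-1, y-1, z-1).
#'
#' @param data numeric 3D array, indexed (x, y, z); all values must be finite.
#' @param voxel_size_um positive scalar, edge length of a voxel in micrometres.
#' @param axis_aligned logical; `TRUE` means the bud rotation axis coincides
#'   with the z grid axis (required by the radial slicer).
#' @return an object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, dim = c(8, 8, 4)), voxel_size_um = 2.75)
#' dim(v$data)
#' @export
ct_volume <- function(data, voxel_size_um, axis_aligned = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all three volume dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("volume values must be finite")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         axis_aligned = isTRUE(axis_aligned)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, %.4g um/voxel, axis_aligned=%s\n",
              d[1], d[2], d[3], x$voxel_size_um, x$axis_aligned))
  invisible(x)
}

#' Continuous centre of a volume grid
#'
#' Returns ((Nx-1)/2, (Ny-1)/2, (Nz-1)/2) in 0-based voxel coordinates — the
#' point used as rotation centre for axis alignment and as the in-plane
#' rotation centre for radial slicing. Symmetric for odd and even dimensions.
#'
#' @param v a `ct_volume`.
#' @return numeric length-3 vector.
#' @export
volume_center <- function(v) {
  stopifnot(inherits(v, "ct_volume"))
  (dim(v$data) - 1) / 2
}

#' Rotation-axis estimate
#'
#' A point the bud rotation axis passes through and its direction, both in
#' voxel units. In the source workflow the axis is determined by visual
#' inspection of the volume; this object just records that estimate. The
#' direction is normalised to unit length.
#'
#' @param point numeric length-3 vector (0-based voxel coordinates).
#' @param direction numeric length-3 vector; must be nonzero, stored unit-norm.
#' @return an object of class `axis_estimate`.
#' @export
axis_estimate <- function(point, direction) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  stopifnot(length(point) == 3L, length(direction) == 3L,
            all(is.finite(point)), all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("axis direction must be nonzero")
  structure(list(point = point, direction = direction / nrm),
            class = "axis_estimate")
}

# Rotation matrix mapping the unit vector `u` onto +z (Rodrigues formula).
.rotation_to_z <- function(u) {
  ez <- c(0, 0, 1)
  d <- sum(u * ez)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-9)
    stop("axis direction is antiparallel to z: rotation is degenerate, flip the direction")
  ax <- c(u[2] * ez[3] - u[3] * ez[2],
          u[3] * ez[1] - u[1] * ez[3],
          u[1] * ez[2] - u[2] * ez[1])
  ax <- ax / sqrt(sum(ax^2))
  th <- acos(max(-1, min(1, d)))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# round half away from zero (base round() rounds half to even)
.round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Resample a volume so the bud rotation axis becomes the z grid axis
#'
#' Applies the rigid map that sends the estimated axis onto the vertical line
#' through the grid centre, then resamples on the original grid by
#' nearest-neighbour lookup. Output voxels whose preimage falls outside the
#' source grid are filled with the mean of all source voxel values, preserving
#' the first-order intensity statistics of the volume. The axis point keeps its
#' z coordinate, so an axis already equal to z through the centre yields the
#' identity.
#'
#' @param v a `ct_volume`.
#' @param axis an `axis_estimate`.
#' @return a `ct_volume` of the same dimensions with `axis_aligned = TRUE`.
#' @export
rotate_volume_to_axis <- function(v, axis) {
  stopifnot(inherits(v, "ct_volume"), inherits(axis, "axis_estimate"))
  dims <- dim(v$data)
  ctr <- volume_center(v)
  M <- .rotation_to_z(axis$direction)
  a <- axis$point
  b <- c(ctr[1], ctr[2], a[3])  # image of the axis point
  fill <- mean(v$data)

  # identity shortcut: axis already the z grid axis through the centre
  if (all(abs(M - diag(3)) < 1e-12) && all(abs(a[1:2] - ctr[1:2]) < 1e-12)) {
    out <- v
    out$axis_aligned <- TRUE
    return(out)
  }

  Mt <- t(M)
  # output voxel grid (0-based), pulled back through the inverse map
  gx <- seq_len(dims[1]) - 1
  gy <- seq_len(dims[2]) - 1
  gz <- seq_len(dims[3]) - 1
  Q <- rbind(rep(gx, times = dims[2] * dims[3]),
             rep(rep(gy, each = dims[1]), times = dims[3]),
             rep(gz, each = dims[1] * dims[2]))
  S <- Mt %*% (Q - b) + a
  xi <- .round_half_away(S[1, ]); yi <- .round_half_away(S[2, ]); zi <- .round_half_away(S[3, ])
  ok <- xi >= 0 & xi < dims[1] & yi >= 0 & yi < dims[2] & zi >= 0 & zi < dims[3]
  vals <- rep(fill, ncol(Q))
  if (any(ok))
    vals[ok] <- v$data[cbind(xi[ok] + 1, yi[ok] + 1, zi[ok] + 1)]
  ct_volume(array(vals, dim = dims), v$voxel_size_um, axis_aligned = TRUE)
}

#' Load a CT volume
#'
#' Reads either a multi-page grayscale TIFF stack (page index maps to z) or a
#' raw binary file accompanied by a JSON sidecar `<path>.json` naming `shape`
#' (x, y, z), `dtype` (`uint8`, `uint16`, `float32` or `float64`) and
#' optionally `voxel_size_um`. For TIFF input the page matrix row maps to y and
#' the column to x.
#'
#' @param path file path (`.tif`/`.tiff` or raw binary).
#' @param voxel_size_um voxel edge length in micrometres; for raw input it may
#'   be omitted when the sidecar carries it.
#' @return a `ct_volume` (not axis-aligned).
#' @export
load_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    shp <- dim(pages[[1]])
    if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
      stop("inconsistent page shapes in TIFF stack")
    if (is.null(voxel_size_um)) stop("`voxel_size_um` is required for TIFF input")
    dat <- array(0, dim = c(shp[2], shp[1], length(pages)))
    for (z in seq_along(pages)) dat[, , z] <- t(pages[[z]])
    return(ct_volume(dat, voxel_size_um))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("raw volume requires a JSON sidecar at ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L) stop("sidecar `shape` must have 3 entries")
  n <- prod(shape)
  dtype <- meta$dtype
  vals <- switch(dtype,
    uint8   = as.numeric(readBin(path, "integer", n = n, size = 1, signed = FALSE)),
    uint16  = as.numeric(readBin(path, "integer", n = n, size = 2, signed = FALSE,
                                 endian = "little")),
    float32 = readBin(path, "numeric", n = n, size = 4, endian = "little"),
    float64 = readBin(path, "numeric", n = n, size = 8, endian = "little"),
    stop("unsupported dtype: ", dtype)
  )
  if (length(vals) != n) stop("raw file shorter than shape implies")
  vs <- if (!is.null(voxel_size_um)) voxel_size_um else meta$voxel_size_um
  if (is.null(vs)) stop("voxel size given neither as argument nor in sidecar")
  ct_volume(array(vals, dim = shape), vs)
}

#' Save a CT volume
#'
#' The inverse of [load_volume()]. TIFF output requires values in [0, 1]
#' (written as 16-bit grayscale pages unless `bits_per_sample` says otherwise);
#' raw output writes little-endian binary plus the JSON sidecar and
#' round-trips `float64` data bit-exactly.
#'
#' @param v a `ct_volume`.
#' @param path output path; format chosen by extension as in [load_volume()].
#' @param dtype element type for raw output.
#' @param bits_per_sample bit depth for TIFF output (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path, dtype = "float64", bits_per_sample = 16) {
  stopifnot(inherits(v, "ct_volume"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (min(v$data) < 0 || max(v$data) > 1)
      stop("TIFF output requires values in [0, 1]; rescale or use raw output")
    pages <- lapply(seq_len(dim(v$data)[3]), function(z) t(v$data[, , z]))
    tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  } else {
    dat <- as.vector(v$data)
    con <- file(path, "wb"); on.exit(close(con))
    switch(dtype,
      uint8   = writeBin(as.integer(dat), con, size = 1),
      uint16  = writeBin(as.integer(dat), con, size = 2, endian = "little"),
      float32 = writeBin(dat, con, size = 4, endian = "little"),
      float64 = writeBin(dat, con, size = 8, endian = "little"),
      stop("unsupported dtype: ", dtype)
    )
    jsonlite::write_json(
      list(shape = dim(v$data), dtype = dtype, voxel_size_um = v$voxel_size_um),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
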