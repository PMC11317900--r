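#' Parametric synthetic bud
#'
#' Describes a rotationally symmetric receptacle as a surface of revolution
#' z(r) with florets attached at phyllotactically arranged contact points.
#' Two profiles are supported: a cone z = z_apex - r / tan(alpha) (alpha is
#' the half-apex angle, so alpha = 45 deg gives slope 1) and a paraboloid
#' z = z_apex - r^2 / c. Contact points are placed on a Vogel spiral: point k
#' (k = 0, 1, ...) sits at azimuth k * 137.508 deg (the golden angle) and
#' radius spiral_constant * sqrt(k), clipped to the base radius — an
#' apex-dense, roughly area-uniform packing of the kind seen on real
#' capitula. The real arrangement is not modelled mechanistically; the spiral
#' is a geometric stand-in sufficient for exercising the pipeline.
#'
#' @param n_florets number of contact points (>= 1).
#' @param receptacle `"cone"` or `"paraboloid"`.
#' @param base_radius receptacle base radius R in pixels (> 0).
#' @param apex_z z of the apex, voxel units.
#' @param base_z z of the receptacle base (mask lower bound); defaults to the
#'   profile height at r = R.
#' @param alpha_deg cone half-apex angle in degrees (cone profile).
#' @param parab_c paraboloid scale c (paraboloid profile); defaults so the
#'   surface reaches `base_z` at r = R.
#' @param spiral_constant radial spacing scale of the Vogel spiral; defaults
#'   to `base_radius / sqrt(n_florets)` so the outermost floret sits just
#'   inside the base radius.
#' @param center_xy (x, y) of the rotation axis.
#' @param seed RNG seed used by the stochastic parts of the simulator.
#' @return an object of class `bud_spec`.
#' @export
bud_spec <- function(n_florets, receptacle = c("cone", "paraboloid"),
                     base_radius = 400, apex_z = 500, base_z = NULL,
                     alpha_deg = 45, parab_c = NULL,
                     spiral_constant = NULL, center_xy = c(0, 0), seed = 1L) {
  receptacle <- match.arg(receptacle)
  stopifnot(n_florets >= 1, base_radius > 0)
  if (receptacle == "cone") {
    slope <- 1 / tan(alpha_deg * pi / 180)
    profile <- function(r) apex_z - r * slope
    if (is.null(base_z)) base_z <- apex_z - base_radius * slope
  } else {
    if (is.null(parab_c)) {
      if (is.null(base_z)) base_z <- apex_z - base_radius
      parab_c <- base_radius^2 / (apex_z - base_z)
    }
    profile <- function(r) apex_z - r^2 / parab_c
    if (is.null(base_z)) base_z <- profile(base_radius)
  }
  if (is.null(spiral_constant)) spiral_constant <- base_radius / sqrt(n_florets)
  structure(list(n_florets = as.integer(n_florets), receptacle = receptacle,
                 base_radius = base_radius, apex_z = apex_z, base_z = base_z,
                 alpha_deg = alpha_deg, parab_c = parab_c,
                 spiral_constant = spiral_constant,
                 center_xy = as.numeric(center_xy), seed = as.integer(seed),
                 profile = profile),
            class = "bud_spec")
}

#' Detection-noise model for the simulator
#'
#' @param jitter_sigma_px sd of the in-plane Gaussian jitter added to each
#'   emitted detection centre (px, >= 0).
#' @param p_miss per-slice probability of missing a visible contact point.
#' @param fp_rate expected number of false positives per slice (Poisson),
#'   placed so that their whole box lies off the receptacle mask.
#' @param capture_halfwidth_px maximum perpendicular plane-to-point distance
#'   at which a contact point appears on a slice (models the physical extent
#'   of a contact point, which makes it visible on several adjacent slices).
#' @param box_size_px side length of emitted bounding boxes.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(jitter_sigma_px = 0, p_miss = 0, fp_rate = 0,
                       capture_halfwidth_px = 3, box_size_px = 8) {
  stopifnot(jitter_sigma_px >= 0, p_miss >= 0, p_miss <= 1, fp_rate >= 0,
            capture_halfwidth_px >= 0, box_size_px > 0)
  structure(list(jitter_sigma_px = jitter_sigma_px, p_miss = p_miss,
                 fp_rate = fp_rate, capture_halfwidth_px = capture_halfwidth_px,
                 box_size_px = box_size_px),
            class = "noise_spec")
}

#' Ground-truth contact points of a synthetic bud
#'
#' Deterministic given the spec: point k (k = 0 .. n-1) at azimuth
#' k * 137.508 deg, radius spiral_constant * sqrt(k) clipped to [0, R],
#' height z = profile(r). Point 0 sits exactly at the apex.
#'
#' @param spec a `bud_spec`.
#' @return list with `gt_points` (n x 3 matrix, columns x, y, z) and
#'   `profile` (the z(r) function).
#' @export
make_bud <- function(spec) {
  stopifnot(inherits(spec, "bud_spec"))
  k <- seq_len(spec$n_florets) - 1
  phi <- k * 137.508 * pi / 180
  r <- pmin(spec$spiral_constant * sqrt(k), spec$base_radius)
  pts <- cbind(x = spec$center_xy[1] + r * cos(phi),
               y = spec$center_xy[2] + r * sin(phi),
               z = spec$profile(r))
  list(gt_points = pts, profile = spec$profile)
}

#' Slice planes of a synthetic bud
#'
#' Planes at the radial-slicing azimuths, sharing the bud's axis centre. The
#' image width spans the bud diameter with a small margin; the height spans
#' the receptacle.
#'
#' @param spec a `bud_spec`.
#' @param interval_deg angular increment in degrees (must divide 180).
#' @param width,height image dimensions in pixels; sized from the spec when
#'   omitted.
#' @return list of `slice_plane` objects.
#' @export
bud_planes <- function(spec, interval_deg, width = NULL, height = NULL) {
  if (is.null(width)) width <- 2L * ceiling(spec$base_radius * 1.1) + 1L
  if (is.null(height)) height <- ceiling(spec$apex_z * 1.1) + 1L
  lapply(slice_angles(interval_deg), function(th)
    slice_plane(th, spec$center_xy, width, height))
}

#' Ground-truth receptacle masks per slice
#'
#' For a surface of revolution every mid-longitudinal mask is identical: the
#' filled region bounded above by the profile z(|r|), below by the receptacle
#' base, within |r| <= R. Pixel (h, v) is mask-true iff its centre satisfies
#' those bounds, with signed radius r = h - (width-1)/2.
#'
#' @param spec a `bud_spec`.
#' @param interval_deg angular increment in degrees.
#' @param width,height image dimensions (see [bud_planes()]).
#' @return list of `mask_image` objects, one per slice angle; slice ids are
#'   `"s<k>"` in angle order.
#' @export
render_masks <- function(spec, interval_deg, width = NULL, height = NULL) {
  planes <- bud_planes(spec, interval_deg, width, height)
  width <- planes[[1]]$width; height <- planes[[1]]$height
  h <- 0:(width - 1); v <- 0:(height - 1)
  r <- abs(h - (width - 1) / 2)
  zmax <- spec$profile(r)
  inside <- outer(seq_along(h), seq_along(v), function(i, j)
    r[i] <= spec$base_radius & v[j] >= spec$base_z & v[j] <= zmax[i])
  lapply(seq_along(planes), function(k)
    mask_image(inside, theta_deg = planes[[k]]$theta_deg,
               slice_id = sprintf("s%d", k - 1L)))
}

# uniform placement of a false-positive box fully off the mask
.place_fp <- function(mask, box, max_tries = 200) {
  dims <- dim(mask$pixels)
  on_idx <- which(mask$pixels, arr.ind = TRUE)
  hs <- on_idx[, 1] - 1; vs <- on_idx[, 2] - 1
  for (i in seq_len(max_tries)) {
    ch <- stats::runif(1, box / 2, dims[1] - 1 - box / 2)
    cv <- stats::runif(1, box / 2, dims[2] - 1 - box / 2)
    x0 <- ch - box / 2; x1 <- ch + box / 2
    y0 <- cv - box / 2; y1 <- cv + box / 2
    hit <- length(hs) > 0 &&
      any(hs >= x0 & hs < x1 & vs >= y0 & vs < y1)
    if (!hit) return(c(ch, cv))
  }
  NULL  # mask too full to place an off-mask box
}

#' Simulate per-slice contact-point detections
#'
#' For every plane, each ground-truth point whose perpendicular distance to
#' the plane is at most `capture_halfwidth_px` is visible; it is emitted with
#' probability 1 - p_miss as a box of side `box_size_px` centred on the
#' point's in-plane projection plus isotropic Gaussian jitter of sd
#' `jitter_sigma_px`. Additionally Poisson(`fp_rate`) false positives per
#' slice are placed uniformly with their whole box off the receptacle mask.
#' With all noise at zero and fp_rate 0 the output is the noiseless setup in
#' which the detector and the outlier removal are assumed perfect.
#'
#' Confidences are drawn uniformly in [0.5, 1] for true detections and
#' [0.1, 0.6] for false positives. All randomness comes from the R RNG; call
#' `set.seed()` (or use `spec$seed`) for reproducibility.
#'
#' @param gt_points n x 3 matrix of ground-truth contact points.
#' @param planes list of `slice_plane` (e.g. from [bud_planes()]).
#' @param noise a `noise_spec`.
#' @param masks list of `mask_image` aligned with `planes` (required when
#'   `fp_rate > 0`); their slice ids are reused for the detections.
#' @return a detection data.frame with an extra logical column `is_fp`
#'   (simulation truth; strip it before feeding evaluation code that should
#'   not see it).
#' @export
simulate_detections <- function(gt_points, planes, noise = noise_spec(),
                                masks = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$fp_rate > 0 && is.null(masks))
    stop("masks are required to place off-mask false positives")
  b2 <- noise$box_size_px / 2
  rows <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    plane <- planes[[k]]
    sid <- if (!is.null(masks)) masks[[k]]$slice_id else sprintf("s%d", k - 1L)
    proj <- world_to_plane(plane, gt_points)
    vis <- which(abs(proj[, "off_plane"]) <= noise$capture_halfwidth_px)
    out <- list()
    if (length(vis)) {
      emit <- vis[stats::runif(length(vis)) >= noise$p_miss]
      if (length(emit)) {
        ch <- proj[emit, "h"] + stats::rnorm(length(emit), 0, noise$jitter_sigma_px)
        cv <- proj[emit, "v"] + stats::rnorm(length(emit), 0, noise$jitter_sigma_px)
        out[[1]] <- data.frame(
          slice_id = sid, theta_deg = plane$theta_deg,
          x_min = ch - b2, y_min = cv - b2, x_max = ch + b2, y_max = cv + b2,
          confidence = stats::runif(length(emit), 0.5, 1), is_fp = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    if (noise$fp_rate > 0) {
      nfp <- stats::rpois(1, noise$fp_rate)
      if (nfp > 0) {
        cs <- lapply(seq_len(nfp), function(i)
          .place_fp(masks[[k]], noise$box_size_px))
        cs <- do.call(rbind, Filter(Negate(is.null), cs))
        if (!is.null(cs) && nrow(cs))
          out[[length(out) + 1]] <- data.frame(
            slice_id = sid, theta_deg = plane$theta_deg,
            x_min = cs[, 1] - b2, y_min = cs[, 2] - b2,
            x_max = cs[, 1] + b2, y_max = cs[, 2] + b2,
            confidence = stats::runif(nrow(cs), 0.1, 0.6), is_fp = TRUE,
            stringsAsFactors = FALSE)
      }
    }
    rows[[k]] <- if (length(out)) do.call(rbind, out) else NULL
  }
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(res))
    res <- cbind(detections(), is_fp = logical(0))
  rownames(res) <- NULL
  res
}

#' Voxel rendering of a synthetic bud
#'
#' Renders the receptacle as a bright solid (value `fg`) on a dark background
#' (`bg`) so the radial slicer can be exercised end-to-end on data with a
#' known analytic cross-section. Photometric realism is out of scope.
#'
#' @param spec a `bud_spec`; its `center_xy` is ignored — the bud is centred
#'   on the volume grid.
#' @param dims length-3 integer vector of volume dimensions.
#' @param voxel_size_um voxel size of the rendered volume.
#' @param fg,bg foreground/background intensities.
#' @return an axis-aligned `ct_volume`.
#' @export
render_volume <- function(spec, dims, voxel_size_um = 2.75, fg = 1, bg = 0) {
  dims <- as.integer(dims)
  ctr <- (dims - 1) / 2
  gx <- (seq_len(dims[1]) - 1) - ctr[1]
  gy <- (seq_len(dims[2]) - 1) - ctr[2]
  gz <- seq_len(dims[3]) - 1
  r <- sqrt(outer(gx^2, gy^2, "+"))
  zmax <- spec$profile(r)           # dims[1] x dims[2]
  dat <- array(bg, dim = dims)
  for (z in seq_len(dims[3])) {
    zz <- gz[z]
    dat[, , z][r <= spec$base_radius & zz >= spec$base_z & zz <= zmax] <- fg
  }
  ct_volume(dat, voxel_size_um, axis_aligned = TRUE)
}

#' Run the full synthetic pipeline: simulate, filter, integrate, cluster
#'
#' Convenience wrapper reproducing the simulation experiment end-to-end:
#' build the bud, simulate per-slice detections, remove off-receptacle false
#' positives, back-project the kept detections to 3D and cluster them at
#' threshold `d`.
#'
#' @param spec a `bud_spec`.
#' @param interval_deg slicing increment in degrees.
#' @param noise a `noise_spec`.
#' @param d clustering termination threshold (voxels); default half the
#'   minimum ground-truth nearest-neighbour spacing.
#' @return list with `gt_points`, `detections`, `kept`, `removed`, `points`
#'   (back-projected kept detections), `clusters`, `contact_points` and `d`.
#' @export
simulate_pipeline <- function(spec, interval_deg, noise = noise_spec(), d = NULL) {
  set.seed(spec$seed)
  bud <- make_bud(spec)
  planes <- bud_planes(spec, interval_deg)
  masks <- render_masks(spec, interval_deg)
  dets <- simulate_detections(bud$gt_points, planes, noise, masks)
  keep <- vector("list", length(planes)); drop_ <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    dk <- dets[dets$slice_id == masks[[k]]$slice_id, , drop = FALSE]
    f <- filter_detections(dk, masks[[k]])
    keep[[k]] <- f$kept; drop_[[k]] <- f$removed
  }
  kept <- do.call(rbind, keep); removed <- do.call(rbind, drop_)
  rownames(kept) <- rownames(removed) <- NULL
  pts <- backproject_detections(kept, spec$center_xy, planes[[1]]$width)
  if (is.null(d)) {
    d <- if (nrow(bud$gt_points) >= 2)
      min(nearest_floret_distances(bud$gt_points)) / 2 else 10
  }
  cl <- agglomerate(pts, d)
  list(gt_points = bud$gt_points, detections = dets, kept = kept,
       removed = removed, points = pts, clusters = cl,
       contact_points = estimate_contact_points(cl), d = d)
}
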