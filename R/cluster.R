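#' Back-project a per-slice detection into 3D voxel coordinates
#'
#' The integrated point of a detection is the centre of its bounding box
#' (contact-point *position* matters, box size does not), mapped through
#' [plane_to_world()] of the slice plane it was found on.
#'
#' @param det one-row detection data.frame; `det$theta_deg` must equal the
#'   plane azimuth.
#' @param plane the `slice_plane` the detection belongs to.
#' @return numeric length-3 vector (x, y, z) in voxel units.
#' @export
backproject <- function(det, plane) {
  stopifnot(inherits(plane, "slice_plane"), nrow(det) == 1)
  if (abs(det$theta_deg - plane$theta_deg) > 1e-9)
    stop("detection azimuth does not match the plane")
  h <- (det$x_min + det$x_max) / 2
  v <- (det$y_min + det$y_max) / 2
  drop(plane_to_world(plane, h, v))
}

#' Back-project a whole detection table
#'
#' Vectorised form of [backproject()]: maps every detection through the plane
#' geometry implied by its own `theta_deg` (all planes share `center_xy`,
#' `width`, `height`).
#'
#' @param dets detection data.frame.
#' @param center_xy in-plane rotation centre shared by all slices.
#' @param width slice image width in pixels.
#' @return an n x 3 matrix of points, plus attributes `source_slice` and
#'   `source_confidence`.
#' @export
backproject_detections <- function(dets, center_xy, width) {
  th <- dets$theta_deg * pi / 180
  r <- (dets$x_min + dets$x_max) / 2 - (width - 1) / 2
  pts <- cbind(x = center_xy[1] + r * cos(th),
               y = center_xy[2] + r * sin(th),
               z = (dets$y_min + dets$y_max) / 2)
  attr(pts, "source_slice") <- dets$slice_id
  attr(pts, "source_confidence") <- dets$confidence
  pts
}

#' Group-average (UPGMA) distance between two point sets
#'
#' The mean of all |A| x |B| pairwise Euclidean distances between the members
#' of the two clusters.
#'
#' @param a,b numeric matrices with 3 columns (one point per row); vectors of
#'   length 3 are accepted for singletons.
#' @return scalar mean pairwise distance.
#' @export
group_average <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  mean(sqrt(pmax(d2, 0)))
}

#' Group-average agglomerative clustering with threshold termination
#'
#' Starts from singleton clusters and repeatedly merges the pair with the
#' smallest group-average distance while that minimum is strictly below the
#' threshold `d`; merging terminates as soon as the smallest inter-cluster
#' group average is >= d (or one cluster remains). Inter-cluster distances are
#' maintained by the average-linkage Lance-Williams recurrence
#' d(A u B, C) = (|A| d(A,C) + |B| d(B,C)) / (|A| + |B|), which is exact for
#' the group-average criterion. Ties on the minimal distance are broken by the
#' lexicographically smallest (older, newer) pair of cluster-creation indices
#' (original points are created in input order, merged clusters afterwards in
#' merge order), making the partition deterministic.
#'
#' Because the final partition is a threshold cut of the UPGMA dendrogram, the
#' number of clusters is non-increasing in `d`.
#'
#' @param points n x 3 numeric matrix (or data.frame with columns x, y, z).
#' @param d termination threshold in voxel units, > 0.
#' @return an object of class `contact_clusters`: list with `assignment`
#'   (integer cluster label per input point, labels ordered by first member),
#'   `members` (list of member index vectors), `centroids` (k x 3 matrix),
#'   `sizes` and `d`.
#' @export
agglomerate <- function(points, d) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  if (n == 0) stop("no points to cluster")
  stopifnot(d > 0)
  if (n == 1) {
    return(structure(list(assignment = 1L, members = list(1L),
                          centroids = matrix(points, ncol = 3,
                                             dimnames = list(NULL, c("x", "y", "z"))),
                          sizes = 1L, d = d),
                     class = "contact_clusters"))
  }
  # slot-reuse scheme: merging clusters in slots i < j writes the merged
  # cluster into slot i and retires slot j (rows/cols set to Inf); `created`
  # tracks cluster-creation order for deterministic tie-breaking.
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  created <- seq_len(n)
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))
  next_id <- n + 1L
  repeat {
    if (sum(active) < 2) break
    mn <- min(D)
    if (mn >= d) break
    # ties: lexicographically smallest (older, newer) creation-index pair
    hit <- which(D == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    older <- pmin(created[hit[, 1]], created[hit[, 2]])
    newer <- pmax(created[hit[, 1]], created[hit[, 2]])
    pick <- order(older, newer)[1]
    i <- hit[pick, 1]; j <- hit[pick, 2]
    # Lance-Williams average-linkage update against every other cluster
    dn <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    dn[c(i, j)] <- Inf
    D[i, ] <- dn; D[, i] <- dn
    D[j, ] <- Inf; D[, j] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    created[i] <- next_id
    next_id <- next_id + 1L
    active[j] <- FALSE
  }
  mem <- members[active]
  # order clusters by smallest member index for a stable, readable labelling
  mem <- mem[order(vapply(mem, min, integer(1)))]
  assignment <- integer(n)
  for (k in seq_along(mem)) assignment[mem[[k]]] <- k
  centroids <- t(vapply(mem, function(m)
    colMeans(points[m, , drop = FALSE]), numeric(3)))
  colnames(centroids) <- c("x", "y", "z")
  structure(list(assignment = assignment, members = mem, centroids = centroids,
                 sizes = lengths(mem), d = d),
            class = "contact_clusters")
}

#' @export
print.contact_clusters <- function(x, ...) {
  cat(sprintf("<contact_clusters> %d points -> %d clusters (threshold d = %g)\n",
              length(x$assignment), length(x$members), x$d))
  invisible(x)
}

#' Contact-point estimates from a clustering
#'
#' One estimate per cluster, equal to the cluster centroid (the arithmetic
#' mean of the member points). The number of clusters is taken as the number
#' of contact points.
#'
#' @param clusters a `contact_clusters` object from [agglomerate()], or an
#'   n x 3 point matrix, in which case [agglomerate()] is run first.
#' @param d termination threshold; required (and used) only when `clusters`
#'   is a raw point matrix, otherwise taken from the clustering.
#' @return an object of class `contact_points`: list with `estimates`
#'   (k x 3 matrix), `threshold_d`, `n_points` (input detections) and
#'   `sizes` (cluster sizes).
#' @export
estimate_contact_points <- function(clusters, d = NULL) {
  if (!inherits(clusters, "contact_clusters")) {
    if (is.null(d)) stop("`d` is required when passing raw points")
    clusters <- agglomerate(clusters, d)
  }
  structure(list(estimates = clusters$centroids, threshold_d = clusters$d,
                 n_points = length(clusters$assignment),
                 sizes = clusters$sizes),
            class = "contact_points")
}

#' @export
print.contact_points <- function(x, ...) {
  cat(sprintf("<contact_points> %d contact points estimated from %d detections (d = %g)\n",
              nrow(x$estimates), x$n_points, x$threshold_d))
  invisible(x)
}

#' @export
summary.contact_points <- function(object, ...) {
  cat(sprintf("Contact-point estimates: %d clusters from %d back-projected detections\n",
              nrow(object$estimates), object$n_points))
  cat(sprintf("Termination threshold d = %g voxels\n", object$threshold_d))
  cat(sprintf("Cluster sizes: min %d, median %g, max %d\n",
              min(object$sizes), stats::median(object$sizes), max(object$sizes)))
  if (nrow(object$estimates) >= 2) {
    nn <- nearest_floret_distances(object$estimates)
    cat(sprintf("Nearest-neighbour spacing of estimates: mean %.2f, min %.2f voxels\n",
                mean(nn), min(nn)))
  }
  invisible(object)
}

#' @export
as.data.frame.contact_points <- function(x, ...) {
  data.frame(x$estimates, cluster_size = as.integer(x$sizes))
}

#' @export
plot.contact_points <- function(x, which = c("xy", "xz"), ...) {
  which <- match.arg(which)
  e <- x$estimates
  if (which == "xy")
    plot(e[, "x"], e[, "y"], asp = 1, xlab = "x (voxels)", ylab = "y (voxels)",
         main = sprintf("Contact-point estimates (d = %g), top view", x$threshold_d), ...)
  else
    plot(e[, "x"], e[, "z"], asp = 1, xlab = "x (voxels)", ylab = "z (voxels)",
         main = sprintf("Contact-point estimates (d = %g), side view", x$threshold_d), ...)
  invisible(x)
}

#' Positional accuracy of contact-point estimates against ground truth
#'
#' Each estimate is matched to its nearest ground-truth point and the
#' Euclidean distance to it is the positional error. The per-estimate distance
#' from the rotation axis is reported alongside to support the error-versus-
#' axis-distance analysis (clustering degrades near the apex, where contact
#' points are densest). The summary standard deviation is the population sd.
#'
#' @param estimates a `contact_points` object or k x 3 matrix.
#' @param gt m x 3 matrix of ground-truth contact points (m >= 1).
#' @param axis_xy (x, y) of the rotation axis, for the axis-distance column.
#' @return an object of class `contact_eval`: list with `errors`,
#'   `nearest_gt` (index), `axis_distance`, `mean`, `sd`.
#' @export
evaluate_positions <- function(estimates, gt, axis_xy = c(0, 0)) {
  if (inherits(estimates, "contact_points")) estimates <- estimates$estimates
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 3)
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 3)
  stopifnot(nrow(gt) >= 1)
  d2 <- outer(rowSums(estimates^2), rowSums(gt^2), "+") -
        2 * tcrossprod(estimates, gt)
  d2 <- pmax(d2, 0)
  nearest <- max.col(-d2, ties.method = "first")
  errors <- sqrt(d2[cbind(seq_len(nrow(estimates)), nearest)])
  axis_distance <- sqrt((estimates[, 1] - axis_xy[1])^2 +
                        (estimates[, 2] - axis_xy[2])^2)
  structure(list(errors = errors, nearest_gt = nearest,
                 axis_distance = axis_distance,
                 mean = mean(errors),
                 sd = sqrt(mean((errors - mean(errors))^2))),
            class = "contact_eval")
}

#' @export
print.contact_eval <- function(x, ...) {
  cat(sprintf("<contact_eval> %d estimates: error mean %.4g, sd %.4g (voxels)\n",
              length(x$errors), x$mean, x$sd))
  invisible(x)
}

#' Nearest-neighbour distance of every point in a set
#'
#' For each point, the Euclidean distance to its closest *other* point. Used
#' to measure floret spacing on the receptacle and the accuracy of estimated
#' spacings.
#'
#' @param points n x 3 matrix, n >= 2.
#' @return numeric vector of length n.
#' @export
nearest_floret_distances <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) < 2) stop("need at least 2 points")
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  unname(apply(D, 1, min))
}

#' Cluster-count sweep over termination thresholds
#'
#' Runs [agglomerate()] at each threshold and tabulates the resulting cluster
#' count; counts are non-increasing in d.
#'
#' @param points n x 3 matrix of back-projected detections.
#' @param d_values thresholds to sweep, e.g. `c(1, 10, 20, 30, 40, 50)`.
#' @return data.frame with columns `d` and `n_clusters`.
#' @export
sweep_cluster_counts <- function(points, d_values = c(1, 10, 20, 30, 40, 50)) {
  data.frame(d = d_values,
             n_clusters = vapply(d_values, function(d)
               length(agglomerate(points, d)$members), integer(1)))
}
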