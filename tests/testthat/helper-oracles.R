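# Independent oracles and fixture builders used across the suite.

# Naive group-average agglomeration: recomputes every inter-cluster mean
# pairwise distance from scratch each iteration via indicator-matrix
# aggregation of the full point-distance matrix. Same termination and
# tie-break rules as the implementation, but no Lance-Williams recurrence.
naive_agglomerate <- function(points, d) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  Dp <- as.matrix(stats::dist(points))
  groups <- as.list(seq_len(n))
  created <- seq_len(n)
  next_id <- n + 1L
  repeat {
    k <- length(groups)
    if (k < 2) break
    Z <- matrix(0, n, k)
    for (g in seq_len(k)) Z[groups[[g]], g] <- 1
    M <- crossprod(Z, Dp %*% Z) / outer(lengths(groups), lengths(groups))
    diag(M) <- Inf
    mn <- min(M)
    if (mn >= d) break
    hit <- which(M == mn, arr.ind = TRUE)
    # M can be asymmetric in the last ulp; normalise to sorted slot pairs
    hit <- unique(cbind(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])))
    older <- pmin(created[hit[, 1]], created[hit[, 2]])
    newer <- pmax(created[hit[, 1]], created[hit[, 2]])
    pick <- order(older, newer)[1]
    a <- hit[pick, 1]; b <- hit[pick, 2]
    groups[[a]] <- c(groups[[a]], groups[[b]])
    created[a] <- next_id
    next_id <- next_id + 1L
    groups[[b]] <- NULL
    created <- created[-b]
  }
  groups
}

# canonical partition labelling: label clusters by their smallest member,
# in increasing order, so partitions from different routes compare directly
canonical_assignment <- function(groups, n) {
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  a <- integer(n)
  for (k in seq_along(groups)) a[groups[[k]]] <- k
  a
}

# Pixel-enumeration IoU oracle for integer-aligned half-open boxes: a pixel
# (h, v) belongs to the box iff x_min <= h < x_max and y_min <= v < y_max.
raster_iou <- function(a, b) {
  cells <- function(bx) {
    g <- expand.grid(h = seq(bx["x_min"], bx["x_max"] - 1),
                     v = seq(bx["y_min"], bx["y_max"] - 1))
    paste(g$h, g$v)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# 101-point AP computed by explicit enumeration of the interpolated
# precisions, independent of the package's envelope-based implementation
enum_average_precision <- function(tp, n_gt) {
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  vals <- vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(vals)
}

# random logical mask
random_mask <- function(w, h, p = 0.3) {
  mask_image(matrix(runif(w * h) < p, w, h))
}

# small volume with a single bright voxel (0-based position)
impulse_volume <- function(dims, pos, bright = 1, bg = 0, voxel = 1) {
  a <- array(bg, dim = dims)
  a[pos[1] + 1, pos[2] + 1, pos[3] + 1] <- bright
  ct_volume(a, voxel, axis_aligned = TRUE)
}

# 0-based position(s) of voxels holding the maximum value
bright_positions <- function(v) {
  which(v$data == max(v$data), arr.ind = TRUE) - 1
}
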