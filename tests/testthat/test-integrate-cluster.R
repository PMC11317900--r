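test_that("backprojection places box centres on the slice plane in 3D", {
  pl <- slice_plane(0, c(10, 10), 21, 15)
  mid <- (21 - 1) / 2
  on_axis <- detections("s0", 0, mid - 2, 3, mid + 2, 7, 0.9)
  expect_equal(unname(backproject(on_axis, pl)), c(10, 10, 5))

  right <- detections("s0", 0, mid + 8, 0, mid + 12, 4, 0.9)
  expect_equal(unname(backproject(right, pl)), c(20, 10, 2))

  pl30 <- slice_plane(30, c(10, 10), 21, 15)
  d30 <- detections("s0", 30, mid + 18, 2, mid + 22, 6, 0.9)
  p <- backproject(d30, pl30)
  expect_equal(unname(p[1:2] - c(10, 10)), c(17.3205, 10.0), tolerance = 1e-4)
  expect_error(backproject(d30, pl), "azimuth")

  # vectorised route agrees with the one-at-a-time route
  dets <- rbind(on_axis, right)
  pts <- backproject_detections(dets, c(10, 10), 21)
  expect_equal(unname(pts[1, ]), unname(backproject(on_axis, pl)))
  expect_equal(unname(pts[2, ]), unname(backproject(right, pl)))
})

test_that("group_average is the mean pairwise Euclidean distance", {
  expect_equal(group_average(c(0, 0, 0), c(3, 4, 0)), 5)
  A <- rbind(c(0, 0, 0), c(2, 0, 0))
  B <- rbind(c(0, 3, 0), c(0, 4, 0))
  manual <- (3 + 4 + sqrt(13) + sqrt(20)) / 4  # the four pairs, by hand
  expect_equal(group_average(A, B), manual, tolerance = 1e-12)
  expect_equal(group_average(A, B), 3.76942, tolerance = 1e-5)
  expect_equal(group_average(B, A), group_average(A, B))
})

test_that("agglomerate merges below d and terminates at the threshold", {
  # everything merges when all pairwise distances are far below d
  tight <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_length(agglomerate(tight, 10)$members, 1)

  # two separated triples stay apart
  blob <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  two <- rbind(blob, sweep(blob, 2, c(100, 0, 0), "+"))
  cl <- agglomerate(two, 10)
  expect_length(cl$members, 2)
  expect_equal(cl$assignment, c(1, 1, 1, 2, 2, 2))

  # termination is >= d: two points exactly d apart do not merge
  expect_length(agglomerate(rbind(c(0, 0, 0), c(5, 0, 0)), 5)$members, 2)
  expect_length(agglomerate(rbind(c(0, 0, 0), c(5, 0, 0)), 5 + 1e-9)$members, 1)

  expect_error(agglomerate(matrix(numeric(0), ncol = 3), 1), "no points")
  expect_equal(agglomerate(c(1, 2, 3), 1)$centroids[1, ],
               c(x = 1, y = 2, z = 3))
})

test_that("agglomerate matches the naive recompute-everything oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:45, 1)
    pts <- matrix(runif(3 * n, 0, 50), ncol = 3)
    diam <- max(dist(pts))
    d <- runif(1, 1e-3, diam)
    got <- agglomerate(pts, d)$assignment
    want <- canonical_assignment(naive_agglomerate(pts, d), n)
    expect_equal(got, want)
  }
})

test_that("agglomerate agrees with average-linkage hclust cut at the threshold", {
  # independent library cross-check: cutting the UPGMA dendrogram just below
  # d yields the same partition (merge heights are the group averages)
  set.seed(32)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    pts <- matrix(rnorm(3 * n, sd = 20), ncol = 3)
    d <- runif(1, 1, 40)
    hc <- stats::hclust(dist(pts), method = "average")
    want <- as.integer(factor(stats::cutree(hc, h = d * (1 - 1e-12)),
                              levels = unique(stats::cutree(hc, h = d * (1 - 1e-12)))))
    got <- agglomerate(pts, d)$assignment
    # compare partitions up to label permutation
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster centroids are the member means and define the estimates", {
  cl <- agglomerate(rbind(c(0, 0, 0), c(2, 0, 0)), 5)
  est <- estimate_contact_points(cl)
  expect_equal(unname(est$estimates[1, ]), c(1, 0, 0))
  expect_equal(est$threshold_d, 5)

  # singletons map to themselves
  pts <- matrix(seq(0, 120, length.out = 15), ncol = 3)
  est2 <- estimate_contact_points(pts, d = 1e-6)
  expect_equal(nrow(est2$estimates), 5)
  expect_equal(unname(est2$estimates), unname(pts))

  # centroid invariant on a random clustering
  set.seed(33)
  rp <- matrix(runif(90, 0, 30), ncol = 3)
  cl3 <- agglomerate(rp, 8)
  for (k in seq_along(cl3$members))
    expect_equal(unname(cl3$centroids[k, ]),
                 unname(colMeans(rp[cl3$members[[k]], , drop = FALSE])),
                 tolerance = 1e-9)
  df <- as.data.frame(estimate_contact_points(cl3))
  expect_equal(nrow(df), length(cl3$members))
})

test_that("cluster count is non-increasing in the termination threshold", {
  set.seed(34)
  pts <- matrix(runif(150, 0, 60), ncol = 3)
  sw <- sweep_cluster_counts(pts, c(0.5, 1, 2, 5, 10, 20, 40, 80))
  expect_true(all(diff(sw$n_clusters) <= 0))
  expect_equal(sw$n_clusters[1], 50)            # d -> 0: all singletons
  expect_equal(sw$n_clusters[nrow(sw)], 1)      # d > diameter: one cluster
})

test_that("evaluate_positions reports nearest-GT errors, axis distances and summaries", {
  gt <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 5))
  ev0 <- evaluate_positions(gt, gt)
  expect_equal(ev0$errors, rep(0, 3))
  ev1 <- evaluate_positions(gt[1, , drop = FALSE] + c(1, 0, 0), gt)
  expect_equal(ev1$errors, 1)

  set.seed(35)
  est <- matrix(runif(60, 0, 40), ncol = 3)
  g <- matrix(runif(60, 0, 40), ncol = 3)
  ev <- evaluate_positions(est, g, axis_xy = c(20, 20))
  # exhaustive nearest-neighbour oracle
  for (i in 1:20) {
    want <- min(sqrt(colSums((t(g) - est[i, ])^2)))
    expect_equal(ev$errors[i], want, tolerance = 1e-9)
  }
  expect_equal(ev$mean, mean(ev$errors))
  expect_equal(ev$sd, sqrt(mean((ev$errors - mean(ev$errors))^2)))  # population sd
  expect_equal(ev$axis_distance,
               sqrt((est[, 1] - 20)^2 + (est[, 2] - 20)^2))
})

test_that("nearest_floret_distances matches the exhaustive pairwise search", {
  expect_equal(nearest_floret_distances(rbind(c(0, 0, 0), c(5, 0, 0))), c(5, 5))
  coll <- cbind(c(0, 1, 10), 0, 0)
  expect_equal(nearest_floret_distances(coll), c(1, 1, 9))
  expect_error(nearest_floret_distances(c(1, 2, 3)), "at least 2")

  set.seed(36)
  pts <- matrix(runif(90, 0, 25), ncol = 3)
  got <- nearest_floret_distances(pts)
  for (i in 1:30) {
    d <- sqrt(colSums((t(pts[-i, , drop = FALSE]) - pts[i, ])^2))
    expect_equal(got[i], min(d), tolerance = 1e-12)
  }
})

test_that("averaging over more supporting slices shrinks the centroid error", {
  # a planted point detected on N slices with zero-mean isotropic jitter:
  # the centroid (cluster mean) error decreases with N
  set.seed(37)
  err_for <- function(N) {
    jit <- cbind(rnorm(N), rnorm(N), 0)
    cl <- agglomerate(jit, d = 1e6)  # all detections form one cluster
    sqrt(sum(estimate_contact_points(cl)$estimates[1, ]^2))
  }
  reps <- 60
  e5 <- mean(replicate(reps, err_for(5)))
  e100 <- mean(replicate(reps, err_for(100)))
  expect_lt(e100, e5)
})
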