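test_that("make_bud places florets on a golden-angle spiral on the surface", {
  one <- make_bud(bud_spec(1, "cone", base_radius = 100, apex_z = 200))
  expect_equal(nrow(one$gt_points), 1)
  expect_equal(unname(one$gt_points[1, ]), c(0, 0, 200))  # exactly at the apex

  spec <- bud_spec(100, "cone", base_radius = 400, apex_z = 500, alpha_deg = 45)
  bud <- make_bud(spec)
  pts <- bud$gt_points
  expect_equal(nrow(pts), 100)

  # consecutive azimuth differences are all the golden angle (mod 360)
  phi <- atan2(pts[-1, 2], pts[-1, 1]) * 180 / pi  # k >= 1 (k = 0 has r = 0)
  dphi <- diff(phi) %% 360
  expect_true(all(abs(dphi - 137.508) < 1e-6 | abs(dphi - 137.508) > 359.9))

  # every point lies on the receptacle surface z(r)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  expect_true(all(abs(spec$profile(r) - pts[, 3]) < 1e-6))
  expect_true(all(r <= 400 + 1e-9))

  # radial coordinate follows the area-uniform sqrt(k) law
  expect_equal(r[5], spec$spiral_constant * sqrt(4), tolerance = 1e-9)

  # deterministic given the spec
  expect_identical(make_bud(spec)$gt_points, pts)
})

test_that("paraboloid profiles are supported", {
  spec <- bud_spec(30, "paraboloid", base_radius = 100, apex_z = 300,
                   base_z = 100)
  bud <- make_bud(spec)
  r <- sqrt(bud$gt_points[, 1]^2 + bud$gt_points[, 2]^2)
  expect_true(all(abs(spec$profile(r) - bud$gt_points[, 3]) < 1e-6))
  expect_equal(spec$profile(100), 100)  # surface meets the base at r = R
})

test_that("render_masks produces identical rotationally symmetric masks", {
  spec <- bud_spec(10, "cone", base_radius = 200, apex_z = 450, alpha_deg = 45)
  masks <- render_masks(spec, 45, width = 512, height = 480)
  expect_length(masks, 4)
  for (m in masks[-1]) expect_identical(m$pixels, masks[[1]]$pixels)

  # the central column spans apex to base
  px <- masks[[1]]$pixels
  mid <- (512 - 1) / 2
  col <- px[mid + 1.5, ]  # nearest integer column to the axis (r = 0.5)
  v_on <- which(col) - 1
  expect_equal(min(v_on), ceiling(spec$base_z))
  expect_equal(max(v_on), floor(spec$profile(0.5)))

  # rasterised area matches the analytic cross-section within 2 %:
  # cone with slope 1 -> area = R^2
  expect_lt(abs(sum(px) - 200^2) / 200^2, 0.02)
})

test_that("noiseless detections back-project to within the tangential bound", {
  spec <- bud_spec(40, "cone", base_radius = 150, apex_z = 300, seed = 5)
  bud <- make_bud(spec)
  planes <- bud_planes(spec, 2)
  noise <- noise_spec(capture_halfwidth_px = 3, box_size_px = 8)
  set.seed(spec$seed)
  dets <- simulate_detections(bud$gt_points, planes, noise)
  expect_gt(nrow(dets), 0)
  expect_false(any(dets$is_fp))
  pts <- backproject_detections(dets, spec$center_xy, planes[[1]]$width)
  # every back-projected centre is within capture_halfwidth of its gt point
  d2gt <- apply(pts, 1, function(p)
    min(sqrt(colSums((t(bud$gt_points) - p)^2))))
  expect_true(all(d2gt <= noise$capture_halfwidth_px + 1e-9))

  # coverage: every gt point visible on >= 1 plane (capture_halfwidth
  # exceeds half the worst tangential spacing at every radius here)
  offs <- sapply(planes, function(pl)
    abs(world_to_plane(pl, bud$gt_points)[, "off_plane"]))
  expect_true(all(apply(offs, 1, min) <= noise$capture_halfwidth_px))
})

test_that("p_miss = 1 suppresses every true detection", {
  spec <- bud_spec(20, "cone", base_radius = 100, apex_z = 200, seed = 6)
  bud <- make_bud(spec)
  planes <- bud_planes(spec, 15)
  masks <- render_masks(spec, 15)
  set.seed(6)
  dets <- simulate_detections(bud$gt_points, planes,
                              noise_spec(p_miss = 1, fp_rate = 2), masks)
  expect_true(all(dets$is_fp))
})

test_that("planted false positives sit fully off-mask and are all filtered out", {
  spec <- bud_spec(30, "cone", base_radius = 120, apex_z = 250, seed = 7)
  bud <- make_bud(spec)
  planes <- bud_planes(spec, 7.5)
  masks <- render_masks(spec, 7.5)
  set.seed(7)
  dets <- simulate_detections(bud$gt_points, planes,
                              noise_spec(fp_rate = 3), masks)
  expect_gt(sum(dets$is_fp), 0)
  expect_gt(sum(!dets$is_fp), 0)
  for (k in seq_along(masks)) {
    dk <- dets[dets$slice_id == masks[[k]]$slice_id, , drop = FALSE]
    f <- filter_detections(dk, masks[[k]])
    expect_true(all(!f$kept$is_fp))      # no false positive survives
    expect_true(all(f$removed$is_fp))    # no true detection is lost
  }
})

test_that("simulation is deterministic given spec and seed", {
  spec <- bud_spec(25, "cone", base_radius = 100, apex_z = 220, seed = 11)
  run <- function() {
    set.seed(spec$seed)
    simulate_detections(make_bud(spec)$gt_points, bud_planes(spec, 7.5),
                        noise_spec(jitter_sigma_px = 1, p_miss = 0.1,
                                   fp_rate = 1),
                        render_masks(spec, 7.5))
  }
  expect_identical(run(), run())
})

test_that("rendered volumes slice to the analytic receptacle cross-section", {
  spec <- bud_spec(5, "cone", base_radius = 20, apex_z = 50, alpha_deg = 45)
  vol <- render_volume(spec, dims = c(61, 61, 60))
  s <- slice_at_angle(vol, 30)
  mid <- (s$plane$width - 1) / 2
  on <- s$pixels == 1
  # bright pixels fill base_z <= v <= apex_z - |r| for |r| <= R
  for (h in c(mid, mid + 10, mid - 15)) {
    v_on <- which(on[h + 1, ]) - 1
    r <- abs(h - mid)
    expect_equal(min(v_on), ceiling(spec$base_z))
    expect_equal(max(v_on), floor(spec$apex_z - r), tolerance = 1)
  }
})

test_that("the noiseless pipeline recovers the planted contact points", {
  spec <- bud_spec(40, "cone", base_radius = 200, apex_z = 400, seed = 9)
  sim <- simulate_pipeline(spec, 1)
  expect_equal(nrow(sim$contact_points$estimates), 40)
  ev <- evaluate_positions(sim$contact_points, sim$gt_points,
                           axis_xy = spec$center_xy)
  far <- ev$axis_distance > 20
  expect_lt(mean(ev$errors[far]), 1)
  nn_est <- nearest_floret_distances(sim$contact_points$estimates)
  nn_gt <- nearest_floret_distances(sim$gt_points)
  expect_lt(mean(abs(nn_est - nn_gt[ev$nearest_gt])[far]), 1)
})
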