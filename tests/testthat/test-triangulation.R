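test_that("triangulate_rays solves exact and skew intersections", {
  # exactly intersecting rays
  p <- triangulate_rays(list(ray(c(1, 0, 0), c(-1, 0, 0)),
                             ray(c(0, 1, 0), c(0, -1, 0))))
  expect_equal(p, c(0, 0, 0), tolerance = 1e-12)

  # skew rays: minimizing y^2 + z^2 + x^2 + (y - 1)^2 gives (0, 0.5, 0)
  skew <- list(ray(c(0, 0, 0), c(1, 0, 0)), ray(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(triangulate_rays(skew), c(0, 0.5, 0), tolerance = 1e-12)
  expect_equal(triangulate_rays(skew), grid_triangulate(skew),
               tolerance = 1e-4)
})

test_that("closed-form solution matches the brute-force grid oracle", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(2:4, 1)
    rays <- lapply(seq_len(n), function(j)
      ray(stats::runif(3), stats::rnorm(3)))
    # skip near-parallel draws the solver itself rejects
    x <- tryCatch(triangulate_rays(rays),
                  orbimetry_error_degenerate_geometry = function(e) NULL)
    if (is.null(x)) next
    if (max(abs(x)) > 2) next  # keep the optimum inside the search box
    expect_equal(x, grid_triangulate(rays, start = round(x, 1)),
                 tolerance = 1e-4)
  }
})

test_that("degenerate and underdetermined ray sets are rejected", {
  expect_error(triangulate_rays(list(ray(c(0, 0, 0), c(0, 0, 1)))),
               class = "orbimetry_error_too_few_rays")
  expect_error(triangulate_rays(list(ray(c(0, 0, 0), c(0, 0, 1)),
                                     ray(c(1, 0, 0), c(0, 0, 1)))),
               class = "orbimetry_error_degenerate_geometry")
})

test_that("ray order never changes the triangulated point", {
  set.seed(43)
  rays <- lapply(1:5, function(j) ray(stats::runif(3), stats::rnorm(3)))
  ref <- triangulate_rays(rays)
  for (i in 1:10)
    expect_equal(triangulate_rays(sample(rays)), ref, tolerance = 1e-12)
})

test_that("noise-free landmarks triangulate back to ground truth", {
  scn <- generate_scene(scene_spec(n_cameras = 5, n_points = 4, seed = 5))
  truth <- scn$ground_truth$points
  radius <- scn$ground_truth$spec$sphere_radius
  for (lab in rownames(truth)) {
    tri <- triangulate_landmark(scn$project,
                                scn$project$landmarks[[lab]]$observations)
    expect_lt(sqrt(sum((tri$point - truth[lab, ])^2)), 1e-6 * radius)
    expect_lt(tri$rms_reprojection_error, 1e-6)
    expect_gte(tri$n_views, 2)
  }
})

test_that("triangulate_landmark validates its observations", {
  scn <- generate_scene(scene_spec(n_cameras = 4, n_points = 2, seed = 6))
  one <- scn$project$landmarks$P01$observations[1, ]
  expect_error(triangulate_landmark(scn$project, one),
               class = "orbimetry_error_too_few_rays")
  bad <- data.frame(camera_id = c("CAM_001", "NOPE"), px = c(1, 2),
                    py = c(3, 4))
  expect_error(triangulate_landmark(scn$project, bad),
               class = "orbimetry_error_unknown_camera")
})

test_that("reprojection_error measures pixel residuals", {
  scn <- generate_scene(scene_spec(n_cameras = 6, n_points = 3, seed = 8))
  obs <- scn$project$landmarks$P02$observations
  truth <- scn$ground_truth$points["P02", ]
  expect_lt(reprojection_error(scn$project, obs, truth), 1e-8)

  # shifting every observation by +1 px in x gives an RMS of exactly 1
  shifted <- obs
  shifted$px <- shifted$px + 1
  expect_equal(reprojection_error(scn$project, shifted, truth), 1,
               tolerance = 1e-8)

  # random perturbations cross-checked against a direct per-view loop
  set.seed(9)
  noisy <- obs
  noisy$px <- noisy$px + stats::rnorm(nrow(noisy))
  noisy$py <- noisy$py + stats::rnorm(nrow(noisy))
  by_hand <- sqrt(mean(vapply(seq_len(nrow(noisy)), function(i) {
    cam <- get_camera(scn$project, noisy$camera_id[i])
    sum((project_point(cam, truth) - c(noisy$px[i], noisy$py[i]))^2)
  }, numeric(1))))
  expect_equal(reprojection_error(scn$project, noisy, truth), by_hand,
               tolerance = 1e-12)
})

test_that("a rigid motion of all cameras moves points rigidly", {
  scn <- generate_scene(scene_spec(n_cameras = 8, n_points = 5, seed = 10))
  set.seed(12)
  R0 <- random_rotation()
  t0 <- stats::rnorm(3, sd = 3)
  moved <- transform_project_poses(scn$project, R0, t0)

  labs <- rownames(scn$ground_truth$points)
  orig <- t(vapply(labs, function(l)
    triangulate_landmark(scn$project, scn$project$landmarks[[l]]$observations)$point,
    numeric(3)))
  new <- t(vapply(labs, function(l)
    triangulate_landmark(moved, moved$landmarks[[l]]$observations)$point,
    numeric(3)))

  expected <- t(R0 %*% t(orig) + t0)
  expect_equal(new, expected, tolerance = 1e-9)

  # inter-landmark distances are invariant
  expect_equal(as.numeric(stats::dist(new)), as.numeric(stats::dist(orig)),
               tolerance = 1e-9)
})

test_that("3D error shrinks as more views observe a noisy landmark", {
  # median over seeds of the error at 2 views vs all ~30 views
  err_at <- function(project, truth, obs, k) {
    tri <- triangulate_landmark(project, obs[seq_len(k), ])
    sqrt(sum((tri$point - truth)^2))
  }
  few <- c(); many <- c()
  for (seed in 1:6) {
    scn <- generate_scene(scene_spec(n_cameras = 30, n_points = 3,
                                     pixel_noise_sigma = 0.5, seed = seed))
    obs <- scn$project$landmarks$P01$observations
    truth <- scn$ground_truth$points["P01", ]
    few <- c(few, err_at(scn$project, truth, obs, 2))
    many <- c(many, err_at(scn$project, truth, obs, nrow(obs)))
  }
  expect_lt(stats::median(many), stats::median(few))
})

test_that("optional reprojection refinement stays near the linear solve", {
  scn <- generate_scene(scene_spec(n_cameras = 12, n_points = 3,
                                   pixel_noise_sigma = 0.5, seed = 14))
  obs <- scn$project$landmarks$P01$observations
  lin <- triangulate_landmark(scn$project, obs)
  ref <- triangulate_landmark(scn$project, obs, refine = TRUE)
  expect_lt(sqrt(sum((ref$point - lin$point)^2)), 1e-3)
  expect_lte(ref$rms_reprojection_error,
             lin$rms_reprojection_error + 1e-9)
})
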