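#' Intrinsics preset for the synthetic rig
#'
#' Loosely mirrors a 20 Mpx-class industrial sensor with a long focal
#' length, the kind of rig used on motorized specimen-digitization
#' scanners. The exact values are arbitrary; they only need to be
#' representative (narrow field of view, specimen filling a fraction of
#' the frame). Mild radial distortion is included by default so that the
#' full distortion path is exercised.
#'
#' @param k1,k2,k3,p1,p2 distortion coefficients of the preset.
#' @return an [intrinsics()] object.
#' @export
intrinsics_preset <- function(k1 = -0.05, k2 = 0.01, k3 = 0, p1 = 0, p2 = 0) {
  intrinsics(fx = 14500, fy = 14500,
             cx = (5472 - 1) / 2, cy = (3648 - 1) / 2,
             width = 5472, height = 3648,
             k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2)
}

#' Specification of a synthetic test scene
#'
#' Describes a virtual acquisition: cameras quasi-uniformly covering a
#' sphere, all aimed at the specimen at the center, a cloud of landmark
#' points inside an ellipsoidal specimen volume, and a calibration token
#' pair of exactly known physical separation. Pixel observations are the
#' true projections plus optional isotropic Gaussian noise.
#'
#' @param n_cameras number of cameras on the sphere (>= 2). The default
#'   matches a full acquisition of 180 views.
#' @param sphere_radius camera sphere radius in model units (>
#'   `specimen_extent`).
#' @param n_points number of specimen landmark points.
#' @param specimen_extent semi-major axis of the specimen ellipsoid in
#'   model units (points are sampled inside an ellipsoid with semi-axes
#'   `extent * c(1, 0.7, 0.5)`).
#' @param token_separation physical distance between the two token
#'   landmarks in mm (default 6.69, a hexagonal-bead scale token).
#' @param mm_per_unit ground-truth metric scale in mm per model unit.
#' @param pixel_noise_sigma standard deviation of the Gaussian pixel
#'   noise (px, >= 0).
#' @param seed RNG seed: identical specs produce identical scenes.
#' @param intrinsics camera intrinsics shared by all views.
#' @return an object of class `orbi_scene_spec`.
#' @section Errors: `invalid_spec`.
#' @export
scene_spec <- function(n_cameras = 180, sphere_radius = 10, n_points = 20,
                       specimen_extent = 1, token_separation = 6.69,
                       mm_per_unit = 5, pixel_noise_sigma = 0, seed = 1,
                       intrinsics = intrinsics_preset()) {
  if (!is_num(n_cameras) || n_cameras < 2)
    orbi_stop("invalid_spec", "n_cameras must be >= 2")
  if (!is_num(sphere_radius) || !is_num(specimen_extent) ||
      sphere_radius <= specimen_extent || specimen_extent <= 0)
    orbi_stop("invalid_spec", "need sphere_radius > specimen_extent > 0")
  if (!is_num(token_separation) || token_separation <= 0 ||
      !is_num(mm_per_unit) || mm_per_unit <= 0)
    orbi_stop("invalid_spec", "token_separation and mm_per_unit must be > 0")
  if (!is_num(pixel_noise_sigma) || pixel_noise_sigma < 0)
    orbi_stop("invalid_spec", "pixel_noise_sigma must be >= 0")
  if (!is_num(n_points) || n_points < 1)
    orbi_stop("invalid_spec", "n_points must be >= 1")
  stopifnot(inherits(intrinsics, "orbi_intrinsics"))
  structure(list(n_cameras = as.integer(n_cameras),
                 sphere_radius = sphere_radius, n_points = as.integer(n_points),
                 specimen_extent = specimen_extent,
                 token_separation = token_separation,
                 mm_per_unit = mm_per_unit,
                 pixel_noise_sigma = pixel_noise_sigma,
                 seed = as.integer(seed), intrinsics = intrinsics),
            class = "orbi_scene_spec")
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice),
# approximating a pan/tilt acquisition grid.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Camera directions for the acquisition sphere. Even counts are laid out
# as antipodal pairs of a half-density Fibonacci lattice so the centroid
# of the camera centers coincides with the sphere center to machine
# precision (an acquisition property the view-sphere logic relies on);
# odd counts fall back to the plain lattice.
camera_directions <- function(n) {
  if (n %% 2L == 0L) {
    half <- fibonacci_sphere(n %/% 2L)
    rbind(half, -half)
  } else {
    fibonacci_sphere(n)
  }
}

# World-to-camera pose for a camera at center C looking at `target`,
# right-handed, +z forward, y down in the image.
look_at_pose <- function(C, target = c(0, 0, 0)) {
  zc <- normalize(target - C)
  up <- if (abs(zc[3]) > 0.999) c(1, 0, 0) else c(0, 0, 1)
  xc <- normalize(c(zc[2] * up[3] - zc[3] * up[2],
                    zc[3] * up[1] - zc[1] * up[3],
                    zc[1] * up[2] - zc[2] * up[1]))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- rbind(xc, yc, zc, deparse.level = 0)
  pose(R, as.numeric(-R %*% C))
}

#' Generate a synthetic scene with ground truth
#'
#' Places cameras on a Fibonacci lattice over the acquisition sphere, all
#' posed to look at the origin; samples specimen points inside the
#' specimen ellipsoid; adds a token pair separated by exactly
#' `token_separation / mm_per_unit` model units; and records an
#' observation of every point in every camera where it projects with
#' positive depth inside the frame, with Gaussian pixel noise of the
#' requested sigma. The generator is deterministic in the spec (seed
#' included).
#'
#' @param spec an [scene_spec()].
#' @return a list with elements:
#'   \describe{
#'     \item{project}{an `orbi_project` holding the cameras and the
#'       landmarks with their (noisy) pixel observations,}
#'     \item{ground_truth}{list with `points` (matrix, rownames =
#'       landmark labels, model units), `mm_per_unit`, `token_labels`
#'       and the `spec`,}
#'     \item{observations}{the observation table
#'       (`landmark_label, camera_id, px, py`).}
#'   }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "orbi_scene_spec"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(spec$seed)

  dirs <- camera_directions(spec$n_cameras)
  cams <- lapply(seq_len(spec$n_cameras), function(i) {
    C <- spec$sphere_radius * dirs[i, ]
    camera(id = sprintf("CAM_%03d", i),
           image_ref = sprintf("images/view_%03d.jpg", i),
           intrinsics = spec$intrinsics,
           pose = look_at_pose(C))
  })
  project <- new_project(cams, image_dir = ".")

  # specimen points: rejection-sample inside the ellipsoid
  semi <- spec$specimen_extent * c(1, 0.7, 0.5)
  pts <- matrix(NA_real_, spec$n_points, 3)
  k <- 0L
  while (k < spec$n_points) {
    cand <- stats::runif(3, -1, 1)
    if (sum(cand^2) <= 1) {
      k <- k + 1L
      pts[k, ] <- cand * semi
    }
  }
  rownames(pts) <- sprintf("P%02d", seq_len(spec$n_points))

  token_units <- spec$token_separation / spec$mm_per_unit
  token <- rbind(TOKEN_A = c(-token_units / 2, 0, 0),
                 TOKEN_B = c(+token_units / 2, 0, 0))
  all_pts <- rbind(pts, token)

  obs <- list()
  W <- spec$intrinsics$width; H <- spec$intrinsics$height
  for (lab in rownames(all_pts)) {
    for (cm in cams) {
      px <- tryCatch(project_point(cm, all_pts[lab, ]),
                     orbimetry_error_non_positive_depth = function(e) NULL)
      if (is.null(px)) next
      if (spec$pixel_noise_sigma > 0)
        px <- px + stats::rnorm(2, sd = spec$pixel_noise_sigma)
      if (px[1] < 0 || px[1] > W - 1 || px[2] < 0 || px[2] > H - 1) next
      obs[[length(obs) + 1L]] <- data.frame(
        landmark_label = lab, camera_id = cm$id, px = px[1], py = px[2])
    }
  }
  obs <- do.call(rbind, obs)
  project <- add_observations(project, obs)

  list(project = project,
       ground_truth = list(points = all_pts, mm_per_unit = spec$mm_per_unit,
                           token_labels = c("TOKEN_A", "TOKEN_B"), spec = spec),
       observations = obs)
}

#' Triangulation recovery report against ground truth
#'
#' Triangulates every landmark of a (typically generated) project and
#' compares to the ground truth: per-point 3D error in model units and
#' mm, per-pair inter-landmark distance error versus the true distances,
#' and median/max summaries.
#'
#' @param project an `orbi_project` whose landmarks carry observations.
#' @param ground_truth the `ground_truth` element of [generate_scene()].
#' @return list with data.frames `points` (`label, error_units,
#'   error_mm`), `distances` (`label_a, label_b, true_mm, est_mm,
#'   error_mm, rel_error`) and a `summary` list (median/max of both).
#' @export
recovery_report <- function(project, ground_truth) {
  stopifnot(inherits(project, "orbi_project"))
  truth <- ground_truth$points
  mmu <- ground_truth$mm_per_unit
  labels <- intersect(rownames(truth), names(project$landmarks))
  est <- t(vapply(labels, function(lab) {
    triangulate_landmark(project, project$landmarks[[lab]]$observations)$point
  }, numeric(3)))
  err_units <- sqrt(rowSums((est - truth[labels, , drop = FALSE])^2))
  points <- data.frame(label = labels, error_units = err_units,
                       error_mm = mmu * err_units, row.names = NULL)
  pairs <- utils::combn(labels, 2)
  distances <- data.frame(
    label_a = pairs[1, ], label_b = pairs[2, ],
    true_mm = apply(pairs, 2, function(p)
      mmu * vnorm(truth[p[1], ] - truth[p[2], ])),
    est_mm = apply(pairs, 2, function(p)
      mmu * vnorm(est[p[1], ] - est[p[2], ])))
  distances$error_mm <- abs(distances$est_mm - distances$true_mm)
  distances$rel_error <- distances$error_mm / distances$true_mm
  list(points = points, distances = distances,
       summary = list(median_point_error_mm = stats::median(points$error_mm),
                      max_point_error_mm = max(points$error_mm),
                      median_distance_error_mm = stats::median(distances$error_mm),
                      max_distance_error_mm = max(distances$error_mm),
                      median_rel_distance_error = stats::median(distances$rel_error)))
}
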