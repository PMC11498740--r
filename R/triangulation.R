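#' Least-squares intersection of rays
#'
#' Finds the 3D point minimizing the sum of squared perpendicular
#' distances to a set of rays. The minimizer solves the 3x3 normal system
#' `sum_i (I - d_i d_i') x = sum_i (I - d_i d_i') o_i`, where `o_i`, `d_i`
#' are ray origins and unit directions; the solution is the closed-form
#' "midpoint" triangulation used when back-projected landmark rays do not
#' intersect exactly because of image noise and click error.
#'
#' @param rays a list of [ray()] objects, length >= 2.
#' @return length-3 numeric, the least-squares point in model units.
#' @section Errors: `too_few_rays` with fewer than two rays;
#'   `degenerate_geometry` when the rays are parallel or nearly so (the
#'   smallest eigenvalue of the system matrix is below 1e-9 times the
#'   largest).
#' @examples
#' r1 <- ray(c(1, 0, 0), c(-1, 0, 0))
#' r2 <- ray(c(0, 1, 0), c(0, -1, 0))
#' triangulate_rays(list(r1, r2))  # c(0, 0, 0)
#' @export
triangulate_rays <- function(rays) {
  if (!is.list(rays) || length(rays) < 2L)
    orbi_stop("too_few_rays", "triangulation needs at least 2 rays")
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  for (r in rays) {
    stopifnot(inherits(r, "orbi_ray"))
    P <- diag(3) - tcrossprod(r$direction)   # projector orthogonal to d
    A <- A + P
    b <- b + as.numeric(P %*% r$origin)
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9 * max(ev))
    orbi_stop("degenerate_geometry",
              "rays are (near-)parallel: triangulation system is rank-deficient")
  as.numeric(solve(A, b))
}

as_observations <- function(observations) {
  if (inherits(observations, "data.frame")) {
    need <- c("camera_id", "px", "py")
    miss <- setdiff(need, names(observations))
    if (length(miss))
      orbi_stop("schema", paste("observations missing column(s):",
                                paste(miss, collapse = ", ")))
    out <- observations[need]
    rownames(out) <- NULL
    return(out)
  }
  orbi_stop("schema", "observations must be a data.frame with camera_id, px, py")
}

#' Triangulate one landmark from its 2D observations
#'
#' Back-projects every pixel observation to a world ray and intersects the
#' rays in the least-squares sense ([triangulate_rays()]). Optionally the
#' linear solution is refined by Gauss-Newton minimization of the
#' reprojection error; the default is the linear solve, whose output is
#' the point closest to all rays.
#'
#' @param project an `orbi_project` (see [new_project()]).
#' @param observations data.frame with columns `camera_id`, `px`, `py`;
#'   at least two rows in distinct cameras.
#' @param refine if `TRUE`, run up to 20 Gauss-Newton iterations on the
#'   pixel reprojection residuals (default `FALSE`).
#' @return a list of class `orbi_triangulation` with elements `point`
#'   (length-3, model units), `rms_reprojection_error` (pixels) and
#'   `n_views`.
#' @section Errors: `too_few_rays`, `degenerate_geometry`,
#'   `unknown_camera`.
#' @export
triangulate_landmark <- function(project, observations, refine = FALSE) {
  obs <- as_observations(observations)
  obs <- obs[!duplicated(obs$camera_id), , drop = FALSE]
  if (nrow(obs) < 2L)
    orbi_stop("too_few_rays",
              "landmark must be observed in at least 2 distinct cameras")
  cams <- lapply(obs$camera_id, function(id) get_camera(project, id))
  rays <- mapply(function(cam, px, py) back_project(cam, c(px, py)),
                 cams, obs$px, obs$py, SIMPLIFY = FALSE)
  x <- triangulate_rays(rays)
  if (isTRUE(refine)) x <- refine_point(cams, obs, x)
  structure(list(point = x,
                 rms_reprojection_error = reprojection_error(project, obs, x),
                 n_views = nrow(obs)),
            class = "orbi_triangulation")
}

# Gauss-Newton on stacked pixel residuals; numerical Jacobian is adequate
# at these scales and keeps the update free of distortion-model derivatives.
refine_point <- function(cams, obs, x0, max_iter = 20L) {
  resid <- function(x) {
    unlist(mapply(function(cam, px, py) {
      project_point(cam, x) - c(px, py)
    }, cams, obs$px, obs$py, SIMPLIFY = FALSE))
  }
  x <- x0
  h <- 1e-6 * max(1, vnorm(x0))
  for (i in seq_len(max_iter)) {
    r0 <- resid(x)
    J <- vapply(1:3, function(j) {
      xp <- x; xp[j] <- xp[j] + h
      (resid(xp) - r0) / h
    }, numeric(length(r0)))
    step <- tryCatch(qr.solve(J, -r0), error = function(e) numeric(3))
    x <- x + step
    if (vnorm(step) < 1e-12 * max(1, vnorm(x))) break
  }
  x
}

#' Root-mean-square reprojection error of a 3D point
#'
#' Projects `point` into every observing camera and returns the RMS pixel
#' distance to the observed pixels — the standard quality metric for a
#' triangulated landmark.
#'
#' @inheritParams triangulate_landmark
#' @param point length-3 numeric, model units.
#' @return RMS error in pixels.
#' @export
reprojection_error <- function(project, observations, point) {
  obs <- as_observations(observations)
  point <- as.numeric(point)
  if (!is_num(point, 3L)) orbi_stop("schema", "point must be a finite 3-vector")
  d2 <- mapply(function(id, px, py) {
    pr <- project_point(get_camera(project, id), point)
    sum((pr - c(px, py))^2)
  }, obs$camera_id, obs$px, obs$py)
  sqrt(mean(d2))
}

#' Triangulate every landmark in a project
#'
#' Convenience wrapper: runs [triangulate_landmark()] for each landmark
#' having >= 2 observations and stores the resulting position (and, if the
#' project carries a scale calibration, the rescaled position in mm).
#'
#' @inheritParams triangulate_landmark
#' @return the project with landmark `position` (and `position_mm`) filled.
#' @export
triangulate_project <- function(project, refine = FALSE) {
  stopifnot(inherits(project, "orbi_project"))
  s <- project_scale(project)
  project$landmarks <- lapply(project$landmarks, function(lm) {
    if (nrow(lm$observations) >= 2L) {
      tri <- triangulate_landmark(project, lm$observations, refine = refine)
      lm$position <- tri$point
      lm$rms_reprojection_error <- tri$rms_reprojection_error
      lm$position_mm <- s * tri$point
    }
    lm
  })
  project
}

#' @export
print.orbi_triangulation <- function(x, ...) {
  cat(sprintf("<triangulated point> (%.6g, %.6g, %.6g), %d views, RMS reprojection %.4g px\n",
              x$point[1], x$point[2], x$point[3], x$n_views,
              x$rms_reprojection_error))
  invisible(x)
}
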