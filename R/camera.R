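#' Camera intrinsic parameters
#'
#' Pinhole intrinsics with Brown-Conrady lens distortion. Focal lengths and
#' the principal point are in pixels; distortion coefficients are
#' dimensionless and act on normalized image coordinates. All distortion
#' coefficients default to zero (an ideal pinhole).
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels (positive integers).
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return an object of class `orbi_intrinsics`.
#' @examples
#' intrinsics(fx = 1000, fy = 1000, cx = 500, cy = 500,
#'            width = 1000, height = 1000)
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height,
                       k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  for (nm in c("fx", "fy", "cx", "cy", "k1", "k2", "k3", "p1", "p2"))
    if (!is_num(get(nm))) orbi_stop("schema", sprintf("intrinsics$%s must be a finite number", nm))
  if (fx <= 0 || fy <= 0)
    orbi_stop("schema", "focal lengths fx, fy must be positive")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width <= 0 || height <= 0)
    orbi_stop("schema", "width and height must be positive integers")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height,
                 k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "orbi_intrinsics")
}

#' Camera pose (extrinsic parameters)
#'
#' A rigid world-to-camera transform: `X_cam = R %*% X + t`. `R` must be a
#' proper rotation (orthonormal, determinant +1). The camera center in
#' world coordinates is `-t(R) %*% t`.
#'
#' @param R 3x3 rotation matrix mapping world to camera coordinates.
#' @param t length-3 translation vector, in model units.
#' @return an object of class `orbi_pose`.
#' @seealso [camera_center()]
#' @export
pose <- function(R, t) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R)))
    orbi_stop("schema", "pose R must be a finite 3x3 matrix")
  t <- as.numeric(t)
  if (!is_num(t, 3L)) orbi_stop("schema", "pose t must be a finite 3-vector")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    orbi_stop("schema", "pose R is not orthonormal (R'R != I within 1e-9)")
  if (det(R) < 0)
    orbi_stop("schema", "pose R must be a proper rotation (det = +1)")
  dimnames(R) <- NULL
  structure(list(R = R, t = t), class = "orbi_pose")
}

#' One oriented camera (node of the view sphere)
#'
#' @param id unique camera identifier string.
#' @param intrinsics an [intrinsics()] object.
#' @param pose a [pose()] object.
#' @param image_ref relative path to the photograph this camera took. The
#'   image itself is never read; pixel coordinates are supplied as
#'   observations.
#' @return an object of class `orbi_camera`.
#' @export
camera <- function(id, intrinsics, pose, image_ref = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    orbi_stop("schema", "camera id must be a non-empty string")
  stopifnot(inherits(intrinsics, "orbi_intrinsics"), inherits(pose, "orbi_pose"))
  structure(list(id = id, image_ref = image_ref,
                 intrinsics = intrinsics, pose = pose),
            class = "orbi_camera")
}

#' A 3D ray (origin plus unit direction)
#'
#' @param origin length-3 numeric, in model units (typically a camera center).
#' @param direction length-3 numeric; normalized internally.
#' @return an object of class `orbi_ray` with unit-norm `direction`.
#' @export
ray <- function(origin, direction) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (!is_num(origin, 3L) || !is_num(direction, 3L))
    orbi_stop("schema", "ray origin and direction must be finite 3-vectors")
  structure(list(origin = origin, direction = normalize(direction)),
            class = "orbi_ray")
}

#' Camera center in world coordinates
#'
#' For a world-to-camera pose `X_cam = R %*% X + t`, the optical center `C`
#' satisfies `R %*% C + t = 0`, hence `C = -t(R) %*% t`.
#'
#' @param pose a [pose()] object.
#' @return length-3 numeric, the center in model units.
#' @export
camera_center <- function(pose) {
  stopifnot(inherits(pose, "orbi_pose"))
  as.numeric(-crossprod(pose$R, pose$t))
}

#' Apply Brown-Conrady distortion to normalized coordinates
#'
#' Maps ideal normalized image coordinates `(x, y)` (i.e. `X_cam/Z_cam`) to
#' distorted normalized coordinates:
#' radial factor `1 + k1 r^2 + k2 r^4 + k3 r^6` plus the tangential terms
#' with `p1`, `p2`. With all coefficients zero this is the identity, and
#' the origin (principal axis) is always a fixed point.
#'
#' @param intr an [intrinsics()] object (only its distortion coefficients
#'   are used).
#' @param p_norm length-2 numeric, normalized undistorted coordinates.
#' @return length-2 numeric, distorted normalized coordinates.
#' @export
distort_point <- function(intr, p_norm) {
  stopifnot(inherits(intr, "orbi_intrinsics"))
  p_norm <- as.numeric(p_norm)
  if (!is_num(p_norm, 2L)) orbi_stop("schema", "p_norm must be a finite 2-vector")
  x <- p_norm[1]; y <- p_norm[2]
  r2 <- x * x + y * y
  radial <- 1 + r2 * (intr$k1 + r2 * (intr$k2 + r2 * intr$k3))
  c(x * radial + 2 * intr$p1 * x * y + intr$p2 * (r2 + 2 * x * x),
    y * radial + intr$p1 * (r2 + 2 * y * y) + 2 * intr$p2 * x * y)
}

#' Undistort a pixel to normalized coordinates
#'
#' Inverts the intrinsic mapping: converts the pixel to distorted
#' normalized coordinates and solves for the undistorted coordinates by
#' fixed-point iteration (initial guess = distorted value), so that
#' re-distorting and re-projecting the result reproduces the input pixel.
#'
#' @param intr an [intrinsics()] object.
#' @param pixel length-2 numeric pixel coordinates.
#' @param tol convergence tolerance on successive iterates (default 1e-10).
#' @param max_iter iteration cap (default 100); exceeded only for
#'   pathological coefficients, in which case a `no_convergence` error is
#'   raised.
#' @return length-2 numeric, undistorted normalized coordinates.
#' @export
undistort_pixel <- function(intr, pixel, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(intr, "orbi_intrinsics"))
  pixel <- as.numeric(pixel)
  if (!is_num(pixel, 2L)) orbi_stop("schema", "pixel must be a finite 2-vector")
  xd <- (pixel[1] - intr$cx) / intr$fx
  yd <- (pixel[2] - intr$cy) / intr$fy
  if (intr$k1 == 0 && intr$k2 == 0 && intr$k3 == 0 &&
      intr$p1 == 0 && intr$p2 == 0) return(c(xd, yd))
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x * x + y * y
    radial <- 1 + r2 * (intr$k1 + r2 * (intr$k2 + r2 * intr$k3))
    dx <- 2 * intr$p1 * x * y + intr$p2 * (r2 + 2 * x * x)
    dy <- intr$p1 * (r2 + 2 * y * y) + 2 * intr$p2 * x * y
    x_new <- (xd - dx) / radial
    y_new <- (yd - dy) / radial
    if (max(abs(x_new - x), abs(y_new - y)) < tol) return(c(x_new, y_new))
    x <- x_new; y <- y_new
  }
  orbi_stop("no_convergence",
            sprintf("undistortion did not converge in %d iterations", max_iter))
}

#' Project a world point into a camera
#'
#' Forward pinhole model: transform to the camera frame, perspective
#' divide, apply lens distortion, then map to pixels with the focal
#' lengths and principal point.
#'
#' @param camera an [camera()] object.
#' @param point_world length-3 numeric, in model units.
#' @return length-2 numeric pixel coordinates.
#' @section Errors: `non_positive_depth` if the point is behind or on the
#'   camera plane (`z_cam <= 0`).
#' @export
project_point <- function(camera, point_world) {
  stopifnot(inherits(camera, "orbi_camera"))
  point_world <- as.numeric(point_world)
  if (!is_num(point_world, 3L)) orbi_stop("schema", "point_world must be a finite 3-vector")
  pc <- as.numeric(camera$pose$R %*% point_world + camera$pose$t)
  if (pc[3] <= 0)
    orbi_stop("non_positive_depth",
              sprintf("point has non-positive depth z_cam = %g in camera '%s'",
                      pc[3], camera$id))
  pd <- distort_point(camera$intrinsics, pc[1:2] / pc[3])
  c(camera$intrinsics$fx * pd[1] + camera$intrinsics$cx,
    camera$intrinsics$fy * pd[2] + camera$intrinsics$cy)
}

#' Back-project a pixel to a world ray
#'
#' The landmark clicked at a pixel constrains the 3D point to the ray
#' through the camera center and that pixel on the image plane. The ray
#' origin is the camera center; the direction is the undistorted viewing
#' direction rotated into world coordinates.
#'
#' @param camera an [camera()] object.
#' @param pixel length-2 numeric pixel coordinates.
#' @return an [ray()] with unit direction.
#' @export
back_project <- function(camera, pixel) {
  stopifnot(inherits(camera, "orbi_camera"))
  u <- undistort_pixel(camera$intrinsics, pixel)
  dir_world <- as.numeric(crossprod(camera$pose$R, c(u, 1)))
  ray(origin = camera_center(camera$pose), direction = dir_world)
}

#' @export
print.orbi_camera <- function(x, ...) {
  C <- camera_center(x$pose)
  cat(sprintf("<camera '%s'> %dx%d px, fx=%.6g fy=%.6g, center (%.4g, %.4g, %.4g)\n",
              x$id, x$intrinsics$width, x$intrinsics$height,
              x$intrinsics$fx, x$intrinsics$fy, C[1], C[2], C[3]))
  invisible(x)
}
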