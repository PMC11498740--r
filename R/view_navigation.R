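#' Build the view sphere of a project
#'
#' Summarizes the acquisition geometry for pseudo-3D navigation: the
#' sphere center is the centroid of the camera centers and each camera is
#' represented by the unit direction from that center to its optical
#' center.
#'
#' @param project an `orbi_project` with at least one camera.
#' @return an object of class `orbi_view_sphere` with elements `center`
#'   (length 3), `directions` (n x 3 matrix, unit rows, rownames = camera
#'   ids) and `radii` (distance of each camera from the center).
#' @section Errors: `empty_project` with no cameras; `degenerate_sphere`
#'   if any camera coincides with the center (e.g. a single camera).
#' @export
build_view_sphere <- function(project) {
  stopifnot(inherits(project, "orbi_project"))
  if (!length(project$cameras))
    orbi_stop("empty_project", "project has no cameras")
  centers <- t(vapply(project$cameras, function(cm) camera_center(cm$pose),
                      numeric(3)))
  center <- colMeans(centers)
  offsets <- sweep(centers, 2, center)
  radii <- sqrt(rowSums(offsets^2))
  if (any(radii == 0))
    orbi_stop("degenerate_sphere",
              "a camera center coincides with the sphere center")
  structure(list(center = center,
                 directions = offsets / radii,
                 radii = radii),
            class = "orbi_view_sphere")
}

#' Retrieve the acquired image nearest to a viewing direction
#'
#' Nearest-neighbor search on the view sphere: returns the camera whose
#' direction has the smallest angle to the query (maximum dot product).
#' Ties are broken by the lexicographically smallest camera id, so output
#' is deterministic.
#'
#' @param sphere an [build_view_sphere()] result.
#' @param query length-3 viewing direction (any non-zero length; it is
#'   normalized internally, so the result is scale-invariant).
#' @return the camera id (character).
#' @section Errors: `zero_vector_query` for a zero query vector.
#' @export
nearest_view <- function(sphere, query) {
  stopifnot(inherits(sphere, "orbi_view_sphere"))
  query <- as.numeric(query)
  if (!is_num(query, 3L) || vnorm(query) == 0)
    orbi_stop("zero_vector_query", "query must be a non-zero finite 3-vector")
  q <- query / vnorm(query)
  dots <- as.numeric(sphere$directions %*% q)
  ids <- rownames(sphere$directions)
  best <- dots >= max(dots) - 1e-15
  sort(ids[best])[1]
}

#' Unit direction from longitude/latitude angles
#'
#' Math convention: longitude measured in the x-y plane from +x toward
#' +y, latitude from the equator toward +z, both in degrees, so
#' `(0, 0) -> (1, 0, 0)` and `(0, 90) -> (0, 0, 1)`.
#'
#' @param longitude degrees.
#' @param latitude degrees, in `[-90, 90]`.
#' @return length-3 unit vector.
#' @section Errors: `latitude_out_of_range`.
#' @export
direction_from_angles <- function(longitude, latitude) {
  if (!is_num(longitude) || !is_num(latitude))
    orbi_stop("schema", "longitude and latitude must be finite numbers")
  if (latitude < -90 || latitude > 90)
    orbi_stop("latitude_out_of_range", "latitude must be in [-90, 90] degrees")
  lon <- longitude * pi / 180
  lat <- latitude * pi / 180
  c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

#' Standard anatomical view names
#' @return character vector of the six supported view names.
#' @export
standard_view_names <- function() {
  c("frontal", "posterior", "superior", "inferior",
    "left_lateral", "right_lateral")
}

#' Assign a camera to a named standard view
#'
#' Taxonomists publish specimens in six conventional orientations; a
#' project can bookmark the camera matching each one for one-click
#' navigation.
#'
#' @param project an `orbi_project`.
#' @param view one of [standard_view_names()].
#' @param camera_id id of an existing project camera.
#' @return the updated project.
#' @export
set_standard_view <- function(project, view, camera_id) {
  stopifnot(inherits(project, "orbi_project"))
  view <- match.arg(view, standard_view_names())
  get_camera(project, camera_id)  # errors with unknown_camera if absent
  project$standard_views[[view]] <- camera_id
  project
}
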