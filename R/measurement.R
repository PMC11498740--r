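#' Scale factor from a calibration token
#'
#' Bundle-adjusted camera poses fix geometry only up to a global scale;
#' an object of known physical size photographed with the specimen (e.g.
#' a hexagonal bead whose reference points are 6.69 mm apart) anchors the
#' metric scale. The factor is simply mm per model unit.
#'
#' @param model_distance distance between the token landmarks in model
#'   units (> 0).
#' @param known_distance physical distance in mm (> 0).
#' @return the scale `s = known_distance / model_distance` in mm/unit.
#' @section Errors: `non_positive_distance`.
#' @examples
#' scale_factor(2.0, 6.69)  # 3.345 mm per model unit
#' @export
scale_factor <- function(model_distance, known_distance) {
  if (!is_num(model_distance) || model_distance <= 0)
    orbi_stop("non_positive_distance", "model_distance must be > 0")
  if (!is_num(known_distance) || known_distance <= 0)
    orbi_stop("non_positive_distance", "known_distance must be > 0")
  known_distance / model_distance
}

#' Scaled Euclidean distance between two points
#'
#' Full-precision scaled distance `s * ||a - b||`. Rounding to 0.01 mm
#' (caliper precision) is applied only at the reporting layer; see
#' [round_half_up()].
#'
#' @param a,b length-3 points in model units.
#' @param s scale in mm per model unit (default 1: model units out).
#' @return distance in mm (unrounded).
#' @export
point_distance <- function(a, b, s = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!is_num(a, 3L) || !is_num(b, 3L))
    orbi_stop("schema", "a and b must be finite 3-vectors")
  s * vnorm(a - b)
}

#' Rescale landmark positions to mm
#'
#' Sets `position_mm = s * position` on every landmark that has a
#' triangulated position. Idempotent when re-applied with the same `s`
#' (it always starts from the model-unit position).
#'
#' @param landmarks a list of landmark records (as stored in a project).
#' @param s scale in mm per model unit.
#' @return the updated landmark list.
#' @export
apply_scale <- function(landmarks, s) {
  if (!is_num(s) || s <= 0) orbi_stop("non_positive_distance", "scale s must be > 0")
  lapply(landmarks, function(lm) {
    if (!is.null(lm$position)) lm$position_mm <- s * lm$position
    lm
  })
}

#' Calibrate a project's metric scale on a landmark pair
#'
#' Computes the scale factor from the model-unit distance between two
#' triangulated landmarks (the calibration token pair) and the known
#' physical distance, stores it in the project and rescales every
#' landmark. Token landmarks are ordinary landmarks; no special token
#' geometry is fitted.
#'
#' @param project an `orbi_project` whose token landmarks are
#'   triangulated.
#' @param label_a,label_b labels of the calibration pair.
#' @param known_distance physical distance between them in mm (> 0).
#' @return the calibrated project.
#' @export
calibrate_scale <- function(project, label_a, label_b, known_distance) {
  stopifnot(inherits(project, "orbi_project"))
  pa <- project$landmarks[[label_a]]$position
  pb <- project$landmarks[[label_b]]$position
  if (is.null(pa) || is.null(pb))
    orbi_stop("schema",
              "both calibration landmarks must exist and be triangulated")
  s <- scale_factor(point_distance(pa, pb), known_distance)
  project$scale <- list(landmark_a = label_a, landmark_b = label_b,
                        known_distance_mm = known_distance, scale_factor = s)
  project$landmarks <- apply_scale(project$landmarks, s)
  project
}

#' Measure the distance between two landmarks of a project
#'
#' @param project an `orbi_project` with both landmarks triangulated.
#' @param label_a,label_b landmark labels.
#' @param rounded report rounded to 0.01 mm (default `TRUE`, caliper
#'   precision); set `FALSE` for the full-precision value.
#' @return distance in mm (model units if the project is uncalibrated).
#' @export
measure_distance <- function(project, label_a, label_b, rounded = TRUE) {
  stopifnot(inherits(project, "orbi_project"))
  pa <- project$landmarks[[label_a]]$position
  pb <- project$landmarks[[label_b]]$position
  if (is.null(pa) || is.null(pb))
    orbi_stop("schema", "both landmarks must exist and be triangulated")
  d <- point_distance(pa, pb, project_scale(project))
  if (isTRUE(rounded)) round_half_up(d) else d
}
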