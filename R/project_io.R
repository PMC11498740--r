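#' Create an empty project
#'
#' A project bundles the oriented cameras of one acquisition sphere with
#' landmarks, an optional scale calibration and named standard views. It
#' is the unit serialized by [write_project()] / [read_project()].
#'
#' @param cameras list of [camera()] objects with unique ids.
#' @param image_dir directory (relative or absolute) that camera
#'   `image_ref` paths are relative to. Images are never read.
#' @return an object of class `orbi_project`.
#' @export
new_project <- function(cameras = list(), image_dir = ".") {
  ids <- vapply(cameras, function(cm) cm$id, character(1))
  if (anyDuplicated(ids))
    orbi_stop("schema", "camera ids must be unique within a project")
  names(cameras) <- ids
  structure(list(schema_version = 1L,
                 image_dir = image_dir,
                 cameras = cameras,
                 landmarks = list(),
                 scale = NULL,
                 standard_views = list()),
            class = "orbi_project")
}

#' Look up a camera by id
#'
#' @param project an `orbi_project`.
#' @param id camera id string.
#' @return the [camera()] object.
#' @section Errors: `unknown_camera` if the id is not in the project.
#' @export
get_camera <- function(project, id) {
  stopifnot(inherits(project, "orbi_project"))
  cam <- project$cameras[[id]]
  if (is.null(cam))
    orbi_stop("unknown_camera", sprintf("camera '%s' is not in the project", id))
  cam
}

#' Add a landmark (or observations to an existing one)
#'
#' @param project an `orbi_project`.
#' @param label landmark label, unique within the project.
#' @param observations data.frame with columns `camera_id`, `px`, `py`
#'   (may be empty); every camera id must exist in the project.
#' @param color display color associated with the landmark.
#' @return the updated project.
#' @export
add_landmark <- function(project, label, observations = NULL, color = "#ff0000") {
  stopifnot(inherits(project, "orbi_project"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    orbi_stop("schema", "landmark label must be a non-empty string")
  if (is.null(observations))
    observations <- data.frame(camera_id = character(), px = numeric(),
                               py = numeric())
  observations <- as_observations(observations)
  unknown <- setdiff(unique(observations$camera_id), names(project$cameras))
  if (length(unknown))
    orbi_stop("unknown_camera",
              paste("observation(s) reference unknown camera(s):",
                    paste(unknown, collapse = ", ")))
  lm <- project$landmarks[[label]]
  if (is.null(lm))
    lm <- list(label = label, color = color, observations = observations,
               position = NULL, position_mm = NULL,
               rms_reprojection_error = NULL)
  else {
    lm$observations <- rbind(lm$observations, observations)
    rownames(lm$observations) <- NULL
  }
  project$landmarks[[label]] <- lm
  project
}

# mm-per-model-unit factor of the project; 1 when uncalibrated so that
# "mm" outputs fall back to model units.
project_scale <- function(project) {
  if (is.null(project$scale)) 1 else project$scale$scale_factor
}

# ---- JSON serialization -------------------------------------------------

camera_to_list <- function(cm) {
  list(id = cm$id, image_ref = cm$image_ref,
       intrinsics = unclass(cm$intrinsics),
       pose = list(R = cm$pose$R, t = cm$pose$t))
}

camera_from_list <- function(x, where) {
  for (f in c("id", "intrinsics", "pose"))
    if (is.null(x[[f]]))
      orbi_stop("schema", sprintf("missing key '%s' in %s", f, where))
  intr <- x$intrinsics
  for (f in c("fx", "fy", "cx", "cy", "width", "height"))
    if (is.null(intr[[f]]))
      orbi_stop("schema", sprintf("missing key 'intrinsics.%s' in %s", f, where))
  dist <- lapply(c(k1 = "k1", k2 = "k2", k3 = "k3", p1 = "p1", p2 = "p2"),
                 function(f) if (is.null(intr[[f]])) 0 else intr[[f]])
  camera(id = x$id,
         image_ref = if (is.null(x$image_ref)) NA_character_ else x$image_ref,
         intrinsics = intrinsics(intr$fx, intr$fy, intr$cx, intr$cy,
                                 intr$width, intr$height,
                                 dist$k1, dist$k2, dist$k3, dist$p1, dist$p2),
         # JSON stores the matrix as three row arrays
         pose = pose(matrix(unlist(x$pose$R), 3, 3, byrow = TRUE),
                     as.numeric(unlist(x$pose$t))))
}

#' Write a project to a JSON file
#'
#' Numbers are written at full double precision so that
#' `read_project(write_project(p))` reproduces every numeric field
#' exactly.
#'
#' @param project an `orbi_project`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_project <- function(project, path) {
  stopifnot(inherits(project, "orbi_project"))
  doc <- list(
    schema_version = project$schema_version,
    image_dir = project$image_dir,
    cameras = lapply(unname(project$cameras), camera_to_list),
    landmarks = lapply(unname(project$landmarks), function(lm) {
      list(label = lm$label, color = lm$color,
           observations = lm$observations,
           position = lm$position, position_mm = lm$position_mm,
           rms_reprojection_error = lm$rms_reprojection_error)
    }),
    scale = project$scale,
    standard_views = project$standard_views)
  # digits = I(17): 17 *significant* digits, enough for an exact
  # text-decimal round trip of IEEE doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a project from a JSON file
#'
#' @param path path to a project file written by [write_project()].
#' @return an `orbi_project`.
#' @section Errors: `schema` naming the missing/invalid field;
#'   `version_unsupported` for a schema version this package does not
#'   read.
#' @export
read_project <- function(path) {
  if (!file.exists(path))
    orbi_stop("schema", sprintf("project file '%s' does not exist", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    orbi_stop("schema", "missing key 'schema_version'")
  if (!identical(as.integer(doc$schema_version), 1L))
    orbi_stop("version_unsupported",
              sprintf("unsupported project schema version '%s'",
                      doc$schema_version))
  if (is.null(doc$cameras))
    orbi_stop("schema", "missing key 'cameras'")
  cams <- lapply(seq_along(doc$cameras), function(i)
    camera_from_list(doc$cameras[[i]], sprintf("cameras[%d]", i)))
  proj <- new_project(cams, image_dir = if (is.null(doc$image_dir)) "." else doc$image_dir)
  for (lm in doc$landmarks) {
    if (is.null(lm$label)) orbi_stop("schema", "landmark without 'label'")
    obs <- lm$observations
    obs_df <- if (is.null(obs) || length(obs) == 0L ||
                  length(obs$camera_id) == 0L)
      NULL
    else
      data.frame(camera_id = unlist(obs$camera_id),
                 px = as.numeric(unlist(obs$px)),
                 py = as.numeric(unlist(obs$py)))
    proj <- add_landmark(proj, lm$label, obs_df,
                         color = if (is.null(lm$color)) "#ff0000" else lm$color)
    if (!is.null(lm$position))
      proj$landmarks[[lm$label]]$position <- as.numeric(unlist(lm$position))
    if (!is.null(lm$position_mm))
      proj$landmarks[[lm$label]]$position_mm <- as.numeric(unlist(lm$position_mm))
    if (!is.null(lm$rms_reprojection_error))
      proj$landmarks[[lm$label]]$rms_reprojection_error <-
        as.numeric(lm$rms_reprojection_error)
  }
  if (!is.null(doc$scale))
    proj$scale <- list(landmark_a = doc$scale$landmark_a,
                       landmark_b = doc$scale$landmark_b,
                       known_distance_mm = as.numeric(doc$scale$known_distance_mm),
                       scale_factor = as.numeric(doc$scale$scale_factor))
  if (length(doc$standard_views))
    for (v in names(doc$standard_views))
      proj <- set_standard_view(proj, v, doc$standard_views[[v]])
  proj
}

# ---- calibration import -------------------------------------------------

#' Import cameras from photogrammetry calibration exports
#'
#' Builds cameras from the two-file layout photogrammetry suites export
#' after bundle adjustment: a JSON intrinsics file and a CSV extrinsics
#' table. The intrinsics file holds either a single intrinsics object
#' (shared by all cameras) or a map from sensor id to intrinsics objects;
#' absent distortion coefficients are treated as zero. The extrinsics CSV
#' has columns `camera_id, image, sensor_id, r11..r33, tx, ty, tz`
#' (rotation in row-major order).
#'
#' @param intrinsics_file path to the JSON intrinsics file.
#' @param extrinsics_file path to the CSV extrinsics file.
#' @param dialect rotation/translation convention of the extrinsics rows:
#'   `"world_to_camera"` (default; `X_cam = R X + t`) or
#'   `"camera_to_world"` (rows store the camera-to-world rotation and the
#'   camera center `C`; converted internally to `R' = t(R)`,
#'   `t' = -t(R) C`).
#' @return a list of [camera()] objects.
#' @section Errors: `parse` for unreadable files; `missing_intrinsics`
#'   when an extrinsic row references an undefined sensor id.
#' @export
import_calibration <- function(intrinsics_file, extrinsics_file,
                               dialect = c("world_to_camera", "camera_to_world")) {
  dialect <- match.arg(dialect)
  intr_doc <- tryCatch(jsonlite::read_json(intrinsics_file, simplifyVector = FALSE),
                       error = function(e) orbi_stop("parse", conditionMessage(e)))
  ext <- tryCatch(utils::read.csv(extrinsics_file, stringsAsFactors = FALSE),
                  error = function(e) orbi_stop("parse", conditionMessage(e)))
  need <- c("camera_id", "image", "sensor_id",
            paste0("r", outer(1:3, 1:3, paste0)), "tx", "ty", "tz")
  miss <- setdiff(need, names(ext))
  if (length(miss))
    orbi_stop("parse", paste("extrinsics CSV missing column(s):",
                             paste(miss, collapse = ", ")))
  make_intr <- function(x) {
    dist <- lapply(c(k1 = "k1", k2 = "k2", k3 = "k3", p1 = "p1", p2 = "p2"),
                   function(f) if (is.null(x[[f]])) 0 else x[[f]])
    intrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height,
               dist$k1, dist$k2, dist$k3, dist$p1, dist$p2)
  }
  shared <- !is.null(intr_doc$fx)  # single intrinsics object, shared
  intr_map <- if (shared) NULL else lapply(intr_doc, make_intr)
  shared_intr <- if (shared) make_intr(intr_doc) else NULL
  lapply(seq_len(nrow(ext)), function(i) {
    row <- ext[i, ]
    intr <- if (shared) shared_intr else {
      found <- intr_map[[as.character(row$sensor_id)]]
      if (is.null(found))
        orbi_stop("missing_intrinsics",
                  sprintf("extrinsics row %d references undefined sensor id '%s'",
                          i, row$sensor_id))
      found
    }
    R <- matrix(as.numeric(row[paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33))]),
                3, 3, byrow = TRUE)
    t3 <- as.numeric(row[c("tx", "ty", "tz")])
    if (dialect == "camera_to_world") {
      t3 <- as.numeric(-crossprod(R, t3))  # t = -R_wc C with R_wc = t(R_cw)
      R <- t(R)
    }
    camera(id = as.character(row$camera_id), image_ref = as.character(row$image),
           intrinsics = intr, pose = pose(R, t3))
  })
}

# ---- observation / landmark CSV ----------------------------------------

#' Read a landmark observation CSV
#'
#' Expected columns: `landmark_label, camera_id, px, py` — one row per
#' 2D pick of a landmark in an image.
#'
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_observations_csv <- function(path) {
  obs <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) orbi_stop("parse", conditionMessage(e)))
  need <- c("landmark_label", "camera_id", "px", "py")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    orbi_stop("parse", paste("observation CSV missing column(s):",
                             paste(miss, collapse = ", ")))
  obs[need]
}

#' Attach a table of observations to a project
#'
#' @param project an `orbi_project`.
#' @param obs data.frame as returned by [read_observations_csv()].
#' @return the updated project.
#' @export
add_observations <- function(project, obs) {
  for (label in unique(obs$landmark_label)) {
    sub <- obs[obs$landmark_label == label, c("camera_id", "px", "py")]
    project <- add_landmark(project, label, sub)
  }
  project
}

#' Export triangulated landmarks as a coordinate CSV
#'
#' Writes one row per triangulated landmark with header
#' `label,x,y,z,x_mm,y_mm,z_mm`: raw model-unit coordinates plus the
#' rescaled metric coordinates. The mm columns are reported rounded to
#' 0.01 mm ([round_half_up()]); with no scale calibration the scale
#' defaults to 1 and the mm columns repeat the model-unit values
#' (rounded). The file is a plain coordinate table readable by geometric
#' morphometrics tooling.
#'
#' @param project an `orbi_project` with triangulated landmarks.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @section Errors: `nothing_to_export` when no landmark has a 3D
#'   position.
#' @export
export_landmarks_csv <- function(project, path) {
  stopifnot(inherits(project, "orbi_project"))
  lms <- Filter(function(lm) !is.null(lm$position), project$landmarks)
  if (!length(lms))
    orbi_stop("nothing_to_export", "no landmark has a triangulated 3D position")
  s <- project_scale(project)
  rows <- do.call(rbind, lapply(lms, function(lm) {
    mm <- if (is.null(lm$position_mm)) s * lm$position else lm$position_mm
    data.frame(label = lm$label,
               x = lm$position[1], y = lm$position[2], z = lm$position[3],
               x_mm = round_half_up(mm[1]), y_mm = round_half_up(mm[2]),
               z_mm = round_half_up(mm[3]))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.orbi_project <- function(x, ...) {
  cat(sprintf("<orbimetry project> %d cameras, %d landmarks%s\n",
              length(x$cameras), length(x$landmarks),
              if (is.null(x$scale)) " (uncalibrated)"
              else sprintf(", scale %.6g mm/unit", x$scale$scale_factor)))
  invisible(x)
}
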