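#' Scapula models: mesh plus named anatomical landmarks
#'
#' A `scapula_model` bundles a watertight [trimesh] with the named landmarks
#' required by the planning pipeline and the keep-out radii of the
#' suprascapular and spinoglenoid notches.
#'
#' Mandatory landmarks: `supraglenoid_tubercle`, `inferior_glenoid_margin`,
#' at least 8 `glenoid_rim_point_<i>`, `trigonum_spinae`, `inferior_angle`,
#' `spine_confluence`, `suprascapular_notch_center`,
#' `spinoglenoid_notch_center`.
#'
#' @param mesh a [trimesh].
#' @param landmarks named list of length-3 numeric positions (mm).
#' @param keep_out_radii named numeric vector (mm), one entry per notch
#'   landmark; strictly positive.
#' @param case_id character identifier.
#' @param sex `"F"` or `"M"`.
#' @param age years.
#' @param validate check landmark completeness and surface proximity.
#' @param surface_tol maximal admissible landmark distance from the surface
#'   (mm).
#' @return An object of class `scapula_model`.
#' @export
scapula_model <- function(mesh, landmarks, keep_out_radii =
                            c(suprascapular_notch_center = 5,
                              spinoglenoid_notch_center = 5),
                          case_id = "case", sex = c("F", "M"), age = NA_real_,
                          validate = TRUE, surface_tol = 2) {
  sex <- match.arg(sex)
  obj <- structure(list(mesh = mesh, landmarks = landmarks,
                        keep_out_radii = keep_out_radii,
                        case_id = case_id, sex = sex, age = age),
                   class = "scapula_model")
  if (validate) validate_scapula(obj, surface_tol = surface_tol)
  obj
}

mandatory_landmarks <- function() {
  c("supraglenoid_tubercle", "inferior_glenoid_margin", "trigonum_spinae",
    "inferior_angle", "spine_confluence", "suprascapular_notch_center",
    "spinoglenoid_notch_center")
}

rim_point_names <- function(landmarks)
  grep("^glenoid_rim_point_", names(landmarks), value = TRUE)

#' @rdname scapula_model
#' @export
validate_scapula <- function(mesh, surface_tol = 2) {
  s <- mesh
  stopifnot(inherits(s, "scapula_model"))
  nm <- names(s$landmarks)
  if (anyDuplicated(nm)) stop("duplicate landmark names")
  miss <- setdiff(mandatory_landmarks(), nm)
  if (length(miss)) stop("missing landmarks: ", paste(miss, collapse = ", "))
  if (length(rim_point_names(s$landmarks)) < 8)
    stop("at least 8 glenoid rim points are required")
  if (any(s$keep_out_radii <= 0)) stop("keep_out_radii must be positive")
  p <- do.call(rbind, s$landmarks)
  d <- point_mesh_distance(s$mesh, p)
  if (any(d > surface_tol))
    stop(sprintf("landmark(s) further than %.1f mm from the surface: %s",
                 surface_tol, paste(nm[d > surface_tol], collapse = ", ")))
  invisible(s)
}

#' @export
print.scapula_model <- function(x, ...) {
  cat(sprintf("scapula_model '%s' (%s, %.0f y): %d faces, %d landmarks\n",
              x$case_id, x$sex, x$age, nrow(x$mesh$faces),
              length(x$landmarks)))
  invisible(x)
}

rim_points <- function(scapula) {
  nm <- rim_point_names(scapula$landmarks)
  do.call(rbind, scapula$landmarks[nm])
}

#' Landmark file I/O
#'
#' Landmarks travel as JSON:
#' `{case_id, sex, age, landmarks: [{name, xyz}], keep_out_radii: {name: mm}}`.
#' The mesh travels separately (STL/PLY/OBJ); the landmark file is the sole
#' source of anatomical orientation.
#'
#' @param scapula a [scapula_model].
#' @param path JSON path.
#' @return `read_landmarks` returns a list with everything except the mesh;
#'   combine with [load_mesh] via [scapula_model].
#' @export
write_landmarks <- function(scapula, path) {
  obj <- list(
    case_id = scapula$case_id, sex = scapula$sex, age = scapula$age,
    landmarks = lapply(names(scapula$landmarks), function(n)
      list(name = n, xyz = as.numeric(scapula$landmarks[[n]]))),
    keep_out_radii = as.list(scapula$keep_out_radii))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lms <- stats::setNames(
    lapply(obj$landmarks, function(l) as.numeric(unlist(l$xyz))),
    vapply(obj$landmarks, function(l) l$name, character(1)))
  list(case_id = obj$case_id, sex = obj$sex, age = as.numeric(obj$age),
       landmarks = lms,
       keep_out_radii = unlist(obj$keep_out_radii))
}

#' Load a scapula case from mesh + landmark files
#'
#' @param mesh_path STL/PLY/OBJ file.
#' @param landmark_path JSON landmark file.
#' @param ... passed to [load_mesh].
#' @return A [scapula_model].
#' @export
load_scapula <- function(mesh_path, landmark_path, ...) {
  mesh <- load_mesh(mesh_path, ...)
  lm <- read_landmarks(landmark_path)
  scapula_model(mesh, lm$landmarks, keep_out_radii = lm$keep_out_radii,
                case_id = lm$case_id, sex = lm$sex, age = lm$age)
}
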