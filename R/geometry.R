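#' Rays and ray-mesh intersection
#'
#' A `ray` carries an `origin` (mm) and a unit `direction`.
#'
#' @param origin numeric length-3 point (mm).
#' @param direction numeric length-3 vector; must have unit norm within 1e-6
#'   (use [unit_ray()] to normalize).
#' @return An object of class `ray`.
#' @export
ray <- function(origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  if (abs(vnorm(direction) - 1) > 1e-6)
    stop("ray direction must be a unit vector")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction)), class = "ray")
}

#' @rdname ray
#' @export
unit_ray <- function(origin, direction) ray(origin, unitize(direction))

#' Ordered ray-mesh intersections
#'
#' Returns every crossing of the ray with the mesh surface, sorted by
#' distance, with an `entering` flag derived from the outward face
#' orientation and the component id of the solid crossed. Grazing hits on
#' shared edges are counted once (hits of equal sense within 1e-9 mm are
#' deduplicated).
#'
#' @param mesh a [trimesh].
#' @param r a [ray].
#' @return data.frame with columns `distance`, `x`, `y`, `z`, `entering`,
#'   `component`, `face`; zero rows if the ray misses the mesh.
#' @export
ray_mesh_intersections <- function(mesh, r) {
  stopifnot(inherits(mesh, "trimesh"), inherits(r, "ray"))
  cpp_ray_hits(mesh$vertices, mesh$faces - 1L, mesh$components,
               r$origin, r$direction)
}

#' Bi-cortical screw length along a ray
#'
#' The bi-cortical length is the distance from the ray origin to the far
#' ("last") exit of the bone corridor reachable from the first entry without
#' crossing a void wider than `void_bridge_mm`. With the default
#' `void_bridge_mm = 0` the screw terminates at the first exit from bone: a
#' conservative reading under which the screw never bridges an empty gap.
#' Origins lying exactly on the surface count as inside the bone.
#'
#' @param mesh a [trimesh] (watertight union of components).
#' @param r a [ray]; origin at the screw entry, direction into bone.
#' @param max_length search horizon (mm).
#' @param void_bridge_mm widest cancellous void the screw may bridge (mm).
#' @return list with `length` (mm), `exit_point`, `entry` (distance to first
#'   bone entry) and `valid`; `valid = FALSE` (length `NA`) when the ray
#'   enters no bone within `max_length`.
#' @export
bicortical_length <- function(mesh, r, max_length = 200, void_bridge_mm = 0) {
  res <- bicortical_batch(mesh, matrix(r$origin, 1), matrix(r$direction, 1),
                          max_length, void_bridge_mm)
  list(length = if (res[1, 5] > 0) res[1, 1] else NA_real_,
       exit_point = if (res[1, 5] > 0) res[1, 2:4] else NULL,
       entry = if (res[1, 5] > 0) res[1, 6] else NA_real_,
       valid = res[1, 5] > 0)
}

# batch form used by the optimizer: origins/dirs are n x 3 matrices of unit
# directions; returns matrix [length, exit xyz, valid, entry]
bicortical_batch <- function(mesh, origins, dirs, max_length = 200,
                             void_bridge_mm = 0) {
  nd <- sqrt(rowSums(dirs^2))
  if (any(abs(nd - 1) > 1e-6)) stop("directions must be unit vectors")
  cpp_bicortical_batch(mesh$vertices, mesh$faces - 1L, mesh$components,
                       origins, dirs, max_length, void_bridge_mm, 1e-4)
}

#' Distance from points to the mesh surface
#'
#' @param mesh a [trimesh].
#' @param points n x 3 matrix of query points.
#' @return numeric vector of unsigned distances (mm).
#' @export
point_mesh_distance <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_point_mesh_distance(mesh$vertices, mesh$faces - 1L, points)
}
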