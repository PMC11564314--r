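#' Glenoid anatomical coordinate frame
#'
#' The frame is anchored at the glenoid center with three orthonormal,
#' right-handed axes: `axis_superior` along the glenoid long axis toward the
#' supraglenoid tubercle, `axis_posterior`, and `axis_lateral` along the
#' outward glenoid-surface normal.
#'
#' The glenoid rim plane is fitted to the rim landmarks by total least
#' squares (principal components); the origin is the rim centroid projected
#' onto that plane. `axis_lateral` is the plane normal oriented away from the
#' scapular body (the trigonum spinae / inferior angle side),
#' `axis_superior` the in-plane unit projection of (supraglenoid tubercle -
#' origin), and `axis_posterior = axis_lateral x axis_superior` completes the
#' right-handed triad.
#'
#' @param scapula a [scapula_model].
#' @return An object of class `glenoid_frame`: list with `origin`,
#'   `axis_superior`, `axis_posterior`, `axis_lateral`.
#' @export
build_glenoid_frame <- function(scapula) {
  pts <- rim_points(scapula)
  if (nrow(pts) < 8) stop("at least 8 glenoid rim points are required")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1))
    stop("rim points are collinear: plane fit is rank-deficient")
  normal <- sv$v[, 3]
  body_mid <- (scapula$landmarks$trigonum_spinae +
               scapula$landmarks$inferior_angle) / 2
  if (sum(normal * (ctr - body_mid)) < 0) normal <- -normal
  tub <- scapula$landmarks$supraglenoid_tubercle
  sup <- tub - ctr
  sup <- sup - sum(sup * normal) * normal
  if (vnorm(sup) < 1e-9)
    stop("supraglenoid tubercle is coincident with the glenoid center")
  sup <- unitize(sup)
  post <- cross3(normal, sup)
  structure(list(origin = ctr, axis_superior = sup, axis_posterior = post,
                 axis_lateral = unitize(normal)), class = "glenoid_frame")
}

#' @export
print.glenoid_frame <- function(x, ...) {
  cat("glenoid_frame\n")
  cat(sprintf("  origin   %7.2f %7.2f %7.2f\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  superior %7.3f %7.3f %7.3f\n", x$axis_superior[1], x$axis_superior[2], x$axis_superior[3]))
  cat(sprintf("  posterior%7.3f %7.3f %7.3f\n", x$axis_posterior[1], x$axis_posterior[2], x$axis_posterior[3]))
  cat(sprintf("  lateral  %7.3f %7.3f %7.3f\n", x$axis_lateral[1], x$axis_lateral[2], x$axis_lateral[3]))
  invisible(x)
}

# Scapular-body frame from the plane through trigonum spinae, inferior angle
# and the glenoid origin. l_b points laterally (from the trigonum toward the
# glenoid, in plane), n_b is the plane normal oriented to the posterior side
# of the glenoid frame, s_b = l_b rotated to superior (sign fixed by the
# inferior angle). Version and inclination decompose axis_lateral in this
# frame: version in the transverse (l_b, n_b) plane with posterior negative,
# inclination in the coronal (l_b, s_b) plane with superior positive.
scapular_body_frame <- function(scapula, frame) {
  ts <- scapula$landmarks$trigonum_spinae
  ia <- scapula$landmarks$inferior_angle
  o <- frame$origin
  n_b <- cross3(ts - o, ia - o)
  if (vnorm(n_b) < 1e-9) stop("degenerate scapular body plane")
  n_b <- unitize(n_b)
  if (sum(n_b * frame$axis_posterior) < 0) n_b <- -n_b
  l_b <- o - ts
  l_b <- unitize(l_b - sum(l_b * n_b) * n_b)
  s_b <- cross3(n_b, l_b)
  if (sum(s_b * (o - ia)) < 0) s_b <- -s_b
  # re-orthogonalize (s_b is +-90 deg from l_b by construction)
  list(l_b = l_b, s_b = unitize(s_b), n_b = n_b)
}

# version (posterior negative) and inclination (superior positive), degrees,
# of a lateral-pointing direction in the body frame
version_inclination <- function(lateral, body) {
  lx <- sum(lateral * body$l_b)
  version <- -rad2deg(atan2(sum(lateral * body$n_b), lx))
  inclination <- rad2deg(atan2(sum(lateral * body$s_b), lx))
  c(version = version, inclination = inclination)
}

# inverse map: unit lateral direction with given version/inclination
lateral_from_vi <- function(version, inclination, body) {
  unitize(body$l_b + tan(deg2rad(inclination)) * body$s_b -
            tan(deg2rad(version)) * body$n_b)
}
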