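#' Metaglene (baseplate) specification
#'
#' Geometry of the circular glenoid baseplate with a central peg and two
#' variable-angle peripheral screws (superior and inferior). Defaults model
#' a 27 mm plate with an 8 mm central peg and 4.5 mm locking screws whose
#' variable-angle cone spans `cone_half_angle` about a nominal hole axis
#' diverging `nominal_hole_divergence` away from the peg (cranially for the
#' superior screw, caudally for the inferior screw).
#'
#' @param diameter baseplate diameter (mm).
#' @param central_peg_diameter,central_peg_length central peg (mm).
#' @param hole_offset radial distance of the screw holes from the plate
#'   center (mm).
#' @param nominal_hole_divergence nominal hole-axis divergence from the peg
#'   axis (degrees).
#' @param screw_diameter (mm).
#' @param cone_half_angle variable-angle freedom about the nominal hole axis
#'   (degrees).
#' @return An object of class `metaglene_spec`.
#' @export
metaglene_spec <- function(diameter = 27, central_peg_diameter = 8,
                           central_peg_length = 15, hole_offset = 9,
                           nominal_hole_divergence = 10, screw_diameter = 4.5,
                           cone_half_angle = 15) {
  if (hole_offset + screw_diameter / 2 >= diameter / 2)
    stop("screw holes must lie inside the baseplate rim")
  if (cone_half_angle <= 0) stop("cone_half_angle must be positive")
  structure(as.list(environment()), class = "metaglene_spec")
}

#' Read a metaglene specification from a JSON config
#'
#' Any field of [metaglene_spec] may be given; the rest keep their defaults.
#'
#' @param path JSON file.
#' @return A [metaglene_spec].
#' @export
read_metaglene_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(metaglene_spec, cfg[intersect(names(cfg),
                                        names(formals(metaglene_spec)))])
}

#' Place the baseplate on the glenoid
#'
#' The plate normal starts from the glenoid surface normal (nominal
#' placement, minimizing reaming) and is minimally adjusted so that its
#' residual superior tilt and retroversion do not exceed `tilt_limit`
#' degrees. The plate is seated at the most inferior position: its inferior
#' rim is flush with the inferior glenoid margin along the superior axis.
#' The chord through the superior and inferior screw holes makes the
#' glenoid roll angle `gra_deg` with the glenoid axis (supraglenoid
#' tubercle through plate center), anterior positive.
#'
#' Glenoids narrower than the plate are allowed (the study premise); the
#' overhang is reported via the `overhang_mm` field.
#'
#' @param scapula a [scapula_model].
#' @param frame a [build_glenoid_frame] result.
#' @param spec a [metaglene_spec].
#' @param gra_deg glenoid roll angle (degrees, anterior positive).
#' @param tilt_limit admissible residual tilt/retroversion (degrees).
#' @return An object of class `baseplate_placement`: `center`, `normal`
#'   (unit peg axis, lateral), `gra_deg`, `superior_hole_origin`,
#'   `inferior_hole_origin`, plus the local chord (`u_chord`) and posterior
#'   (`p_local`) axes and `overhang_mm`.
#' @export
place_baseplate <- function(scapula, frame, spec, gra_deg = 0,
                            tilt_limit = 5) {
  stopifnot(inherits(spec, "metaglene_spec"))
  body <- scapular_body_frame(scapula, frame)
  vi <- version_inclination(frame$axis_lateral, body)
  v_c <- max(vi["version"], -tilt_limit)
  i_c <- min(vi["inclination"], tilt_limit)
  normal <- if (v_c != vi["version"] || i_c != vi["inclination"])
    lateral_from_vi(v_c, i_c, body) else frame$axis_lateral

  s_bp <- unitize(frame$axis_superior -
                    sum(frame$axis_superior * normal) * normal)
  inf_m <- scapula$landmarks$inferior_glenoid_margin
  inf_proj <- inf_m - sum((inf_m - frame$origin) * normal) * normal
  center <- inf_proj + (spec$diameter / 2) * s_bp

  u <- rotate_about(s_bp, normal, -deg2rad(gra_deg))  # anterior positive
  p_local <- cross3(normal, u)
  sup <- center + spec$hole_offset * u
  inf <- center - spec$hole_offset * u

  pts <- rim_points(scapula)
  cc <- max(pts %*% frame$axis_superior) - min(pts %*% frame$axis_superior)
  overhang <- max(0, spec$diameter - cc)
  if (overhang > 0)
    warning(sprintf("baseplate overhangs the glenoid by %.1f mm", overhang),
            call. = FALSE)

  structure(list(center = center, normal = normal, gra_deg = gra_deg,
                 superior_hole_origin = sup, inferior_hole_origin = inf,
                 u_chord = u, p_local = p_local, spec = spec,
                 overhang_mm = overhang,
                 residual_version = as.numeric(v_c),
                 residual_inclination = as.numeric(i_c)),
            class = "baseplate_placement")
}

# Vectorized screw directions in the baseplate-local frame.
# b = -normal (into bone); r = radial axis toward the screw's own hole
# (cranial positive for the superior screw, caudal positive for the
# inferior screw); p = local posterior axis. Intrinsic CCA-then-APA
# composition collapses to the closed form
#   d = cosA*cosC * b + cosA*sinC * r + sinA * p,
# so the angle to the peg axis is acos(cos(CCA) * cos(APA)).
screw_dirs <- function(placement, which, cca_deg, apa_deg) {
  b <- -placement$normal
  r <- if (which == "superior") placement$u_chord else -placement$u_chord
  p <- placement$p_local
  ca <- cos(deg2rad(apa_deg)); sa <- sin(deg2rad(apa_deg))
  cc <- cos(deg2rad(cca_deg)); sc <- sin(deg2rad(cca_deg))
  cbind(ca * cc * b[1] + ca * sc * r[1] + sa * p[1],
        ca * cc * b[2] + ca * sc * r[2] + sa * p[2],
        ca * cc * b[3] + ca * sc * r[3] + sa * p[3])
}

# angular deviation (degrees) of (cca, apa) pairs from the nominal hole axis
cone_deviation <- function(spec, cca_deg, apa_deg) {
  nom <- deg2rad(spec$nominal_hole_divergence)
  ca <- cos(deg2rad(apa_deg)); sa <- sin(deg2rad(apa_deg))
  cc <- cos(deg2rad(cca_deg)); sc <- sin(deg2rad(cca_deg))
  # dot with nominal direction (cca = nom, apa = 0) in the local frame
  dot <- ca * cc * cos(nom) + ca * sc * sin(nom)
  rad2deg(acos(pmin(1, pmax(-1, dot))))
}

#' Screw trajectory ray
#'
#' Builds the screw centerline for the given hole and angle pair. The
#' cranial-caudal angle (CCA) tilts the trajectory away from the central peg
#' axis in the plane containing the peg axis and the screw-hole chord
#' (cranially for the superior screw, caudally for the inferior screw); the
#' anterior-posterior angle (APA) tilts it in the orthogonal plane,
#' posterior positive. Both rotations live in the baseplate-local frame, so
#' changing the roll angle rotates the whole screw pattern rigidly. Angles
#' beyond `cone_half_angle` from the nominal hole axis are rejected.
#'
#' @param placement a [place_baseplate] result.
#' @param which `"superior"` or `"inferior"`.
#' @param cca_deg cranial-caudal angle from the peg axis (degrees; cranial
#'   positive for the superior screw, caudal positive for the inferior).
#' @param apa_deg anterior-posterior angle (degrees, posterior positive).
#' @return A [ray] from the screw-hole origin into bone.
#' @export
screw_ray <- function(placement, which = c("superior", "inferior"),
                      cca_deg = 0, apa_deg = 0) {
  which <- match.arg(which)
  spec <- placement$spec
  dev <- cone_deviation(spec, cca_deg, apa_deg)
  if (dev > spec$cone_half_angle + 1e-9)
    stop(sprintf("angles (%.1f, %.1f) deviate %.1f deg from the nominal hole axis (cone %.1f deg)",
                 cca_deg, apa_deg, dev, spec$cone_half_angle))
  o <- if (which == "superior") placement$superior_hole_origin
       else placement$inferior_hole_origin
  d <- screw_dirs(placement, which, cca_deg, apa_deg)[1, ]
  ray(o, unitize(d))
}
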