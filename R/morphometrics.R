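#' Glenoid morphometrics
#'
#' Measures the glenoid from rim landmarks and the anatomical frame:
#' cranial-caudal (CC) diameter as the maximal rim-point extent along
#' `axis_superior`, anterior-posterior (AP) width as the maximal extent
#' along `axis_posterior`, and version/inclination as the tilt of
#' `axis_lateral` relative to the scapular-body plane (plane through the
#' trigonum spinae, inferior angle and glenoid origin): version in the
#' transverse plane (posterior negative), inclination in the coronal plane
#' (superior positive). Widths are taken from rim landmarks, not the mesh
#' silhouette, so they are independent of how the bone was segmented.
#'
#' When the scapular-body landmarks are missing, widths are still returned
#' and version/inclination are `NA`.
#'
#' @param scapula a [scapula_model].
#' @param frame a [build_glenoid_frame] result.
#' @return An object of class `glenoid_geometry`: list with `ap_width`,
#'   `cc_diameter`, `version_deg`, `inclination_deg` (mm / degrees).
#' @export
measure_glenoid <- function(scapula, frame) {
  pts <- rim_points(scapula)
  s <- pts %*% frame$axis_superior
  p <- pts %*% frame$axis_posterior
  cc <- max(s) - min(s)
  ap <- max(p) - min(p)
  vi <- c(version = NA_real_, inclination = NA_real_)
  has_body <- !is.null(scapula$landmarks$trigonum_spinae) &&
    !is.null(scapula$landmarks$inferior_angle)
  if (has_body) {
    body <- scapular_body_frame(scapula, frame)
    vi <- version_inclination(frame$axis_lateral, body)
  }
  structure(list(ap_width = as.numeric(ap), cc_diameter = as.numeric(cc),
                 version_deg = as.numeric(vi["version"]),
                 inclination_deg = as.numeric(vi["inclination"])),
            class = "glenoid_geometry")
}

#' @export
print.glenoid_geometry <- function(x, ...) {
  cat(sprintf("glenoid: AP %.1f mm, CC %.1f mm, version %.1f deg, inclination %.1f deg\n",
              x$ap_width, x$cc_diameter, x$version_deg, x$inclination_deg))
  invisible(x)
}

#' Study exclusion filter
#'
#' Excludes a case when its superior tilt exceeds `tilt_limit` or its
#' retroversion exceeds `retro_limit`. Boundaries are strict: a case at
#' exactly the limit is included.
#'
#' @param geometry a [measure_glenoid] result.
#' @param tilt_limit maximal superior inclination (degrees, default 10).
#' @param retro_limit maximal retroversion (degrees, default 10; version
#'   below `-retro_limit` excludes).
#' @return list with `include` (logical) and `reason` (character, `""` when
#'   included; names the violated rule otherwise).
#' @export
apply_exclusions <- function(geometry, tilt_limit = 10, retro_limit = 10) {
  reasons <- character(0)
  if (isTRUE(geometry$inclination_deg > tilt_limit))
    reasons <- c(reasons, sprintf("superior tilt > %g", tilt_limit))
  if (isTRUE(geometry$version_deg < -retro_limit))
    reasons <- c(reasons, sprintf("retroversion > %g", retro_limit))
  list(include = length(reasons) == 0L,
       reason = paste(reasons, collapse = "; "))
}
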