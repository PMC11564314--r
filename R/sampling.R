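# truncated normal by rejection; exact for the modest truncations used here
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic cohort of scapula parameters
#'
#' Gender-stratified draws matching the study population: female AP width
#' ~ N(27.5, 3.9^2), male AP ~ N(31.1, 5.2^2), female CC diameter
#' ~ N(37.1, 4.3^2), male CC ~ N(41.1, 4.3^2) (mm); version ~ N(-4.1, 4.6^2)
#' degrees truncated to the exclusion bounds (retroversion <= 10, and
#' inclination ~ N(0, 4^2) truncated to superior tilt <= 10); age
#' ~ N(73.5, 7.6^2) truncated to the 51-92 year range. Draws violating
#' AP < CC are
#' resampled. Corridor and pillar geometry (lengths, taper, directions) are
#' jittered around their defaults to induce the between-patient
#' heterogeneity that drives the validation experiment.
#'
#' @param n number of cases (>= 1).
#' @param sex_ratio proportion of females, between 0 and 1 (default 0.744).
#' @param seed integer seed; same seed reproduces the identical cohort.
#' @param spread multiplier applied to every SD;
#'   `spread = 0` yields an anatomically homogeneous cohort.
#' @return list of [scapula_params], length `n`.
#' @export
sample_cohort <- function(n, sex_ratio = 0.744, seed = NULL, spread = 1) {
  stopifnot(n >= 1)
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  sexes <- ifelse(runif(n) < sex_ratio, "F", "M")
  lapply(seq_len(n), function(i) {
    female <- sexes[i] == "F"
    repeat {
      ap <- if (female) rtnorm(1, 27.5, 3.9 * spread, 18, 48)
            else        rtnorm(1, 31.1, 5.2 * spread, 18, 48)
      cc <- if (female) rtnorm(1, 37.1, 4.3 * spread, 30, 54)
            else        rtnorm(1, 41.1, 4.3 * spread, 30, 54)
      if (ap < cc - 0.5) break
    }
    scapula_params(
      ap_width = ap, cc_diameter = cc,
      version_deg = rtnorm(1, -4.1, 4.6 * spread, -10, 10),
      inclination_deg = rtnorm(1, 0, 4 * spread, -10, 10),
      vault_depth = rtnorm(1, 10, 1.5 * spread, 6, 14),
      spine_corridor_length = rtnorm(1, 50 + 0.6 * (ap - 28.2), 8 * spread,
                                     30, 80),
      spine_corridor_taper = rtnorm(1, 0.5, 0.07 * spread, 0.3, 0.7),
      body_plate_thickness = rtnorm(1, 6.5, 0.8 * spread, 4.5, 9),
      body_plate_extent = rtnorm(1, 48 + 0.5 * (ap - 28.2), 7 * spread,
                                 30, 70),
      corridor_cranial_deg = rtnorm(1, 7, 3 * spread, -3, 17),
      corridor_posterior_deg = rtnorm(1, -9, 2 * spread, -15, -3),
      corridor_bend_posterior_deg = rtnorm(1, 14, 1.5 * spread, 9, 19),
      corridor_bend_cranial_deg = rtnorm(1, 3, 1.5 * spread, -1, 7),
      corridor_anchor_ap_mm = rtnorm(1, 3.2, 0.6 * spread, 1, 7),
      pillar_caudal_deg = rtnorm(1, 8, 3 * spread, 0, 18),
      pillar_anterior_deg = rtnorm(1, 0.7, 4 * spread, -9, 11),
      pillar_bend_caudal_deg = rtnorm(1, 4, 1.5 * spread, 0, 8),
      pillar_anchor_ap_mm = rtnorm(1, 0, 0.8 * spread, -3, 3),
      sex = sexes[i],
      age = rtnorm(1, 73.5, 7.6 * spread, 51, 92))
  })
}

#' Write a synthetic cohort to disk
#'
#' One STL mesh, one landmark JSON and one ground-truth JSON per case, plus
#' a cohort manifest CSV.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param sex_ratio,spread passed to [sample_cohort].
#' @param mesh_resolution passed to [generate_scapula].
#' @return invisibly, the manifest data.frame.
#' @export
synthesize_cohort <- function(n, seed, out_dir, sex_ratio = 0.744,
                              spread = 1, mesh_resolution = 1.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- sample_cohort(n, sex_ratio = sex_ratio, seed = seed,
                          spread = spread)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("case_%03d", i)
    g <- generate_scapula(params[[i]], mesh_resolution = mesh_resolution,
                          case_id = id)
    write_mesh(g$model$mesh, file.path(out_dir, paste0(id, ".stl")))
    write_landmarks(g$model, file.path(out_dir, paste0(id, "_landmarks.json")))
    tr <- g$truth
    tr$frame <- unclass(tr$frame)
    tr$params <- unclass(tr$params)
    jsonlite::write_json(tr, file.path(out_dir, paste0(id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    p <- params[[i]]
    rows[[i]] <- data.frame(case_id = id, sex = p$sex, age = p$age,
                            ap_width = p$ap_width, cc_diameter = p$cc_diameter,
                            version_deg = p$version_deg,
                            inclination_deg = p$inclination_deg)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "cohort_manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}
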