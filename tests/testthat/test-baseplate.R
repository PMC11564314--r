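setup_case <- function(...) {
  g <- generate_scapula(scapula_params(...), case_id = "bp")
  fr <- build_glenoid_frame(g$model)
  list(g = g, fr = fr, spec = metaglene_spec())
}

test_that("zero roll places the hole chord on the glenoid axis", {
  cs <- setup_case()
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, gra_deg = 0)
  s_proj <- glenplan:::unitize(cs$fr$axis_superior -
    sum(cs$fr$axis_superior * pl$normal) * pl$normal)
  expect_equal(sum(pl$u_chord * s_proj), 1, tolerance = 1e-9)
  expect_equal(glenplan:::vnorm(pl$superior_hole_origin - pl$center), 9,
               tolerance = 1e-9)
  expect_equal(pl$superior_hole_origin + pl$inferior_hole_origin,
               2 * pl$center, tolerance = 1e-9)
})

test_that("the baseplate sits flush with the inferior glenoid margin", {
  cs <- setup_case()
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, 0)
  inf_m <- cs$g$model$landmarks$inferior_glenoid_margin
  rim_dist <- sum((pl$center - inf_m) * pl$u_chord)
  expect_equal(rim_dist, cs$spec$diameter / 2, tolerance = 0.5)
})

test_that("anterior roll is positive: the superior hole moves anteriorly", {
  cs <- setup_case()
  pl0 <- place_baseplate(cs$g$model, cs$fr, cs$spec, 0)
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, 1.6)
  moved <- pl$superior_hole_origin - pl0$superior_hole_origin
  expect_gt(sum(moved * (-cs$fr$axis_posterior)), 0)
  expect_equal(glenplan:::vec_angle_deg(pl$u_chord, pl0$u_chord), 1.6,
               tolerance = 1e-9)
})

test_that("excess retroversion is corrected to exactly the 5-degree cap", {
  cs <- setup_case(version_deg = -8)
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, 0)
  body <- glenplan:::scapular_body_frame(cs$g$model, cs$fr)
  vi <- glenplan:::version_inclination(pl$normal, body)
  expect_equal(as.numeric(vi["version"]), -5, tolerance = 1e-9)
  # nominal placement is untouched when within the admissible box
  cs2 <- setup_case(version_deg = -3)
  pl2 <- place_baseplate(cs2$g$model, cs2$fr, cs2$spec, 0)
  expect_equal(pl2$normal, cs2$fr$axis_lateral, tolerance = 1e-12)
})

test_that("small glenoids produce an overhang warning, not an error", {
  cs <- setup_case(ap_width = 20, cc_diameter = 26)
  expect_warning(place_baseplate(cs$g$model, cs$fr, cs$spec, 0), "overhang")
})

test_that("screw rays follow the CCA/APA conventions", {
  cs <- setup_case()
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, 0)
  r0 <- screw_ray(pl, "superior", 0, 0)
  expect_equal(r0$direction, -pl$normal, tolerance = 1e-12)
  # paper-mean superior angles: cranial and posterior components
  r <- screw_ray(pl, "superior", 9.1, 6.5)
  expect_gt(sum(r$direction * cs$fr$axis_superior), 0)   # cranial
  expect_gt(sum(r$direction * cs$fr$axis_posterior), 0)  # posterior
  ri <- screw_ray(pl, "inferior", 11.2, -0.7)
  expect_lt(sum(ri$direction * cs$fr$axis_superior), 0)  # caudal
  expect_lt(sum(ri$direction * cs$fr$axis_posterior), 0) # anterior
  # angle from the peg axis follows the closed-form composition
  expect_equal(glenplan:::vec_angle_deg(r$direction, -pl$normal),
               acos(cos(9.1 * pi / 180) * cos(6.5 * pi / 180)) * 180 / pi,
               tolerance = 1e-9)
})

test_that("screw directions match a rotation-matrix oracle", {
  cs <- setup_case()
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, -1.6)
  rot <- function(v, k, th) {
    k <- k / sqrt(sum(k^2))
    v * cos(th) + glenplan:::cross3(k, v) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  set.seed(66)
  for (i in 1:100) {
    cca <- runif(1, -4, 24); apa <- runif(1, -14, 14)
    if (glenplan:::cone_deviation(cs$spec, cca, apa) > 15) next
    for (w in c("superior", "inferior")) {
      r <- screw_ray(pl, w, cca, apa)
      b <- -pl$normal
      u <- if (w == "superior") pl$u_chord else -pl$u_chord
      # intrinsic CCA about the local AP axis, then APA about the rotated
      # cranial-plane axis
      k1 <- glenplan:::cross3(b, u)
      d1 <- rot(b, k1, cca * pi / 180)
      k2 <- rot(glenplan:::cross3(b, pl$p_local), k1, cca * pi / 180)
      d2 <- rot(d1, k2, apa * pi / 180)
      expect_lt(glenplan:::vec_angle_deg(r$direction, d2), 1e-9)
    }
  }
})

test_that("roll rotates the whole screw pattern rigidly", {
  cs <- setup_case()
  pl0 <- place_baseplate(cs$g$model, cs$fr, cs$spec, 2)
  pl1 <- place_baseplate(cs$g$model, cs$fr, cs$spec, 2 + 7)
  rotv <- function(v) glenplan:::rotate_about(v, pl0$normal, -7 * pi / 180)
  expect_equal(pl1$superior_hole_origin - pl1$center,
               rotv(pl0$superior_hole_origin - pl0$center), tolerance = 1e-12)
  d0 <- screw_ray(pl0, "superior", 7, 3)$direction
  d1 <- screw_ray(pl1, "superior", 7, 3)$direction
  expect_equal(d1, rotv(d0), tolerance = 1e-12)
})

test_that("the variable-angle cone is enforced about the nominal axis", {
  cs <- setup_case()
  pl <- place_baseplate(cs$g$model, cs$fr, cs$spec, 0)
  expect_error(screw_ray(pl, "superior", -6, 0), "cone")
  # reachable only because the cone sits about the divergent nominal axis
  expect_silent(screw_ray(pl, "inferior", 24.7, 0))
  expect_error(screw_ray(pl, "inferior", 25.2, 0), "cone")
})

test_that("implant specifications validate and load from JSON", {
  expect_error(metaglene_spec(hole_offset = 12), "inside")
  expect_error(metaglene_spec(cone_half_angle = 0), "positive")
  d <- withr::local_tempdir()
  f <- file.path(d, "implant.json")
  jsonlite::write_json(list(diameter = 25, hole_offset = 8), f,
                       auto_unbox = TRUE)
  sp <- read_metaglene_spec(f)
  expect_equal(sp$diameter, 25)
  expect_equal(sp$hole_offset, 8)
  expect_equal(sp$cone_half_angle, 15)
})
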