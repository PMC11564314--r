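test_that("cohort-mean anatomy is measured back from the mesh", {
  g <- generate_scapula(scapula_params(ap_width = 28.2, cc_diameter = 38.0,
                                       version_deg = -4.1),
                        case_id = "mean_case")
  fr <- build_glenoid_frame(g$model)
  geom <- measure_glenoid(g$model, fr)
  expect_lt(abs(geom$ap_width - 28.2), 0.5)
  expect_lt(abs(geom$cc_diameter - 38.0), 0.5)
  expect_lt(abs(geom$version_deg - (-4.1)), 1)
})

test_that("a circular rim measures equal widths", {
  s <- make_rim_scapula(radius = 12)
  fr <- build_glenoid_frame(s)
  geom <- measure_glenoid(s, fr)
  expect_equal(geom$ap_width, 24, tolerance = 1e-9)
  expect_equal(geom$cc_diameter, 24, tolerance = 1e-9)
})

rigid_transform <- function(scapula, R, t) {
  m <- scapula$mesh
  m$vertices <- sweep(m$vertices %*% t(R), 2, t, "+")
  lms <- lapply(scapula$landmarks, function(p) drop(R %*% p) + t)
  scapula_model(m, lms, keep_out_radii = scapula$keep_out_radii,
                case_id = scapula$case_id, sex = scapula$sex,
                age = scapula$age, validate = FALSE)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("measurements are invariant to rigid-body motion", {
  g <- generate_scapula(scapula_params(), case_id = "rigid")
  fr <- build_glenoid_frame(g$model)
  base <- measure_glenoid(g$model, fr)
  set.seed(55)
  for (i in 1:5) {
    s2 <- rigid_transform(g$model, random_rotation(), runif(3, -50, 50))
    g2 <- measure_glenoid(s2, build_glenoid_frame(s2))
    expect_equal(g2$ap_width, base$ap_width, tolerance = 1e-6)
    expect_equal(g2$cc_diameter, base$cc_diameter, tolerance = 1e-6)
    expect_equal(g2$version_deg, base$version_deg, tolerance = 1e-6)
    expect_equal(g2$inclination_deg, base$inclination_deg, tolerance = 1e-6)
  }
})

test_that("mirroring the scapula flips the measured version sign", {
  for (v in c(4, -6)) {
    g <- generate_scapula(scapula_params(version_deg = v), case_id = "mir")
    m <- g$model$mesh
    m$vertices[, 3] <- -m$vertices[, 3]
    m$faces <- m$faces[, c(1, 3, 2)]  # restore outward orientation
    lms <- lapply(g$model$landmarks, function(p) c(p[1], p[2], -p[3]))
    s2 <- scapula_model(m, lms, case_id = "mir", sex = "F", age = 70)
    geom <- measure_glenoid(s2, build_glenoid_frame(s2))
    expect_lt(abs(geom$version_deg - (-v)), 1)
  }
})

test_that("exclusion rules use strict printed boundaries", {
  gg <- function(v, i) structure(list(ap_width = 28, cc_diameter = 38,
                                      version_deg = v, inclination_deg = i),
                                 class = "glenoid_geometry")
  worst <- apply_exclusions(gg(-16.8, 0))  # the cohort's extreme case
  expect_false(worst$include)
  expect_match(worst$reason, "retroversion > 10")
  expect_true(apply_exclusions(gg(-4.1, 0))$include)
  expect_true(apply_exclusions(gg(0, 10))$include)    # boundary: strict >
  expect_false(apply_exclusions(gg(0, 10.1))$include)
  expect_true(apply_exclusions(gg(-10, 0))$include)
  both <- apply_exclusions(gg(-12, 12))
  expect_match(both$reason, "superior tilt")
  expect_match(both$reason, "retroversion")
})

test_that("widths survive missing body landmarks; version does not", {
  g <- generate_scapula(scapula_params(), case_id = "nb")
  fr <- build_glenoid_frame(g$model)
  s <- g$model
  s$landmarks$trigonum_spinae <- NULL
  geom <- measure_glenoid(s, fr)
  expect_false(is.na(geom$ap_width))
  expect_true(is.na(geom$version_deg))
})
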