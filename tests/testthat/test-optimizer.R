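test_that("notch keep-outs are closed sets around the nerve paths", {
  g <- generate_scapula(scapula_params(), case_id = "ns")
  s <- g$model
  # segment passing 20 mm from both notch centers
  q <- s$landmarks$suprascapular_notch_center
  far <- ray(q + c(0, -20, 0), c(1, 0, 0))
  expect_true(check_notch_safety(s, far, 10, clearance_mm = 2))
  # segment through a notch center
  hit <- ray(q - c(30, 0, 0), c(1, 0, 0))
  expect_false(check_notch_safety(s, hit, 60, clearance_mm = 2))
  # tangency at exactly radius + clearance is unsafe
  rad <- s$keep_out_radii[["suprascapular_notch_center"]]
  tang <- ray(q + c(-30, rad + 2, 0), c(1, 0, 0))
  expect_false(check_notch_safety(s, tang, 60, clearance_mm = 2))
  just_clear <- ray(q + c(-30, rad + 2 + 1e-6, 0), c(1, 0, 0))
  expect_true(check_notch_safety(s, just_clear, 60, clearance_mm = 2))
})

test_that("optimization recovers the analytic ground-truth optimum", {
  params <- sample_cohort(4, seed = 41)
  for (p in params) {
    g <- generate_scapula(p, case_id = "gt")
    sol <- optimize_case(g$model)
    gt <- ground_truth_optimum(g)
    expect_lt(abs(sol$superior$length - gt$superior$length), 1)
    expect_lt(abs(sol$inferior$length - gt$inferior$length), 1)
  }
})

test_that("a known corridor length is recovered by the search", {
  # generous straight corridor aligned with the default hole position
  p <- symmetric_params(spine_corridor_length = 50, cc_diameter = 38)
  g <- generate_scapula(p, case_id = "len")
  sol <- optimize_case(g$model)
  expect_lt(abs(sol$superior$length - 50), 1.2)
  gt <- ground_truth_optimum(g)
  expect_lt(abs(sol$superior$length - gt$superior$length), 1)
})

test_that("symmetric anatomy yields a mirror-symmetric roll landscape", {
  g <- generate_scapula(symmetric_params(), case_id = "sym")
  spec <- metaglene_spec()
  fr <- build_glenoid_frame(g$model)
  at_gra <- function(gr) {
    # a single-point roll grid isolates the angle search at that roll
    optimize_case(g$model, fr, spec,
                  search_config(gra_range = c(gr, gr + 0.5), gra_step = 1,
                                refine = FALSE),
                  engine = "analytic", primitives = g$truth$primitives)
  }
  s_plus <- at_gra(6)
  s_minus <- at_gra(-6)
  expect_equal(s_plus$superior$length, s_minus$superior$length,
               tolerance = 1e-6)
  # at zero roll the superior screw tracks the corridor direction (the
  # inward glenoid normal) within one grid step
  s0 <- at_gra(0)
  expect_lt(abs(s0$superior$angles[1]), 1 + 1e-9)
  expect_lt(abs(s0$superior$angles[2]), 1 + 1e-9)
})

test_that("fixed-angle evaluation is consistent with the optimizer", {
  g <- generate_scapula(scapula_params(), case_id = "fx")
  fr <- build_glenoid_frame(g$model)
  spec <- metaglene_spec()
  sol <- optimize_case(g$model, fr, spec)
  fx <- evaluate_fixed_angles(g$model, fr, spec, sol$gra_deg,
                              sol$superior$angles, sol$inferior$angles)
  expect_equal(fx$superior$length, sol$superior$length, tolerance = 1e-9)
  expect_equal(fx$inferior$length, sol$inferior$length, tolerance = 1e-9)
  # any admissible prescription is dominated by the optimum
  ra <- evaluate_fixed_angles(g$model, fr, spec, 0, c(10, 5), c(10, 0))
  expect_lte(ra$superior$length, sol$superior$length + 1e-9)
  expect_lte(ra$inferior$length, sol$inferior$length + 1e-9)
  expect_error(evaluate_fixed_angles(g$model, fr, spec, 0, c(30, 0),
                                     c(10, 0)), "cone")
})

test_that("optimization is deterministic and grid-stable", {
  g <- generate_scapula(scapula_params(), case_id = "det")
  a <- optimize_case(g$model)
  b <- optimize_case(g$model)
  expect_identical(a$gra_deg, b$gra_deg)
  expect_identical(a$superior$length, b$superior$length)
  expect_identical(a$inferior$length, b$inferior$length)
  # halving the grid steps moves the optimum by less than a millimetre
  fine <- optimize_case(g$model, search_cfg = search_config(
    gra_step = 0.5, angle_step = 0.5, refine_step = 0.125))
  expect_lt(abs(fine$superior$length - a$superior$length), 1)
  expect_lt(abs(fine$inferior$length - a$inferior$length), 1)
})

test_that("enlarging the variable-angle cone never shortens screws", {
  g <- generate_scapula(scapula_params(), case_id = "cone")
  fr <- build_glenoid_frame(g$model)
  # pure lexicographic objective so the reported length is the grid max
  cfg <- search_config(tie_mm = 0)
  narrow <- optimize_case(g$model, fr, metaglene_spec(cone_half_angle = 15),
                          cfg)
  wide <- optimize_case(g$model, fr, metaglene_spec(cone_half_angle = 20),
                        cfg)
  expect_gte(wide$superior$length, narrow$superior$length - 1e-9)
  expect_gte(wide$inferior$length, narrow$inferior$length - 1e-9)
})

test_that("search metadata records the work done", {
  g <- generate_scapula(scapula_params(), case_id = "meta")
  sol <- optimize_case(g$model)
  expect_gt(sol$search_metadata$evaluations, 20000)
  expect_identical(sol$search_metadata$engine, "mesh")
  expect_output(print(sol), "GRA")
})
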