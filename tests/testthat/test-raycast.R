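test_that("ray through a cube yields paired entry/exit hits", {
  m <- cube_mesh()
  h <- ray_mesh_intersections(m, ray(c(-5, 0.1, 0.2), c(1, 0, 0)))
  expect_equal(nrow(h), 2L)
  expect_equal(diff(h$distance), 1.0, tolerance = 1e-12)
  expect_equal(h$entering, c(TRUE, FALSE))
  miss <- ray_mesh_intersections(m, ray(c(-5, 3, 0), c(1, 0, 0)))
  expect_equal(nrow(miss), 0L)
})

test_that("two-slab fixture gives four hits at analytic distances", {
  m <- two_slab_mesh()  # slabs [0,5] and [15,20] along x
  h <- ray_mesh_intersections(m, ray(c(-10, 1, 2), c(1, 0, 0)))
  expect_equal(h$distance, c(10, 15, 25, 30), tolerance = 1e-9)
  expect_equal(h$entering, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("hit parity is even for origins outside the solid", {
  g <- generate_scapula(scapula_params(), case_id = "parity")
  m <- g$model$mesh
  set.seed(101)
  for (i in 1:100) {
    o <- c(60, 0, 0) + runif(3, -5, 5)  # well lateral of all bone
    target <- runif(3, -30, 30) * c(1, 1, 0.3) + c(-30, 0, 0)
    r <- unit_ray(o, target - o)
    h <- ray_mesh_intersections(m, r)
    expect_identical(nrow(h) %% 2L, 0L)
  }
})

test_that("bi-cortical length obeys the slab law t / cos(theta)", {
  m <- slab_mesh(10)
  for (th in c(0, 15, 30, 45, 60)) {
    d <- c(cos(th * pi / 180), sin(th * pi / 180), 0)
    res <- bicortical_length(m, ray(c(0, 0, 0), d))
    expect_true(res$valid)
    expect_lt(abs(res$length - 10 / cos(th * pi / 180)) /
                (10 / cos(th * pi / 180)), 1e-6)
  }
})

test_that("void bridging controls whether gaps terminate the screw", {
  m <- two_slab_mesh()
  r <- ray(c(0, 0, 0), c(1, 0, 0))  # origin on first slab surface
  stop_first <- bicortical_length(m, r, void_bridge_mm = 0)
  expect_equal(stop_first$length, 5, tolerance = 1e-6)
  bridged <- bicortical_length(m, r, void_bridge_mm = 12)
  expect_equal(bridged$length, 20, tolerance = 1e-6)
  narrow <- bicortical_length(m, r, void_bridge_mm = 9.9)
  expect_equal(narrow$length, 5, tolerance = 1e-6)
})

test_that("no-solution is reported when the ray misses all bone", {
  m <- cube_mesh()
  res <- bicortical_length(m, ray(c(-5, 3, 0), c(1, 0, 0)))
  expect_false(res$valid)
  expect_true(is.na(res$length))
  expect_error(bicortical_length(m, list(origin = c(0, 0, 0),
                                         direction = c(2, 0, 0))))
})

test_that("bi-cortical length matches a point-in-solid marching oracle", {
  g <- generate_scapula(scapula_params(), case_id = "march")
  m <- g$model$mesh
  fr <- build_glenoid_frame(g$model)
  pl <- place_baseplate(g$model, fr, metaglene_spec(), 0)
  set.seed(202)
  checked <- 0
  for (i in 1:100) {
    which_s <- if (i %% 2 == 0) "superior" else "inferior"
    cca <- runif(1, -3, 23); apa <- runif(1, -12, 12)
    if (glenplan:::cone_deviation(pl$spec, cca, apa) > 15) next
    r <- screw_ray(pl, which_s, cca, apa)
    fast <- bicortical_length(m, r, max_length = 120)
    slow <- r_marching_bicortical(m, r$origin, r$direction, max_len = 120)
    if (is.na(slow)) {
      expect_false(fast$valid)
    } else {
      expect_true(fast$valid)
      expect_lt(abs(fast$length - slow), 0.05)
    }
    checked <- checked + 1
  }
  expect_gte(checked, 60)
})

test_that("point-to-mesh distance is exact on the cube", {
  m <- cube_mesh()
  d <- point_mesh_distance(m, rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 1)))
  expect_equal(d, c(0.5, 1.5, sqrt(3 * 0.25)), tolerance = 1e-12)
})
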