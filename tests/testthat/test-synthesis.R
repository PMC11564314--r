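test_that("generated meshes satisfy the surface invariants", {
  params <- sample_cohort(5, seed = 21)
  for (p in params) {
    g <- generate_scapula(p, case_id = "w")
    expect_true(is_watertight(g$model$mesh))
    expect_silent(validate_scapula(g$model))
  }
})

test_that("morphometrics recover the generating parameters", {
  params <- sample_cohort(20, seed = 22)
  for (p in params) {
    g <- generate_scapula(p, case_id = "r")
    fr <- build_glenoid_frame(g$model)
    geom <- measure_glenoid(g$model, fr)
    expect_lt(abs(geom$ap_width - p$ap_width), 0.5)
    expect_lt(abs(geom$cc_diameter - p$cc_diameter), 0.5)
    expect_lt(abs(geom$version_deg - p$version_deg), 1)
    expect_lt(abs(geom$inclination_deg - p$inclination_deg), 1)
  }
})

test_that("cohort sampler matches the population moments", {
  params <- sample_cohort(10000, sex_ratio = 0.744, seed = 1)
  ap <- vapply(params, `[[`, 0, "ap_width")
  cc <- vapply(params, `[[`, 0, "cc_diameter")
  ver <- vapply(params, `[[`, 0, "version_deg")
  sex <- vapply(params, `[[`, "", "sex")
  f <- sex == "F"
  # independent oracle for the joint AP/CC distribution: plain normal
  # draws with the same AP < CC rejection rule, at large n
  ref <- function(mu_ap, sd_ap, mu_cc, sd_cc, n = 400000) {
    a <- rnorm(n, mu_ap, sd_ap); b <- rnorm(n, mu_cc, sd_cc)
    keep <- a < b - 0.5 & a >= 18 & a <= 48 & b >= 30 & b <= 54
    list(ap = mean(a[keep]), cc = mean(b[keep]), ap_sd = sd(a[keep]))
  }
  set.seed(900)
  rf <- ref(27.5, 3.9, 37.1, 4.3)
  rm_ <- ref(31.1, 5.2, 41.1, 4.3)
  expect_lt(abs(mean(ap[f]) - rf$ap), 3 * 3.9 / sqrt(sum(f)) + 0.03)
  expect_lt(abs(mean(ap[!f]) - rm_$ap), 3 * 5.2 / sqrt(sum(!f)) + 0.05)
  expect_lt(abs(mean(cc[f]) - rf$cc), 3 * 4.3 / sqrt(sum(f)) + 0.03)
  expect_lt(abs(sd(ap[f]) - rf$ap_sd), 0.15)
  # version: compare to the analytic truncated-normal mean (the exclusion
  # bounds at +-10 degrees shift the raw N(-4.1, 4.6^2) mean upward)
  a <- (-10 + 4.1) / 4.6; b <- (10 + 4.1) / 4.6
  ver_expect <- -4.1 + 4.6 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(ver) - ver_expect), 3 * sd(ver) / sqrt(10000))
  expect_lt(abs(mean(f) - 0.744), 3 * sqrt(0.744 * 0.256 / 10000))
  expect_true(all(ap < cc))
})

test_that("sampling is reproducible and bounds are honoured", {
  a <- sample_cohort(25, seed = 5)
  b <- sample_cohort(25, seed = 5)
  expect_identical(a, b)
  expect_error(sample_cohort(10, sex_ratio = 1.2), "sex_ratio")
  one <- sample_cohort(1, seed = 9)
  expect_length(one, 1)
  expect_s3_class(one[[1]], "scapula_params")
  ver <- vapply(sample_cohort(500, seed = 6), `[[`, 0, "version_deg")
  expect_true(all(ver >= -10 & ver <= 10))
})

test_that("parameter invariants are enforced", {
  expect_error(scapula_params(ap_width = 40, cc_diameter = 38), "smaller")
  expect_error(scapula_params(version_deg = 25), "version")
  expect_error(scapula_params(spine_corridor_length = -1))
})

test_that("a written cohort reloads into equivalent models", {
  d <- withr::local_tempdir()
  manifest <- synthesize_cohort(2, seed = 31, out_dir = d)
  expect_true(file.exists(file.path(d, "cohort_manifest.csv")))
  s <- load_scapula(file.path(d, "case_001.stl"),
                    file.path(d, "case_001_landmarks.json"))
  fr <- build_glenoid_frame(s)
  geom <- measure_glenoid(s, fr)
  expect_lt(abs(geom$ap_width - manifest$ap_width[1]), 0.5)
  expect_lt(abs(geom$version_deg - manifest$version_deg[1]), 1)
  tr <- jsonlite::read_json(file.path(d, "case_001_truth.json"))
  expect_named(tr, c("frame", "params", "primitives", "superior_corridor",
                     "inferior_corridor"), ignore.order = TRUE)
})

test_that("analytic primitive intervals agree with the scalar reference", {
  g <- generate_scapula(scapula_params(), case_id = "iv")
  prims <- g$truth$primitives
  set.seed(77)
  for (i in 1:40) {
    o <- c(runif(1, -5, 5), runif(1, -20, 20), runif(1, -10, 10))
    d <- glenplan:::unitize(rnorm(3))
    vec <- glenplan:::analytic_bicortical_batch(prims, matrix(o, 1),
                                               matrix(d, 1))
    iv <- NULL
    for (pr in prims) {
      s <- glenplan:::ray_prim_intervals(pr, o, d)
      if (!is.null(s)) iv <- rbind(iv, s)
    }
    if (is.null(iv)) {
      expect_equal(vec[1, 5], 0)
      next
    }
    iv[, 1] <- pmax(iv[, 1], 0); iv[, 2] <- pmin(iv[, 2], 200)
    iv <- iv[iv[, 2] > iv[, 1] + 1e-12, , drop = FALSE]
    if (!nrow(iv)) {
      expect_equal(vec[1, 5], 0)
      next
    }
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    end <- iv[1, 2]
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv[r, 1] <= end + 1e-9) end <- max(end, iv[r, 2]) else break
    }
    expect_equal(vec[1, 1], end, tolerance = 1e-8)
  }
})
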