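small_cfg <- function(...) search_config(gra_range = c(-10, 10),
                                         gra_step = 2, angle_step = 2,
                                         refine = FALSE, ...)

test_that("a minimal two-case study produces a complete report", {
  res <- suppressWarnings(run_study(sample_cohort(2, seed = 61),
                                    search_cfg = small_cfg()))
  expect_s3_class(res, "cohort_result")
  expect_equal(nrow(res$cases), 2)
  expect_named(res$tests, c("psi_vs_ca_sup", "psi_vs_ca_inf",
                            "psi_vs_ra_sup", "psi_vs_ra_inf",
                            "ca_vs_ra_sup", "ca_vs_ra_inf"))
  expect_equal(res$accounting$analyzed, 2)
  expect_true(all(c("psi_sup", "ca_sup", "ra_sup", "ca_safe") %in%
                    names(res$cases)))
  expect_output(print(res), "analyzed")
})

test_that("every fixed-angle evaluation is dominated by the optimum", {
  res <- suppressWarnings(run_study(sample_cohort(8, seed = 62),
                                    search_cfg = small_cfg()))
  c <- res$cases
  expect_true(all(c$ca_sup <= c$psi_sup + 1e-9))
  expect_true(all(c$ra_sup <= c$psi_sup + 1e-9))
  expect_true(all(c$ca_inf <= c$psi_inf + 1e-9))
  expect_true(all(c$ra_inf <= c$psi_inf + 1e-9))
})

test_that("identical scapulas collapse the validation comparison", {
  p <- sample_cohort(1, seed = 63)[[1]]
  res <- suppressWarnings(run_study(rep(list(p), 4),
                                    search_cfg = small_cfg()))
  expect_equal(res$cases$ca_sup, res$cases$psi_sup, tolerance = 1e-6)
  expect_true(res$tests$psi_vs_ca_sup$degenerate)
})

test_that("shrinking anatomical variance closes the PSI-CA gap", {
  gaps <- vapply(c(1, 0.25, 0), function(sp) {
    res <- suppressWarnings(run_study(
      sample_cohort(8, seed = 64, sex_ratio = 1, spread = sp),
      search_cfg = small_cfg()))
    mean(res$cases$psi_sup - res$cases$ca_sup) +
      mean(res$cases$psi_inf - res$cases$ca_inf)
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-6))  # monotone decrease
  expect_equal(gaps[3], 0, tolerance = 1e-6)
  expect_gt(gaps[1], 0)
})

test_that("excluded anatomy is reported with its reason", {
  p <- sample_cohort(3, seed = 65)
  p[[2]]$version_deg <- -14  # beyond the retroversion limit
  res <- suppressWarnings(run_study(p, search_cfg = small_cfg()))
  expect_equal(nrow(res$cases), 2)
  expect_equal(nrow(res$excluded), 1)
  expect_match(res$excluded$reason, "retroversion")
  expect_equal(res$accounting$analyzed, 2)
})

test_that("study outputs are written as CSV, JSON and Markdown", {
  d <- withr::local_tempdir()
  res <- suppressWarnings(run_study(sample_cohort(2, seed = 66),
                                    search_cfg = small_cfg()))
  write_cohort_result(res, d)
  expect_true(file.exists(file.path(d, "cohort.csv")))
  expect_true(file.exists(file.path(d, "summary.json")))
  expect_true(file.exists(file.path(d, "report.md")))
  summ <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(summ$accounting$analyzed, 2)
  back <- read.csv(file.path(d, "cohort.csv"))
  expect_equal(nrow(back), 2)
})

test_that("a cohort directory round-trips through the study", {
  d <- withr::local_tempdir()
  synthesize_cohort(2, seed = 67, out_dir = d)
  res <- suppressWarnings(run_study(d, search_cfg = small_cfg()))
  expect_equal(nrow(res$cases), 2)
  expect_equal(res$cases$case_id, c("case_001", "case_002"))
})
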