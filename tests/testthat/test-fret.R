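test_that("efficiency and bleach formulas match printed spot checks", {
  expect_identical(fret_efficiency(80, 100), (100 - 80) / 100)
  expect_equal(fret_efficiency(80, 100), 0.2, tolerance = 1e-15)
  expect_identical(bleach_efficiency(100, 30), (1 - 30 / 100) * 100)
  expect_equal(bleach_efficiency(100, 30), 70, tolerance = 1e-15)
})

test_that("noiseless bleach-corrected efficiencies recover the truth exactly", {
  spec <- fret_spec(true_efficiency = 0.2, noise_sigma = 0, seed = 6L)
  g <- generate_fret_cohort(spec)
  bl <- g$rois[g$rois$region == "bleached", ]
  eff <- bleach_corrected_efficiency(bl$d_pre, bl$d_post, bl$a_pre, bl$a_post)
  expect_equal(eff, rep(0.2, nrow(bl)), tolerance = 1e-9)
  expect_equal(mean(eff), 0.2, tolerance = 1e-9)
})

test_that("QC threshold is strict and filtering is monotone in the cutoff", {
  rois <- data.frame(cell_id = 1L, roi_id = 1:3,
                     region = "bleached", distance_um = NA_real_,
                     d_pre = 80, d_post = 100, a_pre = 100,
                     a_post = c(40, 39.9, 20))
  kept <- qc_filter(rois, min_bleach = 60)
  # exactly 60% bleach fails the strict > rule
  expect_identical(kept$roi_id, c(2L, 3L))
  n_kept <- vapply(c(0, 40, 60, 80, 99),
                   function(m) nrow(qc_filter(rois, min_bleach = m)),
                   numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("per-cell correction subtracts a distant unbleached control", {
  rois <- data.frame(cell_id = 1L, roi_id = 1:3,
                     region = c("bleached", "bleached", "unbleached"),
                     distance_um = c(NA, NA, 4),
                     d_pre = c(80, 90, 99),
                     d_post = c(100, 100, 100),
                     a_pre = 100, a_post = c(10, 10, 100))
  cc <- cell_corrected_efficiency(rois)
  expect_equal(cc$raw_mean_eff, mean(c(0.2, 0.1)), tolerance = 1e-12)
  expect_equal(cc$control_eff, 0.01, tolerance = 1e-12)
  expect_equal(cc$corrected_eff, mean(c(0.2, 0.1)) - 0.01, tolerance = 1e-12)
  close_ctrl <- rois
  close_ctrl$distance_um[3] <- 2
  expect_error(cell_corrected_efficiency(close_ctrl), "3 um")
})

test_that("normalization pins the positive control mean to exactly 1", {
  pc <- generate_fret_cohort(fret_spec(true_efficiency = 0.35, seed = 8L))
  sm <- generate_fret_cohort(fret_spec(true_efficiency = 0.2, seed = 9L))
  cohorts <- list(positive = fret_cohort(pc$rois, "positive"),
                  sample = fret_cohort(sm$rois, "sample"))
  norm <- normalize_to_control(cohorts, "positive")
  expect_identical(mean(norm$positive$cells$corrected_eff), 1)
  expect_true(norm$sample$normalized)
  # ratios between cohorts are preserved
  expect_equal(mean(norm$sample$cells$corrected_eff),
               mean(cohorts$sample$cells$corrected_eff) /
                 mean(cohorts$positive$cells$corrected_eff),
               tolerance = 1e-12)
  # idempotent: renormalizing changes nothing
  again <- normalize_to_control(norm, "positive")
  expect_equal(again$sample$cells$corrected_eff,
               norm$sample$cells$corrected_eff, tolerance = 1e-12)
})

test_that("two-cohort comparison uses a rank test and detects a shift", {
  a <- generate_fret_cohort(fret_spec(true_efficiency = 0.35, n_cells = 12L,
                                      noise_sigma = 0.01, seed = 10L))
  b <- generate_fret_cohort(fret_spec(true_efficiency = 0.1, n_cells = 12L,
                                      noise_sigma = 0.01, seed = 11L))
  res <- compare_fret(list(hi = fret_cohort(a$rois, "hi"),
                           lo = fret_cohort(b$rois, "lo")))
  expect_match(res$test, "Wilcoxon")
  expect_lt(res$p_value, 0.001)
  expect_identical(res$stars, significance_stars(res$p_value))
})

test_that("three or more cohorts trigger Kruskal-Wallis with Dunn post hoc", {
  mk <- function(eff, seed, label) {
    fret_cohort(generate_fret_cohort(
      fret_spec(true_efficiency = eff, n_cells = 10L, noise_sigma = 0.01,
                seed = seed))$rois, label)
  }
  res <- compare_fret(list(a = mk(0.35, 1L, "a"), b = mk(0.2, 2L, "b"),
                           c = mk(0.05, 3L, "c")))
  expect_match(res$test, "Kruskal")
  expect_true(is.data.frame(res$posthoc))
  expect_equal(nrow(res$posthoc), 3L)
  expect_identical(res$posthoc$stars,
                   vapply(res$posthoc$p_value, significance_stars,
                          character(1)))
})

test_that("FRET CSV round trip preserves ROI tables", {
  g <- generate_fret_cohort(fret_spec(seed = 14L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_fret_csv(g$rois, path)
  back <- read_fret_csv(path)
  expect_equal(back$d_post, g$rois$d_post, tolerance = 1e-9)
  expect_identical(back$region, g$rois$region)
})
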