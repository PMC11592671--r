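test_that("field generation is bit-reproducible for a fixed seed", {
  spec <- field_spec(n_cells = 5L, image_size = c(256L, 256L), seed = 42L)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$field$protein, b$field$protein)
  expect_identical(a$truth$cell_mask, b$truth$cell_mask)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("truth masks partition consistently and record drawn fractions", {
  g <- generate_field(field_spec(n_cells = 8L, image_size = c(256L, 256L),
                                 noise_sigma = 0, seed = 3L))
  cl <- g$truth$cell_mask
  nl <- g$truth$nuclei_mask
  # every nuclear pixel lies inside its own cell
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
  expect_identical(sort(unique(as.vector(cl[cl > 0]))), 1:8)
  # drawn per-cell fractions scatter around the target (jitter sd = 0.05)
  expect_true(all(abs(g$truth$cells$true_fraction - 0.7) <= 4 * 0.05))
  expect_lt(abs(mean(g$truth$cells$true_fraction) - 0.7), 0.1)
  expect_equal(g$truth$cells$realized_fraction, g$truth$cells$true_fraction,
               tolerance = 1e-6)
})

test_that("degenerate nuclear fractions put all signal in one compartment", {
  base <- 0.05
  g1 <- generate_field(field_spec(n_cells = 4L, image_size = c(256L, 256L),
                                  nuclear_fraction = 1, fraction_jitter = 0,
                                  noise_sigma = 0, speckle_density = 0, seed = 5L))
  cyto <- g1$truth$cell_mask > 0 & g1$truth$nuclei_mask == 0
  expect_equal(max(g1$field$protein[cyto]), base)
  g0 <- generate_field(field_spec(n_cells = 4L, image_size = c(256L, 256L),
                                  nuclear_fraction = 0, fraction_jitter = 0,
                                  noise_sigma = 0, speckle_density = 0, seed = 5L))
  expect_equal(max(g0$field$protein[g0$truth$nuclei_mask > 0]), base)
})

test_that("impossible packing densities fail with an informative error", {
  expect_error(
    generate_field(field_spec(n_cells = 200L, image_size = c(128L, 128L),
                              seed = 1L)),
    "place"
  )
})

test_that("TIFF round trip preserves intensities to quantization accuracy", {
  g <- generate_field(field_spec(n_cells = 4L, image_size = c(256L, 256L),
                                 seed = 9L))
  dir <- tempfile("field-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_field_tiff(g$field, dir)
  back <- read_field_tiff(paths[["protein"]], paths[["dapi"]],
                          paths[["brightfield"]])
  # intensities are stored normalized to the channel maximum
  norm <- g$field$protein / max(g$field$protein)
  expect_lt(max(abs(back$protein - norm)), 1 / 65535 + 1e-12)
})

test_that("FRAP truth half-times match closed form and bisection oracles", {
  s1 <- frap_spec(model = "single", k1 = 0.05, seed = 1L)
  t1 <- generate_frap_trace(s1)$truth$t_half
  expect_equal(t1, log(2) / 0.05, tolerance = 1e-10)
  s2 <- frap_spec(model = "double", A1 = 0.5, A2 = 0.3, k1 = 0.2, k2 = 0.02,
                  seed = 1L)
  t2 <- generate_frap_trace(s2)$truth$t_half
  expect_equal(t2, oracle_double_thalf(0.5, 0.2, 0.3, 0.02), tolerance = 1e-8)
})

test_that("noiseless blot lanes reproduce the requested nuclear percent", {
  for (p in c(10, 50, 70, 95)) {
    lanes <- generate_blot_lanes(p, noise_sigma = 0, seed = 2L)
    expect_equal(quantify_fractionation(lanes)$nuclear_percent, p,
                 tolerance = 1e-9)
  }
})

test_that("FRET cohort generation is reproducible and obeys the bleach model", {
  spec <- fret_spec(true_efficiency = 0.25, seed = 12L)
  a <- generate_fret_cohort(spec)
  b <- generate_fret_cohort(spec)
  expect_identical(a$rois, b$rois)
  bl <- a$rois[a$rois$region == "bleached", ]
  bfrac <- 1 - bl$a_post / bl$a_pre
  expect_equal(bl$d_post, bl$d_pre / (1 - 0.25 * bfrac), tolerance = 1e-9)
})
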