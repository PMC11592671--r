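field_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_field(field_spec(n_cells = 10L, noise_sigma = 0.05,
                                          seed = 21L))
    cache
  }
})

test_that("nucleus segmentation recovers the simulated nuclei", {
  g <- field_once()
  nuc <- segment_nuclei(g$field$dapi)
  labs <- nuc$labels
  truth <- g$truth$nuclei_mask
  expect_equal(max(labs), 10L)
  ious <- vapply(1:10, function(k) {
    hit <- labs[truth == k]
    hit <- hit[hit > 0]
    if (!length(hit)) return(0)
    j <- as.integer(names(which.max(table(hit))))
    sum(truth == k & labs == j) / sum(truth == k | labs == j)
  }, numeric(1))
  expect_true(all(ious >= 0.8))
})

test_that("cell segmentation keeps each nucleus inside its own cell", {
  g <- field_once()
  nuc <- segment_nuclei(g$field$dapi)
  cells <- segment_cells(g$field, nuc)
  cl <- cells$labels
  nl <- nuc$labels
  expect_equal(max(cl), max(nl))
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
})

test_that("noiseless truth-mask measurement recovers fractions to 1e-6", {
  g <- generate_field(field_spec(n_cells = 8L, image_size = c(256L, 256L),
                                 noise_sigma = 0, seed = 3L))
  rec <- measure_nc(g$field, g$truth$cell_mask, g$truth$nuclei_mask)
  truth <- g$truth$cells$realized_fraction[rec$cell_id]
  expect_equal(rec$fraction_nuclear, truth, tolerance = 1e-6)
})

test_that("segmentation pipeline recovers the population mean within 0.05", {
  g <- field_once()
  nuc <- segment_nuclei(g$field$dapi)
  cells <- segment_cells(g$field, nuc)
  rec <- measure_nc(g$field, cells, nuc)
  s <- summarize_population(rec)
  expect_lt(abs(s$mean - 0.7), 0.05)
  expect_true(s$below_min_cells)
})

test_that("fraction estimates are invariant to detector gain", {
  g <- generate_field(field_spec(n_cells = 6L, image_size = c(256L, 256L),
                                 noise_sigma = 0, seed = 7L))
  rec1 <- measure_nc(g$field, g$truth$cell_mask, g$truth$nuclei_mask)
  scaled <- g$field
  scaled$protein <- scaled$protein * 5
  rec2 <- measure_nc(scaled, g$truth$cell_mask, g$truth$nuclei_mask)
  expect_equal(rec2$fraction_nuclear, rec1$fraction_nuclear, tolerance = 1e-9)
})

test_that("nuclear and cytoplasmic areas partition each cell pixel-exactly", {
  g <- field_once()
  rec <- measure_nc(g$field, g$truth$cell_mask, g$truth$nuclei_mask)
  cl <- g$truth$cell_mask
  cell_px <- tabulate(cl[cl > 0], nbins = max(cl))
  expect_identical(rec$area_nuc + rec$area_cyto, cell_px[rec$cell_id])
})

test_that("Pearson colocalization matches a naive two-pass oracle", {
  g <- field_once()
  mask <- g$truth$cell_mask > 0
  r <- pearson_coloc(g$field$protein, g$field$dapi, mask)
  expect_equal(r$pearson_r,
               oracle_pearson(g$field$protein[mask], g$field$dapi[mask]),
               tolerance = 1e-12)
  same <- pearson_coloc(g$field$protein, g$field$protein * 2 + 1, mask)
  expect_equal(same$pearson_r, 1, tolerance = 1e-12)
  flat <- pearson_coloc(g$field$protein, matrix(1, nrow(mask), ncol(mask)), mask)
  expect_identical(flat$status, "undefined")
  expect_true(is.na(flat$pearson_r))
})

test_that("speckle detection finds simulated condensates by compartment", {
  g <- generate_field(field_spec(n_cells = 10L, noise_sigma = 0,
                                 speckle_density = 6, seed = 2L))
  det <- detect_speckles(g$field$protein, g$truth$cell_mask,
                         g$truth$nuclei_mask)
  truth <- g$truth$speckles
  d2 <- outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2
  recall <- mean(apply(d2, 2, min) <= 9)
  expect_gte(recall, 0.8)
  nearest <- apply(d2, 1, which.min)
  expect_true(all(det$compartment == truth$compartment[nearest]))
})

test_that("speckle detection reports nothing on speckle-free fields", {
  g <- generate_field(field_spec(n_cells = 6L, image_size = c(256L, 256L),
                                 noise_sigma = 0, speckle_density = 0,
                                 seed = 3L))
  det <- detect_speckles(g$field$protein, g$truth$cell_mask,
                         g$truth$nuclei_mask)
  expect_identical(nrow(det), 0L)
})

test_that("a blank image yields an empty mask with a warning", {
  blank <- matrix(0, 128, 128)
  expect_warning(nuc <- segment_nuclei(blank))
  expect_equal(max(nuc$labels), 0)
})
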