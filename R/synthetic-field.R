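#' Specification for a synthetic microscopy field
#'
#' Describes one simulated three-channel field (protein of interest, DAPI,
#' brightfield) populated with non-overlapping cells. Each cell is an ellipse
#' containing a smaller elliptical nucleus; the protein channel is painted so
#' that the mean nuclear and cytoplasmic intensities of each cell realize a
#' per-cell nuclear fraction drawn around `nuclear_fraction` (speckle mass is
#' compensated into the compartment base level, so the drawn fraction is exact
#' before noise). The DAPI and brightfield channels receive a light Gaussian
#' edge blur for segmentation realism; the protein channel is left crisp so
#' that ground-truth compartment means stay exact.
#'
#' @param n_cells number of cells to place (>= 1).
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param nuclear_fraction target per-cell nuclear intensity fraction in
#'   `[0, 1]`. The default 0.7 reflects a protein that is predominantly
#'   nuclear with roughly 30% cytoplasmic signal.
#' @param fraction_jitter standard deviation of the per-cell fraction around
#'   `nuclear_fraction` (draws are clipped to `[0, 1]`).
#' @param nucleus_radius_px,cell_radius_px length-2 numeric ranges for the
#'   ellipse semi-axes of nuclei and cell bodies, in pixels.
#' @param speckle_density number of condensate-like speckles per cell.
#' @param speckle_amplitude speckle peak intensity relative to the per-cell
#'   signal scale.
#' @param speckle_nuclear_prob probability that a speckle is placed in the
#'   nucleus rather than the cytoplasm.
#' @param noise_sigma additive Gaussian noise s.d. relative to the per-cell
#'   total signal.
#' @param background_level constant offset added to the protein channel.
#' @param poisson_noise if `TRUE`, apply Poisson shot noise instead of
#'   additive Gaussian noise.
#' @param edge_blur_sigma Gaussian blur (pixels) applied to the DAPI and
#'   brightfield channels.
#' @param pixel_size nominal pixel size in micrometres (metadata only).
#' @param seed integer seed; generation is bit-reproducible for a fixed spec.
#'
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(n_cells = 15L,
                       image_size = c(512L, 512L),
                       nuclear_fraction = 0.7,
                       fraction_jitter = 0.05,
                       nucleus_radius_px = c(9, 14),
                       cell_radius_px = c(22, 32),
                       speckle_density = 4L,
                       speckle_amplitude = 0.8,
                       speckle_nuclear_prob = 0.5,
                       noise_sigma = 0.05,
                       background_level = 0.05,
                       poisson_noise = FALSE,
                       edge_blur_sigma = 1,
                       pixel_size = 0.2,
                       seed = 1L) {
  assert_scalar_num(n_cells, "n_cells", 1)
  assert_scalar_num(nuclear_fraction, "nuclear_fraction", 0, 1)
  assert_scalar_num(fraction_jitter, "fraction_jitter", 0)
  assert_scalar_num(noise_sigma, "noise_sigma", 0)
  assert_scalar_num(background_level, "background_level", 0)
  if (length(image_size) != 2L || any(image_size < 64))
    stopf("'image_size' must be c(height, width) with both >= 64")
  if (length(nucleus_radius_px) != 2L || length(cell_radius_px) != 2L)
    stopf("radius ranges must have length 2")
  if (max(nucleus_radius_px) >= min(cell_radius_px))
    stopf("nucleus radius range must lie strictly below the cell radius range")
  structure(list(
    n_cells = as.integer(n_cells), image_size = as.integer(image_size),
    nuclear_fraction = nuclear_fraction, fraction_jitter = fraction_jitter,
    nucleus_radius_px = as.numeric(nucleus_radius_px),
    cell_radius_px = as.numeric(cell_radius_px),
    speckle_density = as.integer(speckle_density),
    speckle_amplitude = speckle_amplitude,
    speckle_nuclear_prob = speckle_nuclear_prob,
    noise_sigma = noise_sigma, background_level = background_level,
    poisson_noise = isTRUE(poisson_noise),
    edge_blur_sigma = edge_blur_sigma, pixel_size = pixel_size,
    seed = as.integer(seed)
  ), class = "field_spec")
}

# Rasterize an ellipse; returns a logical matrix the size of the field.
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  rmax <- max(a, b)
  rows <- max(1L, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- (u^2 + v^2) <= 1
  m
}

# Paint a 2-D Gaussian spot, clipped to `clip` (logical matrix), onto canvas.
paint_spot <- function(canvas, clip, cx, cy, sigma, amp) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(4 * sigma)
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  g <- amp * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  g[!clip[rows, cols]] <- 0
  canvas[rows, cols] <- canvas[rows, cols] + g
  canvas
}

#' Generate a synthetic three-channel field with ground truth
#'
#' @param spec a [field_spec()].
#' @return A list with elements `field` (class `field_images`: matrices
#'   `protein`, `dapi`, `brightfield`, plus `field_id` and `pixel_size`) and
#'   `truth` (class `field_truth`: per-cell table with the drawn nuclear
#'   fractions, label masks `nuclei_mask` and `cell_mask`, and a speckle
#'   table).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]

  # --- place non-overlapping cells (bounded rejection sampling) ------------
  a_cell <- stats::runif(spec$n_cells, spec$cell_radius_px[1], spec$cell_radius_px[2])
  b_cell <- stats::runif(spec$n_cells, spec$cell_radius_px[1], spec$cell_radius_px[2])
  theta <- stats::runif(spec$n_cells, 0, pi)
  rmax <- pmax(a_cell, b_cell)
  centers <- matrix(NA_real_, spec$n_cells, 2)
  attempts <- 0L; budget <- 600L * spec$n_cells
  for (i in seq_len(spec$n_cells)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > budget)
        stopf(paste0("could not place %d non-overlapping cells of radius ",
                     "%.0f-%.0f px in a %dx%d field; reduce n_cells or the ",
                     "cell radius"),
              spec$n_cells, spec$cell_radius_px[1], spec$cell_radius_px[2], h, w)
      cx <- stats::runif(1, rmax[i] + 3, w - rmax[i] - 3)
      cy <- stats::runif(1, rmax[i] + 3, h - rmax[i] - 3)
      if (i == 1L) { centers[i, ] <- c(cx, cy); break }
      d <- sqrt((centers[1:(i - 1), 1] - cx)^2 + (centers[1:(i - 1), 2] - cy)^2)
      if (all(d > rmax[i] + rmax[1:(i - 1)] + 2, na.rm = TRUE)) {
        centers[i, ] <- c(cx, cy); break
      }
    }
  }

  # --- nuclei: concentric ellipses, strictly inside the cell ---------------
  a_nuc <- stats::runif(spec$n_cells, spec$nucleus_radius_px[1], spec$nucleus_radius_px[2])
  b_nuc <- stats::runif(spec$n_cells, spec$nucleus_radius_px[1], spec$nucleus_radius_px[2])
  lim <- 0.9 * pmin(a_cell, b_cell)
  a_nuc <- pmin(a_nuc, lim); b_nuc <- pmin(b_nuc, lim)

  frac <- pmin(1, pmax(0, stats::rnorm(spec$n_cells, spec$nuclear_fraction,
                                       spec$fraction_jitter)))
  if (spec$fraction_jitter == 0) frac <- rep(spec$nuclear_fraction, spec$n_cells)

  cell_mask <- matrix(0L, h, w)
  nuc_mask <- matrix(0L, h, w)
  for (i in seq_len(spec$n_cells)) {
    cm <- ellipse_mask(h, w, centers[i, 1], centers[i, 2], a_cell[i], b_cell[i], theta[i])
    nm <- ellipse_mask(h, w, centers[i, 1], centers[i, 2], a_nuc[i], b_nuc[i], theta[i])
    cell_mask[cm] <- i
    nuc_mask[nm] <- i
  }

  # --- speckles, painted clipped to their compartment ----------------------
  sig_scale <- 1      # per-cell total signal (mu_n + mu_c)
  speckle_canvas <- matrix(0, h, w)
  spk <- list()
  for (i in seq_len(spec$n_cells)) {
    n_sp <- spec$speckle_density
    if (n_sp <= 0L) next
    nuc_px <- which(nuc_mask == i)
    cyto_px <- which(cell_mask == i & nuc_mask == 0L)
    for (s in seq_len(n_sp)) {
      nuclear <- stats::runif(1) < spec$speckle_nuclear_prob
      px <- if (nuclear) sample(nuc_px, 1L) else sample(cyto_px, 1L)
      cy <- ((px - 1L) %% h) + 1L
      cx <- ((px - 1L) %/% h) + 1L
      sigma <- stats::runif(1, 1.2, 2.2)
      amp <- spec$speckle_amplitude * sig_scale
      clip <- if (nuclear) nuc_mask == i else (cell_mask == i & nuc_mask == 0L)
      speckle_canvas <- paint_spot(speckle_canvas, clip, cx, cy, sigma, amp)
      spk[[length(spk) + 1L]] <- data.frame(
        cell_id = i, compartment = if (nuclear) "nuclear" else "cytoplasmic",
        x = cx, y = cy, sigma = sigma, amplitude = amp)
    }
  }
  speckles <- if (length(spk)) do.call(rbind, spk) else
    data.frame(cell_id = integer(), compartment = character(),
               x = numeric(), y = numeric(), sigma = numeric(),
               amplitude = numeric())

  # --- protein channel: compartment base levels compensate speckle mass ----
  protein <- matrix(0, h, w)
  realized <- frac
  for (i in seq_len(spec$n_cells)) {
    nm <- nuc_mask == i
    cyt <- cell_mask == i & nuc_mask == 0L
    area_n <- sum(nm); area_c <- sum(cyt)
    mu_n <- sig_scale * frac[i]
    mu_c <- sig_scale * (1 - frac[i])
    base_n <- mu_n - sum(speckle_canvas[nm]) / area_n
    base_c <- mu_c - sum(speckle_canvas[cyt]) / area_c
    if (base_n < 0 || base_c < 0) {
      warnf("cell %d: speckle mass exceeds compartment mean; fraction will deviate", i)
      base_n <- max(0, base_n); base_c <- max(0, base_c)
    }
    protein[nm] <- base_n
    protein[cyt] <- base_c
    realized[i] <- {
      m_n <- base_n + sum(speckle_canvas[nm]) / area_n
      m_c <- base_c + sum(speckle_canvas[cyt]) / area_c
      m_n / (m_n + m_c)
    }
  }
  protein <- protein + speckle_canvas + spec$background_level

  # --- DAPI and brightfield ------------------------------------------------
  dapi <- matrix(0.02, h, w); dapi[nuc_mask > 0L] <- 0.9
  bright <- matrix(0.5, h, w); bright[cell_mask > 0L] <- 0.42
  if (spec$edge_blur_sigma > 0) {
    dapi <- as.matrix(EBImage::gblur(dapi, sigma = spec$edge_blur_sigma))
    bright <- as.matrix(EBImage::gblur(bright, sigma = spec$edge_blur_sigma))
  }

  # --- noise ---------------------------------------------------------------
  if (spec$poisson_noise) {
    qe <- 2000  # photons per unit intensity
    protein <- stats::rpois(length(protein), pmax(protein, 0) * qe) / qe
    dim(protein) <- c(h, w)
  } else if (spec$noise_sigma > 0) {
    protein <- protein + stats::rnorm(length(protein), 0, spec$noise_sigma * sig_scale)
    dim(protein) <- c(h, w)
  }
  if (spec$noise_sigma > 0) {
    dapi <- pmax(dapi + matrix(stats::rnorm(h * w, 0, spec$noise_sigma * 0.9), h, w), 0)
    bright <- pmax(bright + matrix(stats::rnorm(h * w, 0, spec$noise_sigma * 0.5), h, w), 0)
  }
  protein <- pmax(protein, 0)

  field <- structure(list(protein = protein, dapi = dapi, brightfield = bright,
                          field_id = sprintf("synthetic-seed%d", spec$seed),
                          pixel_size = spec$pixel_size),
                     class = "field_images")
  truth <- structure(list(
    cells = data.frame(cell_id = seq_len(spec$n_cells),
                       cx = centers[, 1], cy = centers[, 2],
                       a_cell = a_cell, b_cell = b_cell, theta = theta,
                       a_nuc = a_nuc, b_nuc = b_nuc,
                       true_fraction = frac, realized_fraction = realized),
    nuclei_mask = nuc_mask, cell_mask = cell_mask, speckles = speckles,
    spec = spec), class = "field_truth")
  list(field = field, truth = truth)
}

#' Write a field's channels as 16-bit single-channel TIFF files
#'
#' @param field a `field_images` object.
#' @param dir output directory (created if needed).
#' @param max_intensity intensity mapped to the top of the 16-bit range.
#' @return Invisibly, the paths written, named by channel.
#' @export
write_field_tiff <- function(field, dir, max_intensity = NULL) {
  stopifnot(inherits(field, "field_images"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chans <- c("protein", "dapi", "brightfield")
  paths <- stats::setNames(character(3), chans)
  for (k in seq_along(chans)) {
    img <- field[[chans[k]]]
    mx <- max_intensity %||% max(img, 1e-12)
    paths[k] <- file.path(dir, sprintf("%s_%s.tif", field$field_id, chans[k]))
    tiff::writeTIFF(pmin(img / mx, 1), paths[k], bits.per.sample = 16L)
  }
  invisible(paths)
}

#' Read a three-channel field from single-channel TIFF files
#'
#' @param protein,dapi,brightfield paths to single-channel TIFF files.
#' @param field_id identifier attached to the result.
#' @param pixel_size optional pixel size in micrometres.
#' @return A `field_images` object.
#' @export
read_field_tiff <- function(protein, dapi, brightfield,
                            field_id = "field", pixel_size = NA_real_) {
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  }
  ch <- list(protein = rd(protein), dapi = rd(dapi), brightfield = rd(brightfield))
  if (!all(vapply(ch, function(x) identical(dim(x), dim(ch[[1]])), logical(1))))
    stopf("all three channels must have identical dimensions")
  structure(c(ch, list(field_id = field_id, pixel_size = pixel_size)),
            class = "field_images")
}
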