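#' @import EBImage
NULL

new_label_mask <- function(labels, kind) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind), class = "label_mask")
}

as_label_matrix <- function(mask) {
  if (inherits(mask, "label_mask")) return(mask$labels)
  if (is.matrix(mask)) return(mask)
  stopf("expected a label_mask or a matrix")
}

#' Build a label mask from an integer label matrix
#'
#' Useful for feeding ground-truth label images into the measurement
#' functions.
#'
#' @param labels integer matrix (0 = background, k = object k).
#' @param kind one of `"nuclei"`, `"cells"`, `"cytoplasm"`.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, kind = c("nuclei", "cells", "cytoplasm")) {
  kind <- match.arg(kind)
  if (any(labels < 0)) stopf("labels must be non-negative")
  new_label_mask(labels, kind)
}

# Zero out labelled objects that touch the image border and relabel the rest
# consecutively (a relabel map is returned as an attribute).
drop_border_objects <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  border <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
  border <- setdiff(border, 0L)
  labels[labels %in% border] <- 0L
  labels
}

relabel_consecutive <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) == 0L) return(labels)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- labels
  nz <- labels > 0L
  out[nz] <- map[labels[nz]]
  out
}

#' Segment nuclei from a DAPI channel
#'
#' Otsu thresholding on a Gaussian-smoothed DAPI image, hole filling, and
#' distance-transform watershed declumping; objects outside the area window
#' and objects touching the image border are removed.
#'
#' @param dapi 2-D intensity matrix (finite, >= 0).
#' @param min_area,max_area object area window in pixels.
#' @param smooth_sigma Gaussian smoothing s.d. in pixels before thresholding.
#' @return A `label_mask` of kind `"nuclei"`. A blank (constant) image yields
#'   an empty mask with a warning.
#' @export
segment_nuclei <- function(dapi, min_area = 40, max_area = 5000,
                           smooth_sigma = 2) {
  if (!is.matrix(dapi) || !all(is.finite(dapi)))
    stopf("'dapi' must be a finite 2-D matrix")
  if (stats::sd(dapi) == 0) {
    warnf("blank DAPI image: returning an empty nuclei mask")
    return(new_label_mask(matrix(0L, nrow(dapi), ncol(dapi)), "nuclei"))
  }
  sm <- as.matrix(EBImage::gblur(dapi, sigma = smooth_sigma))
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(smn))
  bw <- EBImage::fillHull(smn > thr)
  labels <- EBImage::watershed(EBImage::distmap(bw), tolerance = 1, ext = 1)
  labels <- as.matrix(EBImage::imageData(labels))
  storage.mode(labels) <- "integer"
  # area filter
  areas <- tabulate(labels[labels > 0L])
  bad <- which(areas < min_area | areas > max_area)
  if (length(bad)) labels[labels %in% bad] <- 0L
  labels <- drop_border_objects(labels)
  new_label_mask(relabel_consecutive(labels), "nuclei")
}

#' Segment cell bodies seeded from nuclei
#'
#' Voronoi-style propagation of nucleus seeds over the cell foreground. The
#' foreground is taken from an Otsu threshold of the smoothed protein channel
#' combined with a brightfield-derived gradient; nuclei with no detectable
#' surrounding signal fall back to a fixed-radius dilation of the nucleus and
#' are flagged.
#'
#' @param field a `field_images` object.
#' @param nuclei a `label_mask` of kind `"nuclei"`.
#' @param dilate_radius fallback dilation radius in pixels for cells without
#'   detectable cytoplasmic signal.
#' @return A `label_mask` of kind `"cells"` whose labels match their seed
#'   nuclei; flagged fallback labels are stored in the `flagged` attribute.
#' @export
segment_cells <- function(field, nuclei, dilate_radius = 15) {
  stopifnot(inherits(field, "field_images"))
  nuc <- as_label_matrix(nuclei)
  h <- nrow(nuc); w <- ncol(nuc)
  if (all(nuc == 0L))
    return(new_label_mask(matrix(0L, h, w), "cells"))
  prot <- as.matrix(EBImage::gblur(field$protein, sigma = 1))
  rng <- range(prot)
  fg <- if (diff(rng) > 0) {
    pn <- (prot - rng[1]) / diff(rng)
    pn > EBImage::otsu(EBImage::Image(pn))
  } else matrix(FALSE, h, w)
  # brightfield gradient adds cell footprints where the protein channel is dim
  bf <- as.matrix(EBImage::gblur(field$brightfield, sigma = 1))
  if (stats::sd(bf) > 0) {
    bfn <- abs(bf - intensity_mode(bf))
    fg <- fg | (bfn > 3 * stats::mad(bfn) + 1e-9)
  }
  fg <- EBImage::fillHull(fg | (nuc > 0L))
  cells <- EBImage::propagate(EBImage::Image(prot), seeds = nuc,
                              mask = fg, lambda = 1e-4)
  cells <- as.matrix(EBImage::imageData(cells))
  storage.mode(cells) <- "integer"
  # fallback: dilated nucleus for seeds whose cell adds almost no area
  flagged <- integer(0)
  brush <- EBImage::makeBrush(2 * dilate_radius + 1, shape = "disc")
  for (k in sort(setdiff(unique(as.vector(nuc)), 0L))) {
    extra <- sum(cells == k) - sum(nuc == k)
    if (extra <= 5) {
      flagged <- c(flagged, k)
      dil <- EBImage::dilate(nuc == k, brush)
      add <- as.matrix(dil) & cells == 0L
      cells[add | nuc == k] <- k
    }
  }
  out <- new_label_mask(cells, "cells")
  attr(out, "flagged") <- flagged
  out
}

#' Measure per-cell nuclear and cytoplasmic protein intensities
#'
#' For each matched nucleus-cell pair, the cytoplasm is the cell minus its
#' nucleus. The image background, estimated as the mode of the non-cell
#' pixels, is subtracted (clipped at zero) before means are taken. The
#' per-cell nuclear fraction is `mean_nuc / (mean_nuc + mean_cyto)`.
#'
#' @param field a `field_images` object.
#' @param cells,nuclei `label_mask` objects with matching labels.
#' @param min_cyto_px records with a cytoplasm of at most this many pixels are
#'   dropped (with a message).
#' @param use_integrated if `TRUE`, compute the fraction from integrated
#'   (summed) rather than mean compartment intensities.
#' @return A data frame of class `cell_records` with columns `cell_id`,
#'   `mean_nuc`, `mean_cyto`, `area_nuc`, `area_cyto`, `fraction_nuclear`;
#'   the estimated background is attached as attribute `background`.
#' @export
measure_nc <- function(field, cells, nuclei, min_cyto_px = 5,
                       use_integrated = FALSE) {
  stopifnot(inherits(field, "field_images"))
  cl <- as_label_matrix(cells); nl <- as_label_matrix(nuclei)
  if (!identical(dim(cl), dim(field$protein)) ||
      !identical(dim(nl), dim(field$protein)))
    stopf("masks must match the field dimensions")
  bg <- intensity_mode(field$protein[cl == 0L])
  if (!is.finite(bg)) bg <- 0
  img <- pmax(field$protein - bg, 0)
  ids <- intersect(setdiff(unique(as.vector(cl)), 0L),
                   setdiff(unique(as.vector(nl)), 0L))
  out <- list()
  for (k in sort(ids)) {
    nm <- nl == k
    cm <- cl == k & !nm
    area_n <- sum(nm); area_c <- sum(cm)
    if (area_c <= min_cyto_px || area_n == 0L) {
      message(sprintf("cell %d dropped: degenerate cytoplasm (%d px)", k, area_c))
      next
    }
    if (use_integrated) {
      mn <- sum(img[nm]); mc <- sum(img[cm])
    } else {
      mn <- mean(img[nm]); mc <- mean(img[cm])
    }
    if (mn + mc <= 0) {
      message(sprintf("cell %d dropped: no signal above background", k))
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      cell_id = k, mean_nuc = mn, mean_cyto = mc,
      area_nuc = area_n, area_cyto = area_c,
      fraction_nuclear = mn / (mn + mc))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = integer(), mean_nuc = numeric(),
               mean_cyto = numeric(), area_nuc = integer(),
               area_cyto = integer(), fraction_nuclear = numeric())
  class(res) <- c("cell_records", "data.frame")
  attr(res, "background") <- bg
  res
}

#' Summarize a population of per-cell nuclear fractions
#'
#' @param records a `cell_records` data frame.
#' @param min_cells minimum number of cells below which the summary is
#'   flagged; the convention of at least 75 cells per experiment is the
#'   default.
#' @return A list with `mean`, `sd`, `n` and `below_min_cells`.
#' @export
summarize_population <- function(records, min_cells = 75) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("no cell records to summarize")
  f <- records$fraction_nuclear
  structure(list(mean = mean(f), sd = stats::sd(f), n = length(f),
                 below_min_cells = length(f) < min_cells),
            class = "population_summary")
}

#' Pearson colocalization over masked pixels
#'
#' Standard Pearson correlation of two channels over the pixels of a mask,
#' without intensity thresholding.
#'
#' @param ch1,ch2 intensity matrices of identical dimensions.
#' @param mask a `label_mask`, an integer label matrix or a logical matrix;
#'   pixels with value > 0 (or `TRUE`) are used.
#' @return A list of class `coloc_result` with `pearson_r`, `n_pixels`,
#'   `mask_kind` and `status` (`"ok"` or `"undefined"` when either channel has
#'   zero variance within the mask).
#' @export
pearson_coloc <- function(ch1, ch2, mask) {
  if (!identical(dim(ch1), dim(ch2))) stopf("channels must have equal dimensions")
  kind <- if (inherits(mask, "label_mask")) mask$kind else "custom"
  m <- as_label_matrix(if (is.logical(mask)) mask * 1L else mask) > 0
  x <- ch1[m]; y <- ch2[m]
  if (length(x) < 2L) stopf("mask must contain at least two pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(pearson_r = NA_real_, n_pixels = length(x),
                          mask_kind = kind, status = "undefined"),
                     class = "coloc_result"))
  structure(list(pearson_r = stats::cor(x, y), n_pixels = length(x),
                 mask_kind = kind, status = "ok"),
            class = "coloc_result")
}

#' Detect condensate-like speckles and assign them to compartments
#'
#' The compartment base level (per-cell median of the nucleus and of the
#' cytoplasm) is subtracted, a difference-of-Gaussians band-pass isolates
#' spot-like structure, and connected components above `threshold` become
#' speckles. Each speckle is assigned nuclear or cytoplasmic by its centroid.
#'
#' @param channel intensity matrix (typically the protein channel).
#' @param cells,nuclei `label_mask` objects.
#' @param min_sigma,max_sigma band-pass scales in pixels.
#' @param threshold absolute response threshold on the band-passed residual.
#' @return A data frame of class `speckle_set` with columns `cell_id`, `x`,
#'   `y`, `area`, `compartment`, `integrated_intensity`.
#' @export
detect_speckles <- function(channel, cells, nuclei,
                            min_sigma = 1, max_sigma = 3, threshold = 0.1) {
  cl <- as_label_matrix(cells); nl <- as_label_matrix(nuclei)
  if (!identical(dim(cl), dim(channel)))
    stopf("masks must match the channel dimensions")
  resid <- matrix(0, nrow(channel), ncol(channel))
  for (k in sort(setdiff(unique(as.vector(cl)), 0L))) {
    nm <- nl == k
    cm <- cl == k & !nm
    if (any(nm)) resid[nm] <- channel[nm] - stats::median(channel[nm])
    if (any(cm)) resid[cm] <- channel[cm] - stats::median(channel[cm])
  }
  g1 <- as.matrix(EBImage::gblur(resid, sigma = min_sigma))
  g2 <- as.matrix(EBImage::gblur(resid, sigma = 2 * max_sigma))
  dog <- g1 - g2
  bw <- dog > threshold & cl > 0L
  empty <- data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                      area = integer(), compartment = character(),
                      integrated_intensity = numeric())
  class(empty) <- c("speckle_set", "data.frame")
  if (!any(bw)) return(empty)
  # local maxima of the band-passed response separate touching speckles
  dil <- as.matrix(EBImage::dilate(EBImage::Image(dog),
                                   EBImage::makeBrush(5, "disc")))
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bw)))
  pk <- which(dog >= dil & bw)
  if (!length(pk)) return(empty)
  py <- ((pk - 1L) %% nrow(dog)) + 1L
  px <- ((pk - 1L) %/% nrow(dog)) + 1L
  # greedy dedupe of plateau maxima closer than min_sigma
  ord <- order(-dog[pk])
  keep <- logical(length(pk))
  for (i in ord) {
    if (any(keep & sqrt((px - px[i])^2 + (py - py[i])^2) < min_sigma)) next
    keep[i] <- TRUE
  }
  out <- list()
  blob_area <- tabulate(lab[lab > 0L])
  for (i in which(keep)) {
    cell_id <- cl[py[i], px[i]]
    if (cell_id == 0L) next
    blob <- lab[py[i], px[i]]
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cell_id, x = px[i], y = py[i],
      area = if (blob > 0L) blob_area[blob] else 1L,
      compartment = if (nl[py[i], px[i]] > 0L) "nuclear" else "cytoplasmic",
      integrated_intensity = if (blob > 0L) sum(resid[lab == blob]) else
        resid[py[i], px[i]])
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  class(res) <- c("speckle_set", "data.frame")
  res
}
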