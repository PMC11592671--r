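#' Specification for a synthetic FRAP recovery trace
#'
#' Describes a photobleaching time course sampled at fixed intervals: `n_pre`
#' pre-bleach frames at plateau followed by `n_post` post-bleach frames whose
#' recovery follows a single or double exponential. The default frame interval
#' of one second and a four-minute post-bleach window mirror a typical
#' spinning-disc live-cell acquisition.
#'
#' @param model `"single"` or `"double"` exponential recovery.
#' @param A1,A2 recovery amplitudes (dimensionless, `A1 + A2 <= 1`); `A2` is
#'   ignored for the single model.
#' @param k1,k2 recovery rates in 1/s (> 0).
#' @param n_pre number of pre-bleach frames (>= 3).
#' @param n_post number of post-bleach frames.
#' @param dt frame interval in seconds.
#' @param floor residual normalized intensity immediately after the bleach
#'   (0 = complete bleach of the ROI).
#' @param noise_sigma Gaussian noise s.d. relative to the bleach-ROI signal.
#' @param seed integer seed.
#' @return An object of class `frap_spec`.
#' @export
frap_spec <- function(model = c("single", "double"),
                      A1 = 0.8, A2 = 0, k1 = 0.05, k2 = 0.01,
                      n_pre = 10L, n_post = 240L, dt = 1,
                      floor = 0, noise_sigma = 0.02, seed = 1L) {
  model <- match.arg(model)
  assert_scalar_num(k1, "k1", 1e-12)
  assert_scalar_num(A1, "A1", 0)
  if (model == "double") {
    assert_scalar_num(k2, "k2", 1e-12)
    assert_scalar_num(A2, "A2", 0)
  } else A2 <- 0
  if (A1 + A2 > 1) stopf("A1 + A2 must be <= 1")
  assert_scalar_num(n_pre, "n_pre", 3)
  assert_scalar_num(floor, "floor", 0, 0.99)
  structure(list(model = model, A1 = A1, A2 = A2, k1 = k1, k2 = k2,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 dt = dt, floor = floor, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "frap_spec")
}

# Noiseless normalized recovery model of a frap_spec at post-bleach time t'.
frap_model_value <- function(spec, tpost) {
  v <- spec$floor + spec$A1 * (1 - exp(-spec$k1 * tpost))
  if (spec$model == "double") v <- v + spec$A2 * (1 - exp(-spec$k2 * tpost))
  v
}

# Time at which the noiseless recovery reaches half its asymptote
# (above the post-bleach floor). Closed form for the single model,
# root bisection for the double model.
frap_true_thalf <- function(spec) {
  if (spec$model == "single") return(log(2) / spec$k1)
  A <- spec$A1 + spec$A2
  f <- function(t) spec$A1 * (1 - exp(-spec$k1 * t)) +
    spec$A2 * (1 - exp(-spec$k2 * t)) - A / 2
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-12)$root
}

#' Generate a synthetic FRAP trace with ground truth
#'
#' Builds raw ROI intensities (bleached ROI, whole cell, background) whose
#' double-normalized trace equals the spec's exponential model exactly in the
#' noiseless case.
#'
#' @param spec a [frap_spec()].
#' @return A list with `trace` (a [frap_trace()]) and `truth` (true half-time,
#'   mobile fraction, and the noiseless normalized values).
#' @export
generate_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  set.seed(spec$seed)
  n <- spec$n_pre + spec$n_post
  time <- (seq_len(n) - 1) * spec$dt
  bleach_frame <- spec$n_pre + 1L
  tpost <- time[bleach_frame:n] - time[bleach_frame]
  v <- c(rep(1, spec$n_pre), frap_model_value(spec, tpost))

  bg <- 50; cell <- 1000; peak <- 600
  roi_bleach <- bg + (peak - bg) * v
  roi_cell <- rep(cell, n)
  roi_background <- rep(bg, n)
  if (spec$noise_sigma > 0) {
    roi_bleach <- roi_bleach + stats::rnorm(n, 0, spec$noise_sigma * (peak - bg))
    roi_cell <- roi_cell + stats::rnorm(n, 0, spec$noise_sigma * (cell - bg))
  }
  trace <- frap_trace(time, roi_bleach, roi_cell, roi_background, bleach_frame)
  truth <- list(t_half = frap_true_thalf(spec),
                mobile_fraction = (spec$A1 + spec$A2) / (1 - spec$floor),
                model_values = v)
  list(trace = trace, truth = truth)
}

#' Specification for a synthetic FRET acceptor-photobleaching cohort
#'
#' Each cell carries `rois_per_cell` bleached regions of interest plus one
#' unbleached control region. For a realized acceptor bleach fraction `b`,
#' donor intensities follow `Dpost = Dpre / (1 - E * b)`, so the apparent
#' per-ROI efficiency `(Dpost - Dpre)/Dpost` equals `E * b`; dividing by the
#' bleach fraction measured from the acceptor channel recovers the true
#' efficiency `E` exactly in the noiseless case.
#'
#' @param true_efficiency true FRET efficiency in `[0, 1)`.
#' @param n_cells number of cells.
#' @param rois_per_cell bleached ROIs per cell (>= 1; six is the convention
#'   used to average out sub-cellular structure).
#' @param bleach_efficiency_range percent interval from which per-ROI acceptor
#'   bleach efficiencies are drawn uniformly.
#' @param donor_baseline,acceptor_baseline pre-bleach mean intensities.
#' @param control_distance_range micrometre interval for the distance of the
#'   unbleached control region from the bleached area.
#' @param noise_sigma multiplicative Gaussian noise s.d. relative to baseline.
#' @param seed integer seed.
#' @return An object of class `fret_spec`.
#' @export
fret_spec <- function(true_efficiency = 0.2,
                      n_cells = 10L,
                      rois_per_cell = 6L,
                      bleach_efficiency_range = c(65, 95),
                      donor_baseline = 100,
                      acceptor_baseline = 100,
                      control_distance_range = c(3, 8),
                      noise_sigma = 0,
                      seed = 1L) {
  assert_scalar_num(true_efficiency, "true_efficiency", 0, 1 - 1e-9)
  assert_scalar_num(n_cells, "n_cells", 1)
  assert_scalar_num(rois_per_cell, "rois_per_cell", 1)
  if (length(bleach_efficiency_range) != 2L ||
      bleach_efficiency_range[1] > bleach_efficiency_range[2] ||
      bleach_efficiency_range[2] > 100)
    stopf("'bleach_efficiency_range' must be an increasing percent interval <= 100")
  structure(list(true_efficiency = true_efficiency,
                 n_cells = as.integer(n_cells),
                 rois_per_cell = as.integer(rois_per_cell),
                 bleach_efficiency_range = as.numeric(bleach_efficiency_range),
                 donor_baseline = donor_baseline,
                 acceptor_baseline = acceptor_baseline,
                 control_distance_range = as.numeric(control_distance_range),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fret_spec")
}

#' Generate a synthetic FRET ROI cohort with ground truth
#'
#' @param spec a [fret_spec()].
#' @return A list with `rois` (a data frame of class `fret_rois` with columns
#'   `cell_id`, `roi_id`, `region`, `distance_um`, `d_pre`, `d_post`, `a_pre`,
#'   `a_post`) and `truth` (per-ROI realized bleach fractions and the true
#'   efficiency).
#' @export
generate_fret_cohort <- function(spec) {
  stopifnot(inherits(spec, "fret_spec"))
  if (spec$n_cells < 1L) stopf("empty cohort requested")
  set.seed(spec$seed)
  E <- spec$true_efficiency
  rows <- list(); tr <- list()
  jit <- function(n) if (spec$noise_sigma > 0)
    1 + stats::rnorm(n, 0, spec$noise_sigma) else rep(1, n)
  for (cell in seq_len(spec$n_cells)) {
    b <- stats::runif(spec$rois_per_cell,
                      spec$bleach_efficiency_range[1],
                      spec$bleach_efficiency_range[2]) / 100
    d_pre <- spec$donor_baseline * jit(spec$rois_per_cell)
    d_post <- d_pre / (1 - E * b) * jit(spec$rois_per_cell)
    a_pre <- spec$acceptor_baseline * jit(spec$rois_per_cell)
    a_post <- a_pre * (1 - b) * jit(spec$rois_per_cell)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cell, roi_id = seq_len(spec$rois_per_cell),
      region = "bleached", distance_um = NA_real_,
      d_pre = d_pre, d_post = d_post, a_pre = a_pre, a_post = a_post)
    # one unbleached control region per cell
    dc <- stats::runif(1, spec$control_distance_range[1],
                       spec$control_distance_range[2])
    dp <- spec$donor_baseline * jit(1)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cell, roi_id = spec$rois_per_cell + 1L,
      region = "unbleached", distance_um = dc,
      d_pre = dp, d_post = dp * jit(1),
      a_pre = spec$acceptor_baseline * jit(1),
      a_post = spec$acceptor_baseline * jit(1))
    tr[[cell]] <- data.frame(cell_id = cell, roi_id = seq_len(spec$rois_per_cell),
                             bleach_fraction = b)
  }
  rois <- do.call(rbind, rows)
  class(rois) <- c("fret_rois", "data.frame")
  list(rois = rois,
       truth = list(true_efficiency = E, per_roi = do.call(rbind, tr)))
}

#' Generate a pair of synthetic fractionation blot lanes
#'
#' Produces one nuclear and one cytoplasmic lane whose band intensities,
#' normalized to total protein, reproduce the requested nuclear percentage
#' exactly in the noiseless case. Histone H3 marks the nuclear lane and
#' tubulin the cytoplasmic lane, with a small configurable cross-contamination.
#'
#' @param nuclear_percent target percent of signal in the nuclear lane,
#'   in `[0, 100]`.
#' @param totals length-2 vector of total protein loaded per lane
#'   (nuclear, cytoplasmic); must be positive.
#' @param noise_sigma multiplicative Gaussian noise s.d. on band intensities.
#' @param cross_contamination fraction of each marker leaking into the other
#'   fraction's lane.
#' @param seed integer seed.
#' @return A data frame of class `blot_lanes` with one row per lane.
#' @export
generate_blot_lanes <- function(nuclear_percent, totals = c(30, 30),
                                noise_sigma = 0, cross_contamination = 0.02,
                                seed = 1L) {
  assert_scalar_num(nuclear_percent, "nuclear_percent", 0, 100)
  if (any(totals <= 0)) stopf("total protein amounts must be positive")
  set.seed(as.integer(seed))
  gain <- 2.5
  p <- nuclear_percent / 100
  band <- gain * c(p * totals[1], (1 - p) * totals[2])
  if (noise_sigma > 0)
    band <- band * (1 + stats::rnorm(2, 0, noise_sigma))
  if (any(band < 0)) stopf("negative band intensities are not allowed")
  lanes <- data.frame(
    fraction = c("nuclear", "cytoplasmic"),
    band_intensity = band,
    total_protein = as.numeric(totals),
    histone_h3 = c(1000, 1000 * cross_contamination),
    tubulin = c(800 * cross_contamination, 800))
  class(lanes) <- c("blot_lanes", "data.frame")
  lanes
}
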