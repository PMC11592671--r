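#' Construct a FRAP time course
#'
#' @param time time in seconds (strictly increasing).
#' @param roi_bleach,roi_cell,roi_background mean ROI intensities per frame
#'   for the bleached region, the whole cell and an extracellular background.
#' @param bleach_frame index of the first post-bleach frame (>= 4, so at
#'   least three pre-bleach frames exist).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time, roi_bleach, roi_cell, roi_background, bleach_frame) {
  n <- length(time)
  if (any(lengths(list(roi_bleach, roi_cell, roi_background)) != n))
    stopf("all trace columns must have equal length")
  if (any(diff(time) <= 0)) stopf("'time' must be strictly increasing")
  if (bleach_frame < 4L || bleach_frame > n)
    stopf("'bleach_frame' must leave at least 3 pre-bleach frames")
  if (!all(is.finite(c(roi_bleach, roi_cell, roi_background))))
    stopf("intensities must be finite")
  structure(data.frame(time = time, roi_bleach = roi_bleach,
                       roi_cell = roi_cell, roi_background = roi_background),
            bleach_frame = as.integer(bleach_frame),
            class = c("frap_trace", "data.frame"))
}

#' Read / write FRAP trace CSV files
#'
#' The file format has columns `time_s`, `roi_bleach`, `roi_cell`,
#' `roi_background`, plus a `bleach_frame` column repeating the index of the
#' first post-bleach frame.
#'
#' @param path file path.
#' @return For `read_frap_csv`, a `frap_trace`.
#' @export
read_frap_csv <- function(path) {
  d <- utils::read.csv(path)
  frap_trace(d$time_s, d$roi_bleach, d$roi_cell, d$roi_background,
             d$bleach_frame[1])
}

#' @rdname read_frap_csv
#' @param trace a `frap_trace`.
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  d <- data.frame(time_s = trace$time, roi_bleach = trace$roi_bleach,
                  roi_cell = trace$roi_cell,
                  roi_background = trace$roi_background,
                  bleach_frame = attr(trace, "bleach_frame"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

new_normalized_trace <- function(time, value, normalization, bleach_frame) {
  structure(data.frame(time = time, value = value),
            normalization = normalization,
            bleach_frame = as.integer(bleach_frame),
            class = c("normalized_trace", "data.frame"))
}

#' Double normalization of a FRAP trace
#'
#' Corrects the background-subtracted bleach-ROI signal for acquisition
#' bleaching using the whole-cell ROI:
#' `value(t) = [mean_pre(cell - bg) / (cell(t) - bg(t))] *
#' [(bleach(t) - bg(t)) / mean_pre(bleach - bg)]`.
#' The pre-bleach mean of the result is 1 by construction.
#'
#' @param trace a [frap_trace()].
#' @return A `normalized_trace` with `normalization = "double"`.
#' @export
double_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  bf <- attr(trace, "bleach_frame")
  pre <- seq_len(bf - 1L)
  cell <- trace$roi_cell - trace$roi_background
  bleach <- trace$roi_bleach - trace$roi_background
  bad <- which(cell <= 0)
  if (length(bad))
    stopf("cell ROI does not exceed background at frame %d", bad[1])
  value <- (mean(cell[pre]) / cell) * (bleach / mean(bleach[pre]))
  new_normalized_trace(trace$time, value, "double", bf)
}

#' Full-scale normalization of a double-normalized trace
#'
#' Rescales a double-normalized trace so that the first post-bleach frame is 0
#' and the pre-bleach plateau is 1: `F(t) = (I(t) - I(t0)) / (1 - I(t0))`.
#'
#' @param trace a double-normalized `normalized_trace`.
#' @return A `normalized_trace` with `normalization = "full_scale"`.
#' @export
full_scale_normalize <- function(trace) {
  stopifnot(inherits(trace, "normalized_trace"))
  if (!identical(attr(trace, "normalization"), "double"))
    stopf("full-scale normalization expects a double-normalized trace")
  bf <- attr(trace, "bleach_frame")
  i0 <- trace$value[bf]
  if (i0 >= 1) stopf("no bleach depth: value at the first post-bleach frame is >= 1")
  new_normalized_trace(trace$time, (trace$value - i0) / (1 - i0),
                       "full_scale", bf)
}

# log-linear initial rate estimate over the first half of the recovery
init_rate <- function(tpost, y, A) {
  frac <- pmin(pmax(1 - (y / A), 1e-6), 1)
  half <- seq_len(max(4L, length(tpost) %/% 2L))
  fit <- stats::lm(log(frac[half]) ~ tpost[half] - 1)
  max(1e-4, -unname(stats::coef(fit)[1]))
}

#' Fit an exponential recovery model to a normalized FRAP trace
#'
#' Least-squares fit of `F(t') = c0 + A1 (1 - exp(-k1 t')) [+ A2 (1 -
#' exp(-k2 t'))]` to the post-bleach frames, with `t'` measured from the
#' first post-bleach frame. For full-scale traces the offset `c0` is fixed at
#' 0. Rates are bounded to `(1e-5, 10)` 1/s and the fit is restarted from
#' jittered rate constants. The half-time solves `F(t) = plateau/2` above the
#' offset: `ln 2 / k` for the single model, root bisection for the double
#' model.
#'
#' @param trace a `normalized_trace` (double or full-scale).
#' @param model `"single"` or `"double"`.
#' @param n_starts number of multi-starts with jittered rates.
#' @return A list of class `recovery_fit` with `model`, `A1`, `k1` (and `A2`,
#'   `k2`), `c0`, `plateau` (sum of amplitudes), `t_half`, `rss`, `converged`,
#'   and the `normalization` of the input trace.
#' @export
fit_recovery <- function(trace, model = c("single", "double"), n_starts = 5L) {
  stopifnot(inherits(trace, "normalized_trace"))
  model <- match.arg(model)
  bf <- attr(trace, "bleach_frame")
  norm <- attr(trace, "normalization")
  post <- bf:nrow(trace)
  if (length(post) < 8L) stopf("need at least 8 post-bleach frames")
  tpost <- trace$time[post] - trace$time[bf]
  y <- trace$value[post]

  c0 <- if (norm == "full_scale") 0 else y[1]
  A_tot <- mean(y[tpost >= stats::quantile(tpost, 0.75)]) - c0
  A_tot <- max(A_tot, 1e-3)
  k0 <- init_rate(tpost, y - c0, A_tot)

  lower <- if (model == "single") c(A1 = 0, k1 = 1e-5) else
    c(A1 = 0, k1 = 1e-5, A2 = 0, k2 = 1e-5)
  upper <- if (model == "single") c(A1 = 1.5, k1 = 10) else
    c(A1 = 1.5, k1 = 10, A2 = 1.5, k2 = 10)
  if (norm != "full_scale") {
    lower <- c(lower, c0 = -0.5); upper <- c(upper, c0 = 1)
  }
  form <- if (model == "single") {
    if (norm == "full_scale") y ~ A1 * (1 - exp(-k1 * tt)) else
      y ~ c0 + A1 * (1 - exp(-k1 * tt))
  } else {
    if (norm == "full_scale")
      y ~ A1 * (1 - exp(-k1 * tt)) + A2 * (1 - exp(-k2 * tt)) else
      y ~ c0 + A1 * (1 - exp(-k1 * tt)) + A2 * (1 - exp(-k2 * tt))
  }
  dat <- data.frame(tt = tpost, y = y)

  best <- NULL
  set_jitter <- c(1, 0.3, 3, 0.1, 10)[seq_len(n_starts)]
  for (j in set_jitter) {
    start <- if (model == "single") list(A1 = A_tot, k1 = k0 * j) else
      list(A1 = A_tot * 0.6, k1 = k0 * j, A2 = A_tot * 0.4, k2 = k0 * j / 10)
    if (norm != "full_scale") start$c0 <- c0
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = lower[names(start)], upper = upper[names(start)],
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(model = model, A1 = NA_real_, k1 = NA_real_,
                          A2 = NA_real_, k2 = NA_real_, c0 = NA_real_,
                          plateau = NA_real_, t_half = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          normalization = norm),
                     class = "recovery_fit"))
  }
  cf <- stats::coef(best$fit)
  A1 <- unname(cf["A1"]); k1 <- unname(cf["k1"])
  A2 <- if (model == "double") unname(cf["A2"]) else 0
  k2 <- if (model == "double") unname(cf["k2"]) else NA_real_
  c0_hat <- if (norm == "full_scale") 0 else unname(cf["c0"])
  # order components by rate so A1/k1 is always the fast component
  if (model == "double" && k2 > k1) {
    tmp <- c(A1, k1); A1 <- A2; k1 <- k2; A2 <- tmp[1]; k2 <- tmp[2]
  }
  plateau <- A1 + A2
  t_half <- if (model == "single") log(2) / k1 else {
    f <- function(t) A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)) -
      plateau / 2
    stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-12)$root
  }
  structure(list(model = model, A1 = A1, k1 = k1, A2 = A2, k2 = k2,
                 c0 = c0_hat, plateau = plateau, t_half = t_half,
                 rss = best$rss, converged = TRUE, normalization = norm,
                 flagged_plateau = plateau > 1.2),
            class = "recovery_fit")
}

#' Mobile fraction from a recovery fit on a double-normalized trace
#'
#' The mobile fraction is the recovered amplitude relative to the bleach
#' depth: `plateau / (1 - c0)` where `c0` is the fitted post-bleach offset of
#' the double-normalized curve. It is not identifiable from a full-scale
#' trace, whose plateau is rescaled to the bleach depth.
#'
#' @param fit a converged `recovery_fit` obtained on a double-normalized
#'   trace.
#' @return The mobile fraction; values above 1.2 raise a warning flag.
#' @export
mobile_fraction <- function(fit) {
  stopifnot(inherits(fit, "recovery_fit"))
  if (!isTRUE(fit$converged)) stopf("fit did not converge")
  if (!identical(fit$normalization, "double"))
    stopf("mobile fraction requires a fit on a double-normalized trace")
  mf <- fit$plateau / (1 - fit$c0)
  if (mf > 1.2) warnf("mobile fraction %.2f exceeds 1.2; check normalization", mf)
  mf
}
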