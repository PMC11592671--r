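# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lo || x > hi)
    stopf("'%s' must be in [%g, %g], got %g", name, lo, hi, x)
  invisible(x)
}

# Mode of a numeric vector. Exact table mode when the data are effectively
# discrete (few unique values, e.g. noiseless synthetic backgrounds),
# otherwise the peak of a kernel density estimate.
intensity_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  ux <- unique(x)
  if (length(ux) <= max(256L, length(x) %/% 100L)) {
    tab <- table(x)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  d <- stats::density(x, n = 1024L)
  d$x[which.max(d$y)]
}

#' Derive a reproducible child seed from a parent seed and a stream label
#'
#' Distinct stream labels yield distinct, reproducible child seeds, so several
#' generators can be driven from a single top-level seed without sharing a
#' random stream. The result stays inside the 32-bit signed integer range.
#'
#' @param seed integer parent seed.
#' @param stream character label of the sub-stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  vals <- utf8ToInt(stream)
  as.integer((as.numeric(seed) * 48271 + sum(vals * seq_along(vals))) %%
               2147483647)
}

# Intersection-over-union of two binary masks.
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0L) return(NA_real_)
  sum(a & b) / u
}
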