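#' Significance star label for a p-value
#'
#' Tier map: `***` for p <= 0.0009, `**` for p <= 0.009, `*` for p <= 0.05,
#' otherwise `ns`. Boundaries are inclusive.
#'
#' @param p a probability in `[0, 1]`.
#' @return `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significance_stars <- function(p) {
  assert_scalar_num(p, "p", 0, 1)
  if (p <= 0.0009) "***" else if (p <= 0.009) "**" else if (p <= 0.05) "*"
  else "ns"
}

#' Compare two groups of per-cell measurements
#'
#' Two-sided two-sample t-test, either on the pooled per-cell values
#' (`mode = "cell"`) or on per-experiment means (`mode = "experiment"`, which
#' first collapses cells to one mean per experiment and tests those).
#'
#' @param a,b numeric vectors of measurements.
#' @param mode `"cell"` or `"experiment"`.
#' @param experiments_a,experiments_b experiment labels per measurement
#'   (required for experiment mode).
#' @param var_equal passed to [stats::t.test()].
#' @return A list of class `comparison_result` with `test`, `mode`,
#'   `statistic`, `p_value`, `stars` and `n` per group.
#' @export
compare_groups <- function(a, b, mode = c("cell", "experiment"),
                           experiments_a = NULL, experiments_b = NULL,
                           var_equal = FALSE) {
  mode <- match.arg(mode)
  if (mode == "experiment") {
    if (is.null(experiments_a) || is.null(experiments_b))
      stopf("experiment mode requires experiment labels for both groups")
    a <- as.numeric(tapply(a, experiments_a, mean))
    b <- as.numeric(tapply(b, experiments_b, mean))
  }
  if (length(a) < 2L || length(b) < 2L)
    stopf("need at least 2 values per group in %s mode", mode)
  ht <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(test = "two-sample t-test", mode = mode,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 stars = significance_stars(ht$p.value),
                 n = c(length(a), length(b))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s mode): statistic = %.4g, p = %.4g [%s], n = %s\n",
              x$test, x$mode %||% "cell", x$statistic, x$p_value, x$stars,
              paste(x$n, collapse = "/")))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
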