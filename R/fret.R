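#' FRET efficiency of one acceptor-photobleach ROI
#'
#' Acceptor photobleaching dequenches the donor, so the relative donor
#' increase estimates the FRET efficiency: `E = (Dpost - Dpre) / Dpost`.
#' Negative values (donor loss) are allowed and reported as-is.
#'
#' @param donor_pre,donor_post mean donor intensities before and after the
#'   acceptor bleach. Vectors are processed element-wise.
#' @return Efficiency (dimensionless).
#' @export
fret_efficiency <- function(donor_pre, donor_post) {
  if (any(donor_post <= 0)) stopf("donor_post must be positive")
  (donor_post - donor_pre) / donor_post
}

#' Acceptor bleach efficiency in percent
#'
#' `B = (1 - Apost/Apre) * 100`.
#'
#' @param acceptor_pre,acceptor_post mean acceptor intensities before and
#'   after the bleach.
#' @return Bleach efficiency in percent (at most 100).
#' @export
bleach_efficiency <- function(acceptor_pre, acceptor_post) {
  if (any(acceptor_pre <= 0)) stopf("acceptor_pre must be positive")
  (1 - acceptor_post / acceptor_pre) * 100
}

#' Bleach-corrected FRET efficiency
#'
#' With a partial acceptor bleach of fraction `b`, the apparent efficiency
#' `(Dpost - Dpre)/Dpost` equals `E * b`. Dividing by the bleach fraction
#' measured from the acceptor channel recovers the underlying efficiency;
#' on noiseless data the recovery is exact.
#'
#' @param donor_pre,donor_post,acceptor_pre,acceptor_post mean ROI
#'   intensities.
#' @return Bleach-corrected efficiency.
#' @export
bleach_corrected_efficiency <- function(donor_pre, donor_post,
                                        acceptor_pre, acceptor_post) {
  b <- bleach_efficiency(acceptor_pre, acceptor_post) / 100
  if (any(b <= 0)) stopf("bleach fraction must be positive for correction")
  fret_efficiency(donor_pre, donor_post) / b
}

#' Quality-control filter on acceptor bleach efficiency
#'
#' Keeps bleached ROIs whose bleach efficiency is strictly greater than
#' `min_bleach` percent. Unbleached control regions are exempt. Cells whose
#' bleached ROIs are all removed are excluded entirely (with a message).
#'
#' @param rois a `fret_rois` data frame (columns `cell_id`, `roi_id`,
#'   `region`, `distance_um`, `d_pre`, `d_post`, `a_pre`, `a_post`).
#' @param min_bleach percent threshold (default 60, strict inequality).
#' @return The filtered `fret_rois` data frame.
#' @export
qc_filter <- function(rois, min_bleach = 60) {
  stopifnot(is.data.frame(rois))
  bleached <- rois$region == "bleached"
  be <- rep(NA_real_, nrow(rois))
  be[bleached] <- bleach_efficiency(rois$a_pre[bleached], rois$a_post[bleached])
  keep <- !bleached | (be > min_bleach)
  out <- rois[keep, , drop = FALSE]
  # drop cells left with no bleached ROI at all
  surviving <- unique(out$cell_id[out$region == "bleached"])
  lost <- setdiff(unique(rois$cell_id), surviving)
  if (length(lost))
    message(sprintf("%d cell(s) excluded: no ROI above %g%% bleach efficiency",
                    length(lost), min_bleach))
  out <- out[out$cell_id %in% surviving, , drop = FALSE]
  class(out) <- c("fret_rois", "data.frame")
  out
}

#' Per-cell corrected FRET efficiency
#'
#' Averages the efficiencies of the (QC-passing) bleached ROIs of one cell and
#' subtracts the efficiency of the cell's unbleached control region, which
#' must lie at least `min_control_distance` micrometres from the bleached
#' area.
#'
#' @param rois rows of a `fret_rois` data frame belonging to a single cell.
#' @param min_control_distance minimum distance (micrometres) of the
#'   unbleached region.
#' @return A one-row data frame of class `cell_fret` with `cell_id`,
#'   `raw_mean_eff`, `control_eff`, `corrected_eff`, `n_rois_used`, `qc_pass`.
#' @export
cell_corrected_efficiency <- function(rois, min_control_distance = 3) {
  stopifnot(is.data.frame(rois))
  if (length(unique(rois$cell_id)) != 1L)
    stopf("expected ROIs of exactly one cell")
  bl <- rois[rois$region == "bleached", , drop = FALSE]
  un <- rois[rois$region == "unbleached", , drop = FALSE]
  if (nrow(bl) < 1L) stopf("cell has no QC-passing bleached ROI")
  if (nrow(un) != 1L) stopf("cell must have exactly one unbleached region")
  if (is.na(un$distance_um) || un$distance_um < min_control_distance)
    stopf("unbleached region at %.2f um is closer than the required %g um",
          un$distance_um, min_control_distance)
  raw <- mean(fret_efficiency(bl$d_pre, bl$d_post))
  ctrl <- fret_efficiency(un$d_pre, un$d_post)
  out <- data.frame(cell_id = rois$cell_id[1], raw_mean_eff = raw,
                    control_eff = ctrl, corrected_eff = raw - ctrl,
                    n_rois_used = nrow(bl), qc_pass = TRUE)
  class(out) <- c("cell_fret", "data.frame")
  out
}

#' Build a per-cell FRET cohort from an ROI table
#'
#' Applies the bleach-efficiency QC filter and computes one corrected
#' efficiency per surviving cell.
#'
#' @param rois a `fret_rois` data frame.
#' @param condition label attached to the cohort.
#' @param min_bleach QC threshold in percent.
#' @param min_control_distance minimum control-region distance in micrometres.
#' @return A list of class `fret_cohort` with `condition`, `cells` (a
#'   `cell_fret` data frame), and `normalized = FALSE`.
#' @export
fret_cohort <- function(rois, condition = "sample", min_bleach = 60,
                        min_control_distance = 3) {
  filt <- qc_filter(rois, min_bleach)
  cells <- lapply(split(as.data.frame(filt), filt$cell_id), function(d) {
    tryCatch(cell_corrected_efficiency(d, min_control_distance),
             error = function(e) { message(conditionMessage(e)); NULL })
  })
  cells <- do.call(rbind, cells[!vapply(cells, is.null, logical(1))])
  structure(list(condition = condition, cells = cells, normalized = FALSE,
                 positive_control_mean = NA_real_),
            class = "fret_cohort")
}

#' Normalize FRET cohorts to a positive control
#'
#' Divides every corrected efficiency by the mean corrected efficiency of the
#' positive-control cohort, so that the positive-control cohort mean becomes
#' exactly 1. Normalizing an already normalized set is the identity.
#'
#' @param cohorts a named list of `fret_cohort` objects.
#' @param positive_control_label name of the positive-control cohort.
#' @return The list of cohorts with normalized efficiencies.
#' @export
normalize_to_control <- function(cohorts, positive_control_label) {
  if (!positive_control_label %in% names(cohorts))
    stopf("positive control cohort '%s' not found", positive_control_label)
  ctrl <- cohorts[[positive_control_label]]
  if (is.null(ctrl$cells) || nrow(ctrl$cells) == 0L)
    stopf("positive control cohort is empty")
  if (isTRUE(ctrl$normalized)) return(cohorts)
  m <- mean(ctrl$cells$corrected_eff)
  if (m <= 0) stopf("positive control mean efficiency must be positive")
  lapply(cohorts, function(co) {
    co$cells$corrected_eff <- co$cells$corrected_eff / m
    co$normalized <- TRUE
    co$positive_control_mean <- m
    co
  })
}

# Dunn's rank-based post hoc comparisons after a Kruskal-Wallis test,
# with tie correction and Holm adjustment. No packaged implementation of
# Dunn's z statistics is available in the dependency set, so the standard
# large-sample formula is used.
dunn_posthoc <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group_a = combs[1, ], group_b = combs[2, ], z = z,
             p_value = stats::p.adjust(p, method = p_adjust))
}

#' Compare FRET cohorts
#'
#' Two cohorts are compared with a rank-based Wilcoxon test (unpaired by
#' default; set `paired = TRUE` when measurements are matched). Three or more
#' cohorts are compared with a Kruskal-Wallis omnibus test followed by Dunn's
#' pairwise post hoc comparisons with Holm adjustment.
#'
#' @param cohorts a named list of `fret_cohort` objects (two or more).
#' @param paired pair the two-cohort comparison (requires equal sizes).
#' @param min_n minimum number of cells required per cohort.
#' @return A list of class `comparison_result`. For two cohorts: `test`,
#'   `statistic`, `p_value`, `stars`, `n`. For more: the omnibus `p_value`
#'   plus a `posthoc` table with per-pair p-values and star labels.
#' @export
compare_fret <- function(cohorts, paired = FALSE, min_n = 3L) {
  vals <- lapply(cohorts, function(co) co$cells$corrected_eff)
  if (any(vapply(vals, length, integer(1)) < min_n))
    stopf("each cohort needs at least %d cells", min_n)
  if (length(vals) == 2L) {
    ht <- stats::wilcox.test(vals[[1]], vals[[2]], paired = paired,
                             exact = FALSE)
    res <- list(test = if (paired) "Wilcoxon signed-rank" else
                  "Wilcoxon rank-sum",
                groups = names(cohorts), statistic = unname(ht$statistic),
                p_value = ht$p.value, stars = significance_stars(ht$p.value),
                n = vapply(vals, length, integer(1)))
  } else {
    g <- rep(names(vals), lengths(vals))
    v <- unlist(vals, use.names = FALSE)
    kw <- stats::kruskal.test(v, factor(g))
    ph <- dunn_posthoc(v, g)
    ph$stars <- vapply(ph$p_value, significance_stars, character(1))
    res <- list(test = "Kruskal-Wallis + Dunn (Holm)", groups = names(vals),
                statistic = unname(kw$statistic), p_value = kw$p.value,
                stars = significance_stars(kw$p.value), posthoc = ph,
                n = vapply(vals, length, integer(1)))
  }
  class(res) <- "comparison_result"
  res
}

#' Read / write FRET ROI tables
#'
#' CSV columns: `cell_id`, `roi_id`, `region` (`bleached`/`unbleached`),
#' `distance_um`, `d_pre`, `d_post`, `a_pre`, `a_post`.
#'
#' @param path file path.
#' @return For `read_fret_csv`, a `fret_rois` data frame.
#' @export
read_fret_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cell_id", "roi_id", "region", "distance_um",
            "d_pre", "d_post", "a_pre", "a_post")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  class(d) <- c("fret_rois", "data.frame")
  d
}

#' @rdname read_fret_csv
#' @param rois a `fret_rois` data frame.
#' @export
write_fret_csv <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}
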