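#' Sensitivity sweep grid
#'
#' One-at-a-time sweeps over the three tunable parameters of the procedure:
#' the matching gate multiplier alpha (0.1-1.0), the minimum-area threshold
#' (2-8 um^2, step 1) and the NMS factor (0.3-0.7, step 0.1). While one
#' parameter varies the others stay at their base configuration.
#'
#' @param alpha_values,min_area_values,nms_values Positive numeric grids.
#' @return A `sweep_grid` list.
#' @export
sweep_grid <- function(alpha_values = seq(0.1, 1.0, by = 0.1),
                       min_area_values = 2:8,
                       nms_values = seq(0.3, 0.7, by = 0.1)) {
  vals <- list(alpha = alpha_values, min_area = min_area_values,
               nms = nms_values)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!length(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort_input(sprintf("%s grid must be non-empty and positive", nm))
    }
  }
  structure(vals, class = "sweep_grid")
}

# evaluate one ROI at one configuration: pipeline on predictions, then
# matching against the (already curated) reference instances
evaluate_roi <- function(pred, ref, roi_points, config, criteria) {
  pp <- apply_fixed_pipeline(pred, roi_points, config)
  m <- match_instances(pp$instances, ref, criteria)
  det <- detection_summary(m)
  list(det = det,
       pred_count = nrow(pp$instances),
       ref_count = nrow(ref),
       mae = abs(nrow(pp$instances) - nrow(ref)),
       audit = pp$audit)
}

#' Run one-at-a-time parameter sweeps
#'
#' For each parameter and each grid value the full pipeline, matching and
#' metrics are recomputed per ROI with all other parameters held at the base
#' configuration. Deterministic given its inputs.
#'
#' @param rois Named list; each element a list with `pred` (instance table or
#'   field), `ref` (reference instance table) and `roi_points` (annotation
#'   points in um).
#' @param grid A [sweep_grid()].
#' @param config Base [postprocess_config()].
#' @param criteria Base [match_criteria()].
#' @return Long-format data frame: roi_id, parameter, value, tp, fp, fn,
#'   precision, recall, f1, pred_count, ref_count, mae.
#' @export
run_sweep <- function(rois, grid = sweep_grid(),
                      config = postprocess_config(),
                      criteria = match_criteria()) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (is.null(names(rois)) || any(!nzchar(names(rois)))) {
    abort_input("rois must be a named list")
  }
  rows <- list()
  for (param in c("alpha", "min_area", "nms")) {
    values <- switch(param, alpha = grid$alpha, min_area = grid$min_area,
                     nms = grid$nms)
    for (v in values) {
      cfg <- config
      crit <- criteria
      if (param == "alpha") crit$alpha <- v
      if (param == "min_area") cfg$min_area_um2 <- v
      if (param == "nms") cfg$nms_factor <- v
      for (id in names(rois)) {
        r <- rois[[id]]
        ev <- evaluate_roi(r$pred, r$ref, r$roi_points, cfg, crit)
        rows[[length(rows) + 1L]] <- data.frame(
          roi_id = id, parameter = param, value = v,
          tp = ev$det$tp, fp = ev$det$fp, fn = ev$det$fn,
          precision = ev$det$precision, recall = ev$det$recall,
          f1 = ev$det$f1,
          pred_count = ev$pred_count, ref_count = ev$ref_count,
          mae = ev$mae, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Select the minimum-area threshold from a sweep
#'
#' Returns the threshold that minimises mean MAE across ROIs; ties are broken
#' first by higher mean F1, then by the smaller threshold.
#'
#' @param sweep A [run_sweep()] result covering `parameter == "min_area"`.
#' @return The selected threshold (um^2).
#' @export
select_min_area <- function(sweep) {
  s <- sweep[sweep$parameter == "min_area", , drop = FALSE]
  if (!nrow(s)) abort_input("sweep contains no min-area rows")
  agg <- stats::aggregate(cbind(mae, f1) ~ value, data = s, FUN = mean)
  agg <- agg[order(agg$mae, -agg$f1, agg$value), , drop = FALSE]
  agg$value[1L]
}

#' Friedman rank test for blocked comparisons
#'
#' Rank-based test for differences between k treatments observed on n blocks
#' (ROIs as repeated measures). Within-block values are mid-ranked, and the
#' tie-corrected chi-square statistic is referred to the chi-square
#' distribution with k - 1 degrees of freedom. A table in which every block
#' is completely tied carries no information: statistic 0, p = 1.
#'
#' @param values An n x k matrix (blocks x treatments), no missing cells.
#' @return List with `statistic`, `df`, `p`, `n_blocks`, `k`.
#' @export
friedman_test <- function(values) {
  m <- as.matrix(values)
  if (any(!is.finite(m))) abort_input("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) abort_input("need >= 2 blocks and >= 2 treatments")
  ranks <- t(apply(m, 1, rank)) # mid-ranks for ties
  rj <- colSums(ranks)
  # tie correction: sum over blocks of (t^3 - t) per tied group
  tiesum <- sum(apply(m, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  stat_uncorr <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  corr <- 1 - tiesum / (n * k * (k^2 - 1))
  if (corr <= 0) {
    statistic <- 0
    p <- 1
  } else {
    statistic <- stat_uncorr / corr
    if (statistic < 0) statistic <- 0 # roundoff guard
    p <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = statistic, df = k - 1, p = p, n_blocks = n, k = k,
       method = "Friedman rank test (mid-ranks, tie-corrected chi-square)")
}

#' Paired Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Zero differences are dropped and ties mid-ranked. The exact null
#' distribution is used for n <= 25 remaining pairs when there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' The Bonferroni-adjusted p is `min(1, m * p)` and is always reported
#' alongside the raw p. All-zero differences give an undefined p (`NA`).
#'
#' @param pairs A list of comparisons, each a list/data frame with equal
#'   length numeric vectors `x` and `y`.
#' @param m Number of comparisons for the correction (default
#'   `length(pairs)`).
#' @return Data frame: comparison, n_effective, statistic, p, p_bonferroni,
#'   method.
#' @export
wilcoxon_bonferroni <- function(pairs, m = length(pairs)) {
  if (!length(pairs)) abort_input("no comparisons supplied")
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    x <- as.numeric(pr$x); y <- as.numeric(pr$y)
    if (length(x) != length(y) || !length(x)) {
      abort_input("each comparison needs equal-length non-empty x and y")
    }
    d <- x - y
    d <- d[d != 0]
    nm <- if (!is.null(names(pairs)[i]) && nzchar(names(pairs)[i])) names(pairs)[i]
          else sprintf("pair_%d", i)
    if (!length(d)) {
      return(data.frame(comparison = nm, n_effective = 0L,
                        statistic = NA_real_, p = NA_real_,
                        p_bonferroni = NA_real_,
                        method = "undefined (all differences zero)"))
    }
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = exact, correct = TRUE)
    )
    data.frame(comparison = nm, n_effective = length(d),
               statistic = unname(wt$statistic), p = wt$p.value,
               p_bonferroni = min(1, m * wt$p.value),
               method = if (exact) "exact signed-rank (n <= 25, no ties)"
                        else "normal approximation with continuity correction")
  })
  do.call(rbind, rows)
}
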