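#' Pixel-level confusion counts between two masks
#'
#' Foreground is any positive label. When an ROI polygon is given, counting
#' is restricted to pixels whose physical centres fall inside or on the
#' polygon, the same membership rule used for instance restriction.
#'
#' @param pred,ref [label_field()]s of identical dimensions and calibration.
#' @param roi Optional [roi_polygon()].
#' @return A `pixel_confusion` list with counts `tp`, `fp`, `fn`, `tn`.
#' @export
pixel_confusion <- function(pred, ref, roi = NULL) {
  stopifnot(inherits(pred, "label_field"), inherits(ref, "label_field"))
  if (!identical(dim(pred$labels), dim(ref$labels))) {
    abort_input("masks must have identical dimensions")
  }
  if (pred$calib$microns_per_pixel != ref$calib$microns_per_pixel) {
    abort_input("masks must share a calibration")
  }
  p <- pred$labels > 0L
  g <- ref$labels > 0L
  if (!is.null(roi)) {
    s <- pred$calib$microns_per_pixel
    nr <- nrow(p); nc <- ncol(p)
    cx <- (rep(seq_len(nc), each = nr) - 0.5) * s
    cy <- (rep(seq_len(nr), times = nc) - 0.5) * s
    inside <- points_in_polygon(cx, cy, roi)
    p <- p[inside]; g <- g[inside]
  }
  structure(list(
    tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g)
  ), class = "pixel_confusion")
}

#' Dice coefficient and intersection-over-union
#'
#' `Dice = 2TP / (2TP + FP + FN)` and `IoU = TP / (TP + FP + FN)`. When both
#' masks are empty over the evaluated region (`TP = FP = FN = 0`) the metric
#' is undefined and `NA` is returned rather than 0 or 1; this distinction
#' matters in low-prevalence regions.
#'
#' @param conf A [pixel_confusion()] or any list with `tp`, `fp`, `fn`.
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @export
dice <- function(conf) {
  den <- 2 * conf$tp + conf$fp + conf$fn
  if (den == 0) return(NA_real_)
  2 * conf$tp / den
}

#' @rdname dice
#' @export
iou <- function(conf) {
  den <- conf$tp + conf$fp + conf$fn
  if (den == 0) return(NA_real_)
  conf$tp / den
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n > 0`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`, contained in `[0, 1]` and containing `k/n`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    abort_input("n must be a positive count")
  }
  if (k < 0 || k > n) abort_input("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Instance-level detection summary
#'
#' Precision, recall and F1 from a match result, with Wilson intervals for
#' precision (over `tp + fp` trials) and recall (over `tp + fn`). Ratios
#' with zero denominator are reported as `NA` ("undefined"), never coerced
#' to 0.
#'
#' @param m A `match_result` (see [match_instances()]) or a list with counts
#'   `tp`, `fp`, `fn`.
#' @param conf Confidence level for the Wilson intervals.
#' @return A `detection_summary` list.
#' @export
detection_summary <- function(m, conf = 0.95) {
  if (inherits(m, "match_result")) {
    tp <- nrow(m$pairs)
    fp <- length(m$false_positives)
    fn <- length(m$false_negatives)
  } else {
    tp <- m$tp; fp <- m$fp; fn <- m$fn
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  # F1 = 2TP/(2TP+FP+FN): equals 2PR/(P+R) whenever both are defined and
  # positive, and stays defined when only one of them is
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    wilson_precision = if (tp + fp > 0) wilson_ci(tp, tp + fp, conf) else c(lo = NA_real_, hi = NA_real_),
    wilson_recall = if (tp + fn > 0) wilson_ci(tp, tp + fn, conf) else c(lo = NA_real_, hi = NA_real_),
    conf = conf
  ), class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.4f", v))
  cat(sprintf("<detection_summary> TP %d FP %d FN %d | P %s R %s F1 %s\n",
              x$tp, x$fp, x$fn, fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  invisible(x)
}

#' Write per-ROI metrics to JSON
#'
#' @param pixel A [pixel_confusion()] (or NULL).
#' @param det A [detection_summary()] (or NULL).
#' @param path Output path.
#' @param calib Optional calibration echoed into the output.
#' @export
write_metrics_json <- function(path, pixel = NULL, det = NULL, calib = NULL) {
  out <- list()
  if (!is.null(calib)) out$microns_per_pixel <- calib$microns_per_pixel
  if (!is.null(pixel)) {
    out$dice <- dice(pixel); out$iou <- iou(pixel)
    out$tp_px <- pixel$tp; out$fp_px <- pixel$fp; out$fn_px <- pixel$fn
  }
  if (!is.null(det)) {
    out <- c(out, det[c("tp", "fp", "fn", "precision", "recall", "f1")])
    out$wilson_precision <- unname(det$wilson_precision)
    out$wilson_recall <- unname(det$wilson_recall)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
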