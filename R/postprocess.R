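#' Fixed post-processing configuration
#'
#' The fixed pipeline applies, in this order: (1) restriction to a
#' convex-hull proxy ROI built from the annotation points, (2) exclusion of
#' objects smaller than `min_area_um2` (staining-noise fragments), and
#' (3) centroid-distance non-maximum suppression with gate
#' `nms_factor * min(r)` of the two equivalent radii. The defaults
#' (6 um^2, 0.7) are the operating values of the procedure this package
#' implements; the order is fixed and not configurable.
#'
#' @param min_area_um2 Strictly positive area threshold; objects with
#'   `area_um2 < min_area_um2` are removed.
#' @param nms_factor Positive gate multiplier in `(0, 1]`.
#' @param nms_mode `"suppress"` (drop the smaller duplicate, default) or
#'   `"union"` (merge records; see [nms_merge()]).
#' @param roi_rule Membership rule; only `"centroid"` is implemented.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(min_area_um2 = 6, nms_factor = 0.7,
                               nms_mode = c("suppress", "union"),
                               roi_rule = "centroid") {
  nms_mode <- match.arg(nms_mode)
  if (!is.numeric(min_area_um2) || min_area_um2 <= 0) {
    abort_input("min_area_um2 must be positive")
  }
  if (!is.numeric(nms_factor) || nms_factor <= 0 || nms_factor > 1) {
    abort_input("nms_factor must lie in (0, 1]")
  }
  if (!identical(roi_rule, "centroid")) {
    abort_input("only the centroid ROI membership rule is implemented")
  }
  structure(list(min_area_um2 = as.numeric(min_area_um2),
                 nms_factor = as.numeric(nms_factor),
                 nms_mode = nms_mode, roi_rule = roi_rule,
                 steps_order = c("roi", "min_area", "nms")),
            class = "postprocess_config")
}

#' Convex-hull proxy ROI from annotation points
#'
#' Builds the convex hull ("rubber band") around a set of annotation points,
#' used as a proxy for the capsule-bounded nodal region when the true ROI
#' outline is unavailable. Collinear or insufficient points are an error
#' rather than a zero-area polygon, because a silently empty ROI would
#' corrupt downstream counts.
#'
#' @param points Two-column matrix of um coordinates (>= 3 non-collinear).
#' @return An [roi_polygon()].
#' @export
convex_hull_roi <- function(points) {
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  if (nrow(pts) < 3L) {
    abort_input("convex hull needs at least 3 distinct annotation points")
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) {
    abort_input("annotation points are collinear; the hull is degenerate")
  }
  roi_polygon(pts[h, , drop = FALSE])
}

#' Restrict instances to an ROI
#'
#' Retains exactly the instances whose centroid lies inside or on the
#' boundary of the polygon.
#'
#' @param instances Instance table.
#' @param roi An [roi_polygon()].
#' @return The retained subset (row order preserved).
#' @export
restrict_to_roi <- function(instances, roi) {
  instances <- validate_instances(instances)
  if (!nrow(instances)) return(instances)
  keep <- points_in_polygon(instances$centroid_x_um, instances$centroid_y_um, roi)
  instances[keep, , drop = FALSE]
}

#' Minimum-area filter
#'
#' Removes objects strictly smaller than the threshold ("smaller than" is
#' strict: an object exactly at the threshold is retained).
#'
#' @param instances Instance table.
#' @param min_area_um2 Positive threshold in um^2.
#' @return The retained subset.
#' @export
filter_min_area <- function(instances, min_area_um2) {
  instances <- validate_instances(instances)
  if (!is.numeric(min_area_um2) || min_area_um2 <= 0) {
    abort_input("min_area_um2 must be positive")
  }
  instances[instances$area_um2 >= min_area_um2, , drop = FALSE]
}

#' Centroid-distance non-maximum suppression
#'
#' Duplicate detections are resolved greedily over instances sorted by
#' decreasing area (ties broken by ascending id): an instance is suppressed
#' when its centroid lies within `factor * min(r_i, r_j)` of an already
#' retained instance, where `r` is the equivalent radius. The single greedy
#' pass reaches a fixed point (re-applying it changes nothing). In
#' `"suppress"` mode the larger instance's record is kept unchanged; in
#' `"union"` mode a cluster is merged into one record with summed area and
#' area-weighted centroid (a record-level approximation of the pixel union;
#' the perimeter of a merged record is set to NA).
#'
#' @param instances Instance table.
#' @param factor Positive gate multiplier.
#' @param mode `"suppress"` or `"union"`.
#' @return The retained (or merged) instance table.
#' @export
nms_merge <- function(instances, factor = 0.7, mode = c("suppress", "union")) {
  mode <- match.arg(mode)
  instances <- validate_instances(instances)
  if (!is.numeric(factor) || factor <= 0) abort_input("factor must be positive")
  n <- nrow(instances)
  if (n <= 1L) return(instances)
  ord <- order(-instances$area_um2, instances$id)
  x <- instances$centroid_x_um[ord]
  y <- instances$centroid_y_um[ord]
  r <- instances$eq_radius_um[ord]
  assigned_to <- integer(n) # 0 = retained, else index (in ord) of suppressor
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept)) {
      d <- sqrt((x[kept] - x[i])^2 + (y[kept] - y[i])^2)
      gate <- factor * pmin(r[kept], r[i])
      hit <- which(d <= gate)
      if (length(hit)) {
        assigned_to[i] <- kept[hit[1L]]
        next
      }
    }
    kept <- c(kept, i)
  }
  if (mode == "suppress") {
    out <- instances[ord[kept], , drop = FALSE]
    out[order(out$id), , drop = FALSE]
  } else {
    merged <- lapply(kept, function(k) {
      members <- c(k, which(assigned_to == k))
      m <- instances[ord[members], , drop = FALSE]
      if (nrow(m) == 1L) return(m)
      a <- sum(m$area_um2)
      data.frame(id = m$id[1L],
                 centroid_x_um = sum(m$centroid_x_um * m$area_um2) / a,
                 centroid_y_um = sum(m$centroid_y_um * m$area_um2) / a,
                 area_px = if (all(!is.na(m$area_px))) sum(m$area_px) else NA_integer_,
                 area_um2 = a,
                 perimeter_um = NA_real_,
                 eq_radius_um = sqrt(a / pi))
    })
    out <- do.call(rbind, merged)
    validate_instances(out[order(out$id), , drop = FALSE])
  }
}

#' Apply the fixed three-step post-processing pipeline
#'
#' Steps run in the fixed order ROI -> minimum area -> NMS. The audit table
#' records the retained/removed instance count after each step, which is what
#' makes the procedure reportable.
#'
#' @param x Instance table, [label_field()] or [probability_field()] (a
#'   probability field is thresholded, labelled and measured first).
#' @param roi_points Two-column matrix of annotation points (um) from which
#'   the convex-hull proxy ROI is built, or an [roi_polygon()] directly.
#' @param config A [postprocess_config()].
#' @param threshold Probability threshold when `x` is a probability field.
#' @return A list with `instances` (final table), `audit` (data frame with
#'   columns step, retained, removed) and `roi` (the polygon used).
#' @export
apply_fixed_pipeline <- function(x, roi_points, config = postprocess_config(),
                                 threshold = 0.5) {
  stopifnot(inherits(config, "postprocess_config"))
  if (inherits(x, "probability_field")) {
    x <- label_components(threshold_probability(x, threshold))
  }
  if (inherits(x, "label_field")) x <- extract_instances(x)
  instances <- validate_instances(x)
  roi <- if (inherits(roi_points, "roi_polygon")) roi_points
         else convex_hull_roi(roi_points)

  audit <- data.frame(step = "input", retained = nrow(instances), removed = 0L,
                      stringsAsFactors = FALSE)
  s1 <- restrict_to_roi(instances, roi)
  audit <- rbind(audit, data.frame(step = "roi", retained = nrow(s1),
                                   removed = nrow(instances) - nrow(s1)))
  s2 <- filter_min_area(s1, config$min_area_um2)
  audit <- rbind(audit, data.frame(step = "min_area", retained = nrow(s2),
                                   removed = nrow(s1) - nrow(s2)))
  s3 <- nms_merge(s2, config$nms_factor, config$nms_mode)
  audit <- rbind(audit, data.frame(step = "nms", retained = nrow(s3),
                                   removed = nrow(s2) - nrow(s3)))
  list(instances = s3, audit = audit, roi = roi)
}
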