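#' Physical pixel calibration
#'
#' A calibration carries the physical pixel pitch of a scanned image and is
#' attached to every mask, instance table and polygon so that all downstream
#' morphometry is expressed in micrometres. The default of 0.137 um/px is a
#' typical 40x whole-slide scanner pitch.
#'
#' @param microns_per_pixel Positive length of one pixel side in micrometres.
#' @return An object of class `pixel_calibration`.
#' @examples
#' calib <- pixel_calibration(0.137)
#' area_px_to_um2(10, calib) # ~0.19 um^2
#' @export
pixel_calibration <- function(microns_per_pixel = 0.137) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    abort_input("microns_per_pixel must be a single positive finite number")
  }
  structure(
    list(microns_per_pixel = as.numeric(microns_per_pixel)),
    class = "pixel_calibration"
  )
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %g um/px (%g um^2/px)\n",
              x$microns_per_pixel, x$microns_per_pixel^2))
  invisible(x)
}

#' Convert a pixel area to square micrometres
#'
#' @param area_px Non-negative pixel count(s).
#' @param calib A [pixel_calibration()].
#' @return `area_px * microns_per_pixel^2`, unrounded.
#' @export
area_px_to_um2 <- function(area_px, calib) {
  stopifnot(inherits(calib, "pixel_calibration"))
  if (any(!is.finite(area_px)) || any(area_px < 0)) {
    abort_input("area_px must be non-negative and finite")
  }
  as.numeric(area_px) * calib$microns_per_pixel^2
}

#' Equivalent-circle radius of an area
#'
#' The equivalent radius of an object is the radius of the circle whose area
#' equals the object's area, r = sqrt(A / pi). It anchors both the centroid
#' distance gate used in matching and the non-maximum-suppression gate.
#'
#' @param area_um2 Positive area(s) in um^2.
#' @return Radius in um.
#' @export
equivalent_radius <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    abort_input("area_um2 must be positive and finite")
  }
  sqrt(area_um2 / pi)
}

#' Euclidean distance between the centroids of two instances
#'
#' @param p,g Either single-row instance tables (see [instance_records()]) or
#'   numeric `c(x, y)` coordinates in um.
#' @return Distance in um.
#' @export
centroid_distance <- function(p, g) {
  xy <- function(z) {
    if (is.data.frame(z)) {
      if (nrow(z) != 1L) abort_input("expected a single instance record")
      c(z$centroid_x_um, z$centroid_y_um)
    } else if (is.numeric(z) && length(z) == 2L) {
      as.numeric(z)
    } else {
      abort_input("centroid must be a 1-row instance record or length-2 numeric")
    }
  }
  a <- xy(p); b <- xy(g)
  if (any(!is.finite(c(a, b)))) abort_input("centroids must be finite")
  sqrt(sum((a - b)^2))
}

#' Intersection-over-union of two circles
#'
#' Closed-form IoU of two discs with radii `r1`, `r2` whose centres are `d`
#' apart, using the exact circular-lens intersection area with a containment
#' branch (no numerical integration). This is the overlap used by the
#' equivalent-circle matching mode, where each instance is represented by the
#' disc of its equivalent radius.
#'
#' @param r1,r2 Positive radii (um). Vectorised.
#' @param d Non-negative centre distance (um). Vectorised.
#' @return IoU in `[0, 1]`.
#' @examples
#' circle_iou(1, 1, 0) # 1
#' circle_iou(1, 1, 2) # 0 (externally tangent)
#' @export
circle_iou <- function(r1, r2, d) {
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(as.numeric(r1), n)
  r2 <- rep_len(as.numeric(r2), n)
  d <- rep_len(as.numeric(d), n)
  if (any(!is.finite(c(r1, r2, d))) || any(r1 <= 0) || any(r2 <= 0)) {
    abort_input("radii must be positive and finite")
  }
  if (any(d < 0)) abort_input("distance must be non-negative")

  inter <- numeric(n)
  disjoint <- d >= r1 + r2
  contained <- !disjoint & (d <= abs(r1 - r2))
  lens <- !disjoint & !contained

  rmin <- pmin(r1, r2)
  inter[contained] <- pi * rmin[contained]^2
  if (any(lens)) {
    a <- r1[lens]; b <- r2[lens]; dd <- d[lens]
    # clamp acos arguments against roundoff at tangency
    ca <- pmin(1, pmax(-1, (dd^2 + a^2 - b^2) / (2 * dd * a)))
    cb <- pmin(1, pmax(-1, (dd^2 + b^2 - a^2) / (2 * dd * b)))
    tri <- (-dd + a + b) * (dd + a - b) * (dd - a + b) * (dd + a + b)
    inter[lens] <- a^2 * acos(ca) + b^2 * acos(cb) -
      0.5 * sqrt(pmax(0, tri))
  }
  uni <- pi * r1^2 + pi * r2^2 - inter
  pmin(1, pmax(0, inter / uni))
}
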