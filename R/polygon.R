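#' Region-of-interest polygons
#'
#' An ROI polygon is a closed planar polygon in physical um coordinates,
#' stored as an open ring (the closing vertex is implicit). Self-intersecting
#' rings are rejected because membership would be ambiguous.
#'
#' @param vertices Two-column numeric matrix (x, y) in um, >= 3 rows.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    abort_input("vertices must be a two-column numeric matrix")
  }
  if (any(!is.finite(v))) abort_input("polygon vertices must be finite")
  # drop an explicit closing vertex
  if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) abort_input("a polygon needs at least 3 distinct vertices")
  if (polygon_self_intersects(v)) {
    abort_input(paste0(
      "polygon is self-intersecting: non-adjacent edges cross, so ",
      "inside/outside membership is ambiguous"))
  }
  if (abs(polygon_area(v)) < .Machine$double.eps) {
    abort_input("polygon is degenerate (zero area)")
  }
  structure(list(vertices = v), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %d vertices, area %.4g um^2\n",
              nrow(x$vertices), abs(polygon_area(x$vertices))))
  invisible(x)
}

# signed shoelace area of an open ring
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# do two closed segments properly or improperly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(v[idx[i, 1], ], v[idx[i, 2], ],
                             v[idx[j, 1], ], v[idx[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-polygon membership (boundary counts as inside)
#'
#' Crossing-number test with an explicit on-boundary branch so that points
#' lying exactly on an edge or vertex are classed as inside, matching the
#' membership convention used for ROI restriction.
#'
#' @param x,y Point coordinates in um (vectorised).
#' @param roi An [roi_polygon()].
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  v <- roi$vertices
  n <- nrow(v)
  x <- as.numeric(x); y <- as.numeric(y)
  scale <- max(abs(v), 1)
  eps <- 1e-9 * scale
  inside <- logical(length(x))
  boundary <- logical(length(x))
  xi <- v[, 1]; yi <- v[, 2]
  xj <- c(xi[-1], xi[1]); yj <- c(yi[-1], yi[1])
  for (k in seq_len(n)) {
    ax <- xi[k]; ay <- yi[k]; bx <- xj[k]; by <- yj[k]
    # on-segment test
    cross <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
    within <- x >= pmin(ax, bx) - eps & x <= pmax(ax, bx) + eps &
      y >= pmin(ay, by) - eps & y <= pmax(ay, by) + eps
    boundary <- boundary | (abs(cross) <= eps * max(abs(c(ax, ay, bx, by, 1))) & within)
    # ray casting (horizontal ray to +x)
    crosses <- ((ay > y) != (by > y)) &
      (x < (bx - ax) * (y - ay) / (by - ay) + ax)
    inside <- xor(inside, crosses)
  }
  inside | boundary
}
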