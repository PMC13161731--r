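#' Labelled and probability fields
#'
#' A `label_field` is a calibrated raster of non-negative integer instance
#' labels (0 = background); a `probability_field` is a calibrated raster of
#' per-pixel foreground probabilities in `[0, 1]`. Rasters are stored as R
#' matrices indexed `[row, col]` with row = y (increasing downward) and
#' col = x; pixel `(i, j)` has its physical centre at
#' `((j - 0.5) * s, (i - 0.5) * s)` um for pixel pitch `s`.
#'
#' @param labels Integer matrix of labels (0 = background).
#' @param calib A [pixel_calibration()].
#' @return A `label_field` / `probability_field`.
#' @export
label_field <- function(labels, calib) {
  stopifnot(inherits(calib, "pixel_calibration"))
  m <- as.matrix(labels)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0L)) {
    abort_input("labels must be non-negative integers without NA")
  }
  structure(list(labels = m, calib = calib), class = "label_field")
}

#' @rdname label_field
#' @param values Numeric matrix of probabilities in `[0, 1]`.
#' @export
probability_field <- function(values, calib) {
  stopifnot(inherits(calib, "pixel_calibration"))
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort_input("probabilities must lie in [0, 1]")
  }
  structure(list(values = m, calib = calib), class = "probability_field")
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("<label_field> %d x %d px, %d instance(s), %g um/px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$calib$microns_per_pixel))
  invisible(x)
}

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf("<probability_field> %d x %d px, %g um/px\n",
              nrow(x$values), ncol(x$values), x$calib$microns_per_pixel))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal baseline TIFF codec (single-channel, uncompressed, 8/16-bit).
# No TIFF reader is available in the dependency set, so the subset of the
# baseline format needed for label masks is implemented here directly.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw already padded to 4 bytes
  c(u16le(tag), u16le(type), u32le(count), value_raw)
}

#' Read and write label masks as single-channel TIFF
#'
#' Masks are stored as uncompressed single-strip grayscale baseline TIFF
#' (8-bit when the maximum label fits, 16-bit otherwise). `read_mask()`
#' accepts any uncompressed single-channel baseline TIFF in either byte
#' order; a round-trip `write_mask()` then `read_mask()` reproduces the
#' labels bit-exactly.
#'
#' @param path File path ending in `.tif` or `.tiff`.
#' @param calib A [pixel_calibration()] to attach on read.
#' @return `read_mask()` returns a [label_field()].
#' @export
read_mask <- function(path, calib) {
  stopifnot(inherits(calib, "pixel_calibration"))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    abort_input("only single-channel TIFF masks are supported (.tif/.tiff)")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) abort_input("not a TIFF file (truncated header)")
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else abort_input("not a TIFF file (bad byte-order mark)")
  rd16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                size = 2, signed = FALSE, endian = endian)
  rd32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                                size = 4, endian = endian)
  if (rd16(2) != 42L) abort_input("not a TIFF file (bad magic)")
  ifd <- rd32(4)
  nent <- rd16(ifd)
  tags <- list()
  for (k in seq_len(nent)) {
    off <- ifd + 2 + (k - 1) * 12
    tag <- rd16(off); type <- rd16(off + 2); count <- rd32(off + 4)
    size <- c(1, 1, 2, 4, 8)[type] # BYTE ASCII SHORT LONG RATIONAL
    if (is.na(size)) next
    voff <- if (size * count <= 4) off + 8 else rd32(off + 8)
    vals <- vapply(seq_len(count), function(i) {
      if (type == 3L) rd16(voff + (i - 1) * 2) else rd32(voff + (i - 1) * 4)
    }, numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) abort_input(sprintf("TIFF tag %d missing", tag))
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 8)
  if (length(bits) != 1L || !(bits %in% c(8, 16))) {
    abort_input("only single-channel 8/16-bit masks are supported")
  }
  if (need(259, 1) != 1) abort_input("compressed TIFF is not supported")
  if (need(277, 1) != 1) abort_input("multi-channel masks are not supported")
  offsets <- need(273); counts <- need(279, width * height * bits / 8)
  data <- unlist(lapply(seq_along(offsets), function(i) {
    raw[(offsets[i] + 1):(offsets[i] + counts[i])]
  }))
  px <- readBin(data, "integer", n = width * height, size = bits / 8,
                signed = FALSE, endian = endian)
  m <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
  label_field(m, calib)
}

#' @rdname read_mask
#' @param field A [label_field()] to write.
#' @export
write_mask <- function(field, path) {
  stopifnot(inherits(field, "label_field"))
  m <- field$labels
  maxv <- if (length(m)) max(m) else 0L
  if (maxv > 65535L) abort_input("label values exceed 16-bit range")
  bits <- if (maxv > 255L) 16L else 8L
  height <- nrow(m); width <- ncol(m)
  nbytes <- width * height * bits / 8
  data_off <- 8L
  ifd_off <- data_off + nbytes
  short_val <- function(x) c(u16le(x), as.raw(c(0, 0)))
  entries <- c(
    tiff_entry(256, 4, 1, u32le(width)),
    tiff_entry(257, 4, 1, u32le(height)),
    tiff_entry(258, 3, 1, short_val(bits)),
    tiff_entry(259, 3, 1, short_val(1)),   # no compression
    tiff_entry(262, 3, 1, short_val(1)),   # black is zero
    tiff_entry(273, 4, 1, u32le(data_off)),
    tiff_entry(277, 3, 1, short_val(1)),
    tiff_entry(278, 4, 1, u32le(height)),
    tiff_entry(279, 4, 1, u32le(nbytes))
  )
  header <- c(as.raw(c(0x49, 0x49)), u16le(42), u32le(ifd_off))
  ifd <- c(u16le(9), entries, u32le(0))
  pix <- writeBin(as.integer(t(m)), raw(), size = bits / 8, endian = "little")
  writeBin(c(header, pix, ifd), path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Threshold a probability field to a binary field
#'
#' A pixel is foreground iff its probability is greater than or equal to the
#' threshold. The result is an unlabelled binary field (labels 0/1); pass it
#' through [label_components()] to obtain instances.
#'
#' @param prob A [probability_field()].
#' @param t Threshold in `[0, 1]`.
#' @return A binary [label_field()].
#' @export
threshold_probability <- function(prob, t) {
  stopifnot(inherits(prob, "probability_field"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    abort_input("threshold must be a single value in [0, 1]")
  }
  label_field((prob$values >= t) * 1L, prob$calib)
}

#' Label connected components of a binary field
#'
#' Maximal connected components of the foreground receive distinct labels
#' 1..K in deterministic raster-scan order. The default is 8-connectivity so
#' that slender diagonal vessel profiles are not shattered into fragments.
#'
#' @param field A [label_field()] (any positive label counts as foreground)
#'   or a logical matrix plus `calib`.
#' @param connectivity 4 or 8.
#' @param calib Calibration, required when `field` is a bare matrix.
#' @return A [label_field()] with labels 1..K.
#' @export
label_components <- function(field, connectivity = 8, calib = NULL) {
  if (inherits(field, "label_field")) {
    fg <- field$labels > 0L
    calib <- field$calib
  } else {
    if (is.null(calib)) abort_input("calib is required for a bare matrix")
    fg <- as.matrix(field) > 0
  }
  lab <- cc_label_cpp(fg, as.integer(connectivity))
  label_field(lab, calib)
}

# Crofton perimeter (pixel units) of a logical mask from boundary-crossing
# counts along four line families (0, 45, 90, 135 degrees):
#   P ~ (pi/8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
# (Cauchy-Crofton with 4 directions; exact in expectation for discs, and the
# raw marching-squares polygon length overestimates smooth boundaries by
# ~6-8%, which is why it is not used here.)
crofton_perimeter_px <- function(mask) {
  P <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(P); nc <- ncol(P)
  n_h <- sum(P[, -1] != P[, -nc])
  n_v <- sum(P[-1, ] != P[-nr, ])
  n_d1 <- sum(P[-nr, -nc] != P[-1, -1])
  n_d2 <- sum(P[-1, -nc] != P[-nr, -1])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Extract calibrated instance morphometry from a labelled field
#'
#' One record per positive label: pixel area, physical area, centroid in um
#' (pixel-centre convention), Crofton boundary length, and the
#' equivalent-circle radius.
#'
#' @param field A [label_field()].
#' @return A data frame of instance records (see [instance_records()]),
#'   ordered by label; empty when the field has no foreground.
#' @export
extract_instances <- function(field) {
  stopifnot(inherits(field, "label_field"))
  m <- field$labels
  s <- field$calib$microns_per_pixel
  idx <- which(m > 0L)
  if (!length(idx)) return(empty_instances())
  lab <- m[idx]
  nr <- nrow(m)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  ids <- sort(unique(lab))
  area_px <- as.integer(rowsum(rep(1L, length(lab)), lab)[, 1])
  cx <- (rowsum(col - 0.5, lab)[, 1] / area_px) * s
  cy <- (rowsum(row - 0.5, lab)[, 1] / area_px) * s

  rmin <- tapply(row, lab, min); rmax <- tapply(row, lab, max)
  cmin <- tapply(col, lab, min); cmax <- tapply(col, lab, max)
  per <- vapply(seq_along(ids), function(k) {
    sub <- m[rmin[k]:rmax[k], cmin[k]:cmax[k], drop = FALSE] == ids[k]
    crofton_perimeter_px(sub) * s
  }, numeric(1))

  instance_records(
    id = ids,
    centroid_x_um = cx,
    centroid_y_um = cy,
    area_um2 = area_px_to_um2(area_px, field$calib),
    perimeter_um = per,
    area_px = area_px
  )
}

# ---------------------------------------------------------------------------
# ROI annotations (GeoJSON) and instance tables (CSV)

#' Read and write ROI annotations as GeoJSON
#'
#' Annotation point sets are stored as GeoJSON `MultiPoint` and region
#' outlines as GeoJSON `Polygon`. Coordinates are physical um by convention;
#' files written in pixel units can be converted on read with `units = "px"`
#' and a calibration.
#'
#' @param path GeoJSON file path.
#' @param units `"um"` (default) or `"px"`.
#' @param calib Required when `units = "px"`.
#' @return `read_roi_points()`: a two-column matrix of um coordinates;
#'   `read_roi_polygon()`: an [roi_polygon()].
#' @export
read_roi_points <- function(path, units = c("um", "px"), calib = NULL) {
  units <- match.arg(units)
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$type) && identical(gj$type, "MultiPoint")) gj
          else if (!is.null(gj$geometry)) gj$geometry
          else abort_input("expected a GeoJSON MultiPoint geometry or feature")
  if (!identical(geom$type, "MultiPoint")) {
    abort_input("expected a GeoJSON MultiPoint geometry")
  }
  pts <- matrix(as.numeric(as.matrix(geom$coordinates)), ncol = 2)
  if (units == "px") {
    if (is.null(calib)) abort_input("calib is required for pixel-unit files")
    pts <- pts * calib$microns_per_pixel
  }
  colnames(pts) <- c("x_um", "y_um")
  pts
}

#' @rdname read_roi_points
#' @param points Two-column matrix of um coordinates.
#' @export
write_roi_points <- function(points, path) {
  pts <- as.matrix(points)
  gj <- list(type = "MultiPoint",
             coordinates = lapply(seq_len(nrow(pts)),
                                  function(i) as.numeric(pts[i, 1:2])))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_roi_points
#' @export
read_roi_polygon <- function(path, units = c("um", "px"), calib = NULL) {
  units <- match.arg(units)
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$type) && identical(gj$type, "Polygon")) gj
          else if (!is.null(gj$geometry)) gj$geometry
          else abort_input("expected a GeoJSON Polygon geometry or feature")
  if (!identical(geom$type, "Polygon")) {
    abort_input("expected a GeoJSON Polygon geometry")
  }
  ring <- geom$coordinates
  if (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3) ring <- ring[1, , ]
  v <- matrix(as.numeric(as.matrix(ring)), ncol = 2)
  if (units == "px") {
    if (is.null(calib)) abort_input("calib is required for pixel-unit files")
    v <- v * calib$microns_per_pixel
  }
  roi_polygon(v)
}

#' @rdname read_roi_points
#' @param roi An [roi_polygon()].
#' @export
write_roi_polygon <- function(roi, path) {
  stopifnot(inherits(roi, "roi_polygon"))
  v <- roi$vertices
  ring <- lapply(c(seq_len(nrow(v)), 1L), function(i) as.numeric(v[i, ]))
  gj <- list(type = "Polygon", coordinates = list(ring))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write instance tables as CSV
#'
#' Comma-separated UTF-8 with a header row and a leading comment line that
#' echoes the calibration (`# microns_per_pixel=...`). Numeric fields
#' round-trip at full double precision.
#'
#' @param x Instance table (see [instance_records()]).
#' @param path CSV path.
#' @param calib Optional calibration echoed into the header comment.
#' @return `read_instances_csv()` returns the validated instance table with
#'   the calibration (if present) in attribute `"calib"`.
#' @export
write_instances_csv <- function(x, path, calib = NULL) {
  x <- validate_instances(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(calib)) {
    stopifnot(inherits(calib, "pixel_calibration"))
    writeLines(sprintf("# microns_per_pixel=%.17g", calib$microns_per_pixel), con)
  }
  out <- x
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_instances_csv
#' @export
read_instances_csv <- function(path) {
  first <- readLines(path, n = 1L)
  calib <- NULL
  if (startsWith(first, "#")) {
    mpp <- sub("^#\\s*microns_per_pixel=", "", first)
    calib <- pixel_calibration(as.numeric(mpp))
  }
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  x <- validate_instances(x)
  attr(x, "calib") <- calib
  x
}
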