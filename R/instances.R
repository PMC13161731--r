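#' Instance record tables
#'
#' Vessel instances are carried as plain data frames with one row per object
#' and the columns `id`, `centroid_x_um`, `centroid_y_um`, `area_px`,
#' `area_um2`, `perimeter_um`, `eq_radius_um`. `instance_records()` builds a
#' validated table from components; `validate_instances()` checks an existing
#' one. `eq_radius_um` is recomputed from `area_um2` when missing.
#'
#' @param id Instance identifiers (coerced to integer).
#' @param centroid_x_um,centroid_y_um Centroid coordinates in um
#'   (pixel-centre convention, y increasing downward).
#' @param area_um2 Positive areas in um^2.
#' @param perimeter_um Optional boundary lengths in um (NA if unknown).
#' @param area_px Optional integer pixel counts (NA if not mask-derived).
#' @param eq_radius_um Optional; recomputed as `sqrt(area_um2/pi)` if missing.
#' @return A data frame of instance records.
#' @export
instance_records <- function(id, centroid_x_um, centroid_y_um, area_um2,
                             perimeter_um = NA_real_, area_px = NA_integer_,
                             eq_radius_um = NULL) {
  n <- length(id)
  if (is.null(eq_radius_um)) {
    eq_radius_um <- if (n) equivalent_radius(area_um2) else numeric(0)
  }
  out <- data.frame(
    id = as.integer(id),
    centroid_x_um = as.numeric(centroid_x_um),
    centroid_y_um = as.numeric(centroid_y_um),
    area_px = rep_len(suppressWarnings(as.integer(area_px)), n),
    area_um2 = as.numeric(area_um2),
    perimeter_um = rep_len(as.numeric(perimeter_um), n),
    eq_radius_um = as.numeric(eq_radius_um),
    stringsAsFactors = FALSE
  )
  validate_instances(out)
}

#' @rdname instance_records
#' @param x A data frame to validate.
#' @export
validate_instances <- function(x) {
  need <- c("id", "centroid_x_um", "centroid_y_um", "area_px", "area_um2",
            "perimeter_um", "eq_radius_um")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort_input(paste0("instance table must contain columns: ",
                       paste(need, collapse = ", ")))
  }
  if (anyDuplicated(x$id)) abort_input("instance ids must be unique")
  if (nrow(x)) {
    if (any(!is.finite(x$area_um2)) || any(x$area_um2 <= 0)) {
      abort_input("area_um2 must be positive")
    }
    if (any(!is.finite(x$centroid_x_um)) || any(!is.finite(x$centroid_y_um))) {
      abort_input("centroids must be finite")
    }
    rel <- abs(x$eq_radius_um - sqrt(x$area_um2 / pi)) /
      sqrt(x$area_um2 / pi)
    if (any(rel > 1e-9)) {
      abort_input("eq_radius_um inconsistent with area_um2 (r = sqrt(A/pi))")
    }
  }
  x[need]
}

empty_instances <- function() {
  instance_records(integer(0), numeric(0), numeric(0), numeric(0))
}
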