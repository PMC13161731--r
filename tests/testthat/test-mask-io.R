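calib1 <- pixel_calibration(1.0)

test_that("TIFF mask round-trip is bit-exact for 8- and 16-bit labels", {
  set.seed(5)
  # 8-bit
  m <- matrix(sample(0:200, 40 * 30, replace = TRUE), 30, 40)
  fld <- label_field(m, calib1)
  p <- withr::local_tempfile(fileext = ".tif")
  write_mask(fld, p)
  back <- read_mask(p, calib1)
  expect_identical(back$labels, fld$labels)
  # 16-bit with 300 labels preserved
  m2 <- matrix(0L, 60, 50)
  m2[cbind(sample(1:60, 300, TRUE), sample(1:50, 300, TRUE))] <- 1L
  lf <- label_components(m2 > 0, calib = calib1, connectivity = 8)
  k <- max(lf$labels)
  big <- label_field(matrix(sample(0:k, 60 * 50, TRUE) + 300L, 60, 50), calib1)
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_mask(big, p2)
  expect_identical(read_mask(p2, calib1)$labels, big$labels)
  # all-zero raster -> no instances
  z <- label_field(matrix(0L, 5, 5), calib1)
  p3 <- withr::local_tempfile(fileext = ".tif")
  write_mask(z, p3)
  expect_equal(nrow(extract_instances(read_mask(p3, calib1))), 0)
})

test_that("probability thresholding is >= and validates its inputs", {
  pf <- probability_field(matrix(0.6, 4, 4), calib1)
  expect_true(all(threshold_probability(pf, 0.5)$labels == 1L))
  pf <- probability_field(matrix(0.4, 4, 4), calib1)
  expect_true(all(threshold_probability(pf, 0.5)$labels == 0L))
  half <- probability_field(cbind(matrix(0.3, 4, 2), matrix(0.8, 4, 2)), calib1)
  out <- threshold_probability(half, 0.5)$labels
  expect_equal(out[, 1:2], matrix(0L, 4, 2))
  expect_equal(out[, 3:4], matrix(1L, 4, 2))
  expect_true(all(threshold_probability(probability_field(matrix(0.2, 2, 2), calib1), 0)$labels == 1L))
  expect_error(threshold_probability(pf, 1.2), class = "vq_input_error")
  expect_error(probability_field(matrix(1.5, 2, 2), calib1),
               class = "vq_input_error")
})

test_that("connected components match connectivity semantics and a flood-fill oracle", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[7:9, 7:9] <- 1L
  expect_equal(max(label_components(m > 0, calib = calib1)$labels), 2L)
  # diagonal touch: one blob under 8-connectivity, two under 4
  d <- matrix(0L, 6, 6)
  d[2:3, 2:3] <- 1L
  d[4:5, 4:5] <- 1L
  expect_equal(max(label_components(d > 0, 8, calib1)$labels), 1L)
  expect_equal(max(label_components(d > 0, 4, calib1)$labels), 2L)
  # randomized speck fields against the oracle
  set.seed(31)
  for (i in 1:5) {
    r <- matrix(runif(40 * 40) < 0.25, 40, 40)
    for (conn in c(4, 8)) {
      got <- label_components(r, conn, calib1)$labels
      want <- flood_fill_labels(r, conn)
      expect_equal(max(got), max(want))
      # same partition: labels must be a bijection of oracle labels
      expect_equal(length(unique(paste(got[r], want[r]))), max(want))
    }
  }
})

test_that("instance extraction obeys calibration, centroid convention and accuracy bounds", {
  # a 10-px blob at 0.137 um/px has the reference-rule area ~0.19 um^2
  calib <- pixel_calibration(0.137)
  m <- matrix(0L, 8, 8)
  m[3:4, 3:7] <- 1L
  inst <- extract_instances(label_field(m, calib))
  expect_equal(inst$area_px, 10L)
  expect_equal(inst$area_um2, 0.18769)
  # pixel-centre convention for a single pixel at (row 3, col 5)
  s <- 0.5
  m <- matrix(0L, 6, 6); m[3, 5] <- 1L
  one <- extract_instances(label_field(m, pixel_calibration(s)))
  expect_equal(one$centroid_x_um, (5 - 0.5) * s)
  expect_equal(one$centroid_y_um, (3 - 0.5) * s)
  # disc of radius 40 px: perimeter within 5% of 2*pi*r
  n <- 101; m <- matrix(0L, n, n); ctr <- 50.5
  ii <- matrix(seq_len(n) - 0.5, n, n)
  jj <- t(ii)
  m[(ii - ctr)^2 + (jj - ctr)^2 <= 40^2] <- 1L
  disc <- extract_instances(label_field(m, calib1))
  expect_lt(abs(disc$perimeter_um / (2 * pi * 40) - 1), 0.05)
  expect_lt(abs(disc$area_um2 / (pi * 40^2) - 1), 0.02)
})

test_that("ellipse morphometry matches analytic area and Ramanujan perimeter", {
  a <- 20; b <- 10
  n <- 61; m <- matrix(0L, n, n); ctr <- 30.5
  ii <- matrix(seq_len(n) - 0.5, n, n); jj <- t(ii)
  m[((jj - ctr) / a)^2 + ((ii - ctr) / b)^2 <= 1] <- 1L
  e <- extract_instances(label_field(m, calib1))
  ram <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_lt(abs(e$area_um2 / (pi * a * b) - 1), 0.02)
  expect_lt(abs(e$perimeter_um / ram - 1), 0.05)
})

test_that("extraction conserves pixel area and is label-permutation invariant", {
  set.seed(9)
  m <- matrix(0L, 30, 30)
  m[2:6, 2:6] <- 1L; m[10:15, 20:24] <- 2L; m[20:28, 3:10] <- 3L
  inst <- extract_instances(label_field(m, calib1))
  expect_equal(sum(inst$area_px), sum(m > 0))
  # permute labels 1,2,3 -> 3,1,2
  mp <- m
  mp[m == 1L] <- 3L; mp[m == 2L] <- 1L; mp[m == 3L] <- 2L
  instp <- extract_instances(label_field(mp, calib1))
  key <- function(x) x[order(x$area_um2, x$centroid_x_um),
                       c("area_px", "area_um2", "perimeter_um",
                         "centroid_x_um", "centroid_y_um")]
  expect_equal(key(inst), key(instp), ignore_attr = TRUE)
})

test_that("ROI GeoJSON and instance CSV round-trips preserve values", {
  pts <- cbind(x_um = c(0, 10, 10, 0, 5), y_um = c(0, 0, 10, 10, 5))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_roi_points(pts, p)
  expect_equal(unname(read_roi_points(p)), unname(pts))
  sq <- roi_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  p2 <- withr::local_tempfile(fileext = ".geojson")
  write_roi_polygon(sq, p2)
  expect_equal(read_roi_polygon(p2)$vertices, sq$vertices)
  # pixel-unit read applies the calibration
  expect_equal(read_roi_polygon(p2, units = "px",
                                calib = pixel_calibration(0.5))$vertices,
               sq$vertices * 0.5)
  # self-intersecting ring is rejected with an explanation
  expect_error(roi_polygon(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))),
               "self-intersecting", class = "vq_input_error")
  # CSV: 1000 instances round-trip field-identical
  set.seed(2)
  x <- instance_records(1:1000, runif(1000, 0, 5000), runif(1000, 0, 5000),
                        rlnorm(1000, log(100), 1), runif(1000, 5, 50),
                        sample(10:99999, 1000))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_instances_csv(x, p3, calib = pixel_calibration(0.137))
  back <- read_instances_csv(p3)
  expect_equal(back, x, ignore_attr = TRUE)
  expect_equal(attr(back, "calib")$microns_per_pixel, 0.137)
})
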