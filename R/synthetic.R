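#' Synthetic vessel-field specification
#'
#' Describes a ground-truth field of non-overlapping vessel profiles that
#' emulates the ROI-level morphometry of immunostained lymph-node regions:
#' per-ROI counts in the hundreds to thousands at roughly 1e-4 vessels/um^2,
#' median instance area near 100 um^2 with a heavy log-normal right tail
#' (maxima in the 10^3-10^5 um^2 range), and a morphology mixture of filled
#' discs (capillary cross-sections), annuli (vessels with unstained lumina)
#' and curved tubes (longitudinally cut vessels).
#'
#' @param width_um,height_um Field dimensions (um).
#' @param target_count Number of instances to place.
#' @param area_meanlog,area_sdlog Log-normal area parameters (um^2 scale);
#'   defaults give a median of 100 um^2 with a heavy right tail.
#' @param area_min_um2 Lower truncation of the area distribution.
#' @param shape_mix Named proportions for disc / annulus / tube; must sum
#'   to 1.
#' @param large_vessel_rate Proportion of instances drawn from the
#'   conditional tail above `large_area_um2`.
#' @param large_area_um2 Tail threshold for "large" vessels.
#' @param seed RNG seed owned by the generator.
#' @return A `field_spec` list.
#' @export
field_spec <- function(width_um = 2000, height_um = 2000, target_count = 500,
                       area_meanlog = log(100), area_sdlog = 1.2,
                       area_min_um2 = 10,
                       shape_mix = c(disc = 0.3, annulus = 0.4, tube = 0.3),
                       large_vessel_rate = 0.01, large_area_um2 = 5000,
                       seed = 1L) {
  if (width_um <= 0 || height_um <= 0) abort_input("field dimensions must be positive")
  if (target_count < 0) abort_input("target_count must be non-negative")
  if (abs(sum(shape_mix) - 1) > 1e-9 || any(shape_mix < 0)) {
    abort_input("shape_mix proportions must be non-negative and sum to 1")
  }
  if (!all(c("disc", "annulus", "tube") %in% names(shape_mix))) {
    abort_input("shape_mix must name disc, annulus and tube")
  }
  structure(list(width_um = width_um, height_um = height_um,
                 target_count = as.integer(target_count),
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 area_min_um2 = area_min_um2, shape_mix = shape_mix,
                 large_vessel_rate = large_vessel_rate,
                 large_area_um2 = large_area_um2, seed = seed),
            class = "field_spec")
}

#' Degradation specification for synthetic predictions
#'
#' Emulates the residual error modes of a segmentation model on vessel
#' fields: instance dropout (false negatives), small spurious specks below
#' the staining-noise threshold (false positives), fragmentation of large
#' vessels into short dot-like pieces, and centroid/area measurement noise.
#'
#' @param fn_rate Dropout probability per truth instance.
#' @param fp_speck_rate Expected spurious specks per 1e4 um^2 of field.
#' @param fp_speck_area_range Speck area range (um^2); the default stays
#'   below the 6 um^2 filter so specks exercise the minimum-area step (the
#'   4.5 upper bound leaves one pixel of rasterisation headroom at the
#'   1 um/px desk scale).
#' @param fragment_prob Probability that a large vessel is replaced by
#'   fragments.
#' @param fragment_count_range Integer range of pieces per fragmented vessel.
#' @param fragment_min_area_um2 Area above which a vessel counts as "large"
#'   for fragmentation.
#' @param centroid_jitter_sd_um Gaussian jitter SD applied to surviving
#'   centroids (um).
#' @param area_noise_cv Coefficient of variation of multiplicative area
#'   noise.
#' @param seed RNG seed owned by the degradation.
#' @return A `degrade_spec` list.
#' @export
degrade_spec <- function(fn_rate = 0, fp_speck_rate = 0,
                         fp_speck_area_range = c(1.5, 4.5),
                         fragment_prob = 0, fragment_count_range = c(3L, 6L),
                         fragment_min_area_um2 = 1000,
                         centroid_jitter_sd_um = 0, area_noise_cv = 0,
                         seed = 1L) {
  if (fn_rate < 0 || fn_rate > 1 || fragment_prob < 0 || fragment_prob > 1) {
    abort_input("probabilities must lie in [0, 1]")
  }
  if (centroid_jitter_sd_um < 0 || area_noise_cv < 0 || fp_speck_rate < 0) {
    abort_input("noise parameters must be non-negative")
  }
  structure(list(fn_rate = fn_rate, fp_speck_rate = fp_speck_rate,
                 fp_speck_area_range = fp_speck_area_range,
                 fragment_prob = fragment_prob,
                 fragment_count_range = as.integer(fragment_count_range),
                 fragment_min_area_um2 = fragment_min_area_um2,
                 centroid_jitter_sd_um = centroid_jitter_sd_um,
                 area_noise_cv = area_noise_cv, seed = seed),
            class = "degrade_spec")
}

# ---------------------------------------------------------------------------
# parametric shapes (um units, geometry centred at the origin)

make_shape <- function(type, area, px_um) {
  if (type == "annulus") {
    f <- runif(1, 0.35, 0.6)
    r_out <- sqrt(area / (pi * (1 - f^2)))
    if (r_out * (1 - f) >= 1.8 * px_um) {
      return(list(type = "annulus", r_out = r_out, r_in = f * r_out,
                  area = area, bound_r = r_out))
    }
    type <- "disc" # ring too thin to rasterise; fall back
  }
  if (type == "tube") {
    aspect <- runif(1, 2.5, 5)
    w <- max(sqrt(area / aspect), 2 * px_um)
    # rasterised area ~ len * w + pi * (w/2)^2 (rounded end caps); subtract
    # the caps so the target area is met
    len <- max((area - pi * w^2 / 4) / w, w)
    nseg <- 4L
    headings <- runif(1, 0, 2 * pi) + cumsum(rnorm(nseg, 0, 0.35))
    step <- len / nseg
    pts <- rbind(c(0, 0),
                 apply(cbind(cos(headings), sin(headings)) * step, 2, cumsum))
    ctr <- c(mean(range(pts[, 1])), mean(range(pts[, 2])))
    pts <- sweep(pts, 2, ctr)
    bound <- max(sqrt(rowSums(pts^2))) + w / 2
    return(list(type = "tube", path = pts, w = w, area = area, bound_r = bound))
  }
  r <- sqrt(area / pi)
  list(type = "disc", r = r, area = area, bound_r = r)
}

# pixel linear indices covered by a shape placed at (cx, cy) um
shape_pixels <- function(sh, cx, cy, nr, nc, s) {
  grid_idx <- function(x0, x1, y0, y1, keep_fun) {
    j0 <- max(1L, floor(x0)); j1 <- min(nc, ceiling(x1))
    i0 <- max(1L, floor(y0)); i1 <- min(nr, ceiling(y1))
    if (j0 > j1 || i0 > i1) return(integer(0))
    jj <- j0:j1; ii <- i0:i1
    xs <- jj - 0.5; ys <- ii - 0.5
    m <- keep_fun(xs, ys)
    w <- which(m, arr.ind = TRUE)
    if (!nrow(w)) return(integer(0))
    (jj[w[, 2]] - 1L) * nr + ii[w[, 1]]
  }
  cxp <- cx / s; cyp <- cy / s
  if (sh$type == "disc") {
    r <- sh$r / s
    idx <- grid_idx(cxp - r, cxp + r, cyp - r, cyp + r, function(xs, ys) {
      outer((ys - cyp)^2, (xs - cxp)^2, "+") <= r^2
    })
  } else if (sh$type == "annulus") {
    ro <- sh$r_out / s; ri <- sh$r_in / s
    idx <- grid_idx(cxp - ro, cxp + ro, cyp - ro, cyp + ro, function(xs, ys) {
      d2 <- outer((ys - cyp)^2, (xs - cxp)^2, "+")
      d2 <= ro^2 & d2 > ri^2
    })
  } else {
    path <- sweep(sh$path, 2, c(cx, cy), "+") / s
    h <- (sh$w / 2) / s
    idx <- grid_idx(min(path[, 1]) - h, max(path[, 1]) + h,
                    min(path[, 2]) - h, max(path[, 2]) + h,
                    function(xs, ys) {
      nx <- length(xs); ny <- length(ys)
      px <- matrix(xs, ny, nx, byrow = TRUE)
      py <- matrix(ys, ny, nx)
      d2 <- matrix(Inf, ny, nx)
      for (k in seq_len(nrow(path) - 1L)) {
        a <- path[k, ]; b <- path[k + 1L, ]
        ab2 <- sum((b - a)^2)
        t <- if (ab2 == 0) 0 else ((px - a[1]) * (b[1] - a[1]) +
                                   (py - a[2]) * (b[2] - a[2])) / ab2
        t <- pmin(1, pmax(0, t))
        d2 <- pmin(d2, (px - (a[1] + t * (b[1] - a[1])))^2 +
                        (py - (a[2] + t * (b[2] - a[2])))^2)
      }
      d2 <= h^2
    })
  }
  if (!length(idx)) {
    # guarantee at least the centre pixel so every shape exists in the raster
    i <- min(max(1L, round(cyp + 0.5)), nr)
    j <- min(max(1L, round(cxp + 0.5)), nc)
    idx <- (j - 1L) * nr + i
  }
  idx
}

# sequential packing with disjoint bounding circles (plus a margin), so
# placed shapes can never touch in the raster and centroid separations always
# exceed the sum of equivalent radii
place_shapes <- function(shapes, width_um, height_um, margin_um, max_tries = 3000L) {
  ord <- order(-vapply(shapes, `[[`, numeric(1), "bound_r"))
  cx <- numeric(0); cy <- numeric(0); br <- numeric(0)
  placed <- integer(0)
  for (k in ord) {
    b <- shapes[[k]]$bound_r
    if (2 * b + 2 > min(width_um, height_um)) next # cannot fit
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      x <- runif(1, b + 1, width_um - b - 1)
      y <- runif(1, b + 1, height_um - b - 1)
      if (!length(cx) ||
          all((cx - x)^2 + (cy - y)^2 > (br + b + margin_um)^2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    cx <- c(cx, x); cy <- c(cy, y); br <- c(br, b)
    placed <- c(placed, k)
  }
  list(index = placed, cx = cx, cy = cy)
}

rasterize_shapes <- function(shapes, cx, cy, width_um, height_um, calib) {
  s <- calib$microns_per_pixel
  nr <- as.integer(round(height_um / s))
  nc <- as.integer(round(width_um / s))
  m <- matrix(0L, nr, nc)
  for (k in seq_along(shapes)) {
    idx <- shape_pixels(shapes[[k]], cx[k], cy[k], nr, nc, s)
    idx <- idx[m[idx] == 0L] # first painter wins
    m[idx] <- k
  }
  label_field(m, calib)
}

#' Generate a synthetic ground-truth vessel field
#'
#' Places non-overlapping parametric vessel profiles by rejection sampling
#' (bounding circles kept disjoint), rasterises them at the given
#' calibration, and measures the resulting instances. Identical seeds give
#' bit-identical label fields. If the field cannot hold the requested count
#' at the drawn sizes, the achieved shortfall is reported in the result;
#' a grossly infeasible request (expected packing area above 60% of the
#' field) is an error.
#'
#' @param spec A [field_spec()].
#' @param calib A [pixel_calibration()]; the desk-scale default of 1 um/px
#'   keeps paper-scale fields within laptop memory.
#' @return List with `field` (a [label_field()]), `instances` (measured
#'   records; id = label), `shapes` (data frame id, type, cx, cy, target
#'   area, bounding radius), `roi_points` (instance centres, um),
#'   `shortfall`, `spec`, `calib`.
#' @export
generate_field <- function(spec, calib = pixel_calibration(1.0)) {
  stopifnot(inherits(spec, "field_spec"), inherits(calib, "pixel_calibration"))
  s <- calib$microns_per_pixel
  with_seed(spec$seed, {
    n <- spec$target_count
    if (n == 0L) {
      fld <- rasterize_shapes(list(), numeric(0), numeric(0),
                              spec$width_um, spec$height_um, calib)
      return(list(field = fld, instances = empty_instances(),
                  shapes = data.frame(), roi_points = matrix(numeric(0), ncol = 2),
                  shortfall = 0L, spec = spec, calib = calib))
    }
    p_min <- plnorm(spec$area_min_um2, spec$area_meanlog, spec$area_sdlog)
    p_large <- plnorm(spec$large_area_um2, spec$area_meanlog, spec$area_sdlog)
    is_large <- runif(n) < spec$large_vessel_rate
    areas <- ifelse(
      is_large,
      qlnorm(runif(n, p_large, 1), spec$area_meanlog, spec$area_sdlog),
      qlnorm(runif(n, p_min, min(p_large, 1)), spec$area_meanlog, spec$area_sdlog)
    )
    types <- sample(names(spec$shape_mix), n, replace = TRUE,
                    prob = spec$shape_mix)
    shapes <- mapply(make_shape, types, areas,
                     MoreArgs = list(px_um = s), SIMPLIFY = FALSE)
    pack_area <- sum(pi * vapply(shapes, `[[`, numeric(1), "bound_r")^2)
    if (pack_area > 0.6 * spec$width_um * spec$height_um) {
      abort_input(sprintf(
        "infeasible density: packing area %.3g um^2 exceeds 60%% of the field",
        pack_area))
    }
    pl <- place_shapes(shapes, spec$width_um, spec$height_um,
                       margin_um = 2 * s)
    shapes <- shapes[pl$index]
    fld <- rasterize_shapes(shapes, pl$cx, pl$cy,
                            spec$width_um, spec$height_um, calib)
    inst <- extract_instances(fld)
    sh_df <- data.frame(
      id = seq_along(shapes),
      type = vapply(shapes, `[[`, character(1), "type"),
      cx_um = pl$cx, cy_um = pl$cy,
      target_area_um2 = vapply(shapes, `[[`, numeric(1), "area"),
      bound_r_um = vapply(shapes, `[[`, numeric(1), "bound_r"),
      stringsAsFactors = FALSE
    )
    # annotation points are the measured instance centroids (not the ideal
    # placement centres): instances on the hull then lie exactly on its
    # boundary, which the membership rule counts as inside
    list(field = fld, instances = inst, shapes = sh_df,
         shape_geom = shapes, shape_cx = pl$cx, shape_cy = pl$cy,
         roi_points = cbind(x_um = inst$centroid_x_um,
                            y_um = inst$centroid_y_um),
         shortfall = spec$target_count - length(shapes),
         spec = spec, calib = calib)
  })
}

# scale a shape's geometry by a linear factor
scale_shape <- function(sh, lin) {
  if (sh$type == "disc") {
    sh$r <- sh$r * lin
  } else if (sh$type == "annulus") {
    sh$r_out <- sh$r_out * lin; sh$r_in <- sh$r_in * lin
  } else {
    sh$path <- sh$path * lin; sh$w <- sh$w * lin
  }
  sh$area <- sh$area * lin^2
  sh$bound_r <- sh$bound_r * lin
  sh
}

# replace a shape by k small discs spaced along its main axis
fragment_shape <- function(sh, cx, cy, k, px_um) {
  if (sh$type == "tube") {
    # arc-length positions along the path
    pts <- sweep(sh$path, 2, c(cx, cy), "+")
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    pos <- seq(0.1, 0.9, length.out = k) * cum[length(cum)]
    ctr <- t(vapply(pos, function(p) {
      i <- max(which(cum <= p)); i <- min(i, length(seg))
      a <- pts[i, ]; b <- pts[i + 1, ]
      frac <- if (seg[i] == 0) 0 else (p - cum[i]) / seg[i]
      a + frac * (b - a)
    }, numeric(2)))
    spacing <- cum[length(cum)] * 0.8 / max(1, k - 1)
  } else {
    r <- sh$bound_r
    phi <- runif(1, 0, pi)
    tpos <- seq(-0.7, 0.7, length.out = k) * r
    ctr <- cbind(cx + tpos * cos(phi), cy + tpos * sin(phi))
    spacing <- 1.4 * r / max(1, k - 1)
  }
  # cap the fragment radius so that every NMS gate (0.7 * min radius) stays
  # below the 2-pixel packing margin: fragments can then never suppress, or
  # be suppressed by, detections of other vessels
  rf <- max(min(0.3 * spacing, sh$bound_r / 5, 2.8 * px_um), 1.2 * px_um)
  lapply(seq_len(k), function(i) {
    list(shape = list(type = "disc", r = rf, area = pi * rf^2, bound_r = rf),
         cx = ctr[i, 1], cy = ctr[i, 2])
  })
}

#' Degrade a synthetic truth into a predicted field with a truth ledger
#'
#' Applies, in order: instance dropout, fragmentation of large vessels into
#' dot-like disc fragments, centroid jitter, multiplicative area noise, and
#' speck injection. Every event is recorded in the ledger so expected
#' TP/FP/FN after post-processing are computable without running the
#' evaluator.
#'
#' @param truth A [generate_field()] result.
#' @param dspec A [degrade_spec()].
#' @return List with `field` (predicted [label_field()]), `instances`
#'   (measured predicted records; id = label), `ledger` (list with `truth`
#'   and `pred` data frames), `dspec`.
#' @export
degrade <- function(truth, dspec) {
  stopifnot(inherits(dspec, "degrade_spec"))
  spec <- truth$spec
  calib <- truth$calib
  s <- calib$microns_per_pixel
  with_seed(dspec$seed, {
    n <- nrow(truth$shapes)
    survived <- if (n) runif(n) >= dspec$fn_rate else logical(0)
    meas_area <- truth$instances$area_um2[match(seq_len(n), truth$instances$id)]
    fragmented <- survived & meas_area > dspec$fragment_min_area_um2 &
      runif(n) < dspec$fragment_prob

    pred_shapes <- list(); pred_cx <- numeric(0); pred_cy <- numeric(0)
    origin <- character(0); parent <- integer(0)
    for (i in seq_len(n)) {
      if (!survived[i]) next
      if (fragmented[i]) {
        k <- sample(seq(dspec$fragment_count_range[1],
                        dspec$fragment_count_range[2]), 1L)
        frs <- fragment_shape(truth$shape_geom[[i]], truth$shape_cx[i],
                              truth$shape_cy[i], k, s)
        for (fr in frs) {
          pred_shapes[[length(pred_shapes) + 1L]] <- fr$shape
          pred_cx <- c(pred_cx, fr$cx); pred_cy <- c(pred_cy, fr$cy)
          origin <- c(origin, "fragment"); parent <- c(parent, i)
        }
      } else {
        sh <- truth$shape_geom[[i]]
        if (dspec$area_noise_cv > 0) {
          f <- max(0.2, 1 + dspec$area_noise_cv * rnorm(1))
          sh <- scale_shape(sh, sqrt(f))
        }
        x <- truth$shape_cx[i]; y <- truth$shape_cy[i]
        if (dspec$centroid_jitter_sd_um > 0) {
          x <- x + rnorm(1, 0, dspec$centroid_jitter_sd_um)
          y <- y + rnorm(1, 0, dspec$centroid_jitter_sd_um)
          x <- min(max(x, sh$bound_r + 1), spec$width_um - sh$bound_r - 1)
          y <- min(max(y, sh$bound_r + 1), spec$height_um - sh$bound_r - 1)
        }
        pred_shapes[[length(pred_shapes) + 1L]] <- sh
        pred_cx <- c(pred_cx, x); pred_cy <- c(pred_cy, y)
        origin <- c(origin, "true"); parent <- c(parent, i)
      }
    }

    n_speck <- rpois(1, dspec$fp_speck_rate * spec$width_um * spec$height_um / 1e4)
    if (n_speck > 0) {
      # specks emulate staining noise inside the tissue: place them inside
      # the convex hull of the annotation points (with a 2-pixel buffer so
      # their measured centroids stay inside too)
      hull <- if (nrow(truth$roi_points) >= 3) convex_hull_roi(truth$roi_points)
              else NULL
      buffered_inside <- function(x, y) {
        if (is.null(hull)) return(TRUE)
        v <- hull$vertices
        if (!points_in_polygon(x, y, hull)) return(FALSE)
        vn <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
        e <- vn - v
        len <- sqrt(rowSums(e^2))
        dist_edge <- abs(e[, 1] * (y - v[, 2]) - e[, 2] * (x - v[, 1])) / len
        all(dist_edge > 2 * s)
      }
      br_all <- vapply(pred_shapes, `[[`, numeric(1), "bound_r")
      for (q in seq_len(n_speck)) {
        a <- runif(1, dspec$fp_speck_area_range[1], dspec$fp_speck_area_range[2])
        r <- sqrt(a / pi)
        for (t in 1:2000) {
          x <- runif(1, r + 1, spec$width_um - r - 1)
          y <- runif(1, r + 1, spec$height_um - r - 1)
          if (!buffered_inside(x, y)) next
          if (!length(pred_cx) ||
              all((pred_cx - x)^2 + (pred_cy - y)^2 > (br_all + r + 2 * s)^2)) {
            pred_shapes[[length(pred_shapes) + 1L]] <-
              list(type = "disc", r = r, area = a, bound_r = r)
            pred_cx <- c(pred_cx, x); pred_cy <- c(pred_cy, y)
            br_all <- c(br_all, r)
            origin <- c(origin, "speck"); parent <- c(parent, NA_integer_)
            break
          }
        }
      }
    }

    fld <- rasterize_shapes(pred_shapes, pred_cx, pred_cy,
                            spec$width_um, spec$height_um, calib)
    inst <- extract_instances(fld)
    ledger <- list(
      truth = data.frame(truth_id = seq_len(n), survived = survived,
                         fragmented = fragmented),
      pred = data.frame(pred_id = seq_along(pred_shapes), origin = origin,
                        truth_id = parent, stringsAsFactors = FALSE)
    )
    list(field = fld, instances = inst, ledger = ledger, dspec = dspec)
  })
}

#' Bundled synthetic evaluation scenarios
#'
#' Deterministic fixtures pairing a truth field with a degraded prediction
#' and, from the construction ledger, the expected TP/FP/FN after the fixed
#' post-processing pipeline. Available scenarios:
#' \describe{
#'   \item{"clean"}{no degradation; end-to-end F1 must be exactly 1.}
#'   \item{"speck-noise"}{planted sub-6-um^2 specks; the minimum-area step
#'     must remove exactly the planted specks.}
#'   \item{"fragmented-large"}{large vessels split into dot-like fragments,
#'     the dominant residual error mode of vessel segmentation.}
#'   \item{"low-prevalence"}{a small region with limited vascular load
#'     (tens of vessels), where count metrics are volatile.}
#' }
#'
#' @param name Scenario name.
#' @param seed Seed applied to both generation and degradation.
#' @param calib Calibration (default 1 um/px desk scale).
#' @return List with `truth`, `pred`, `roi_points`, `ledger`, `expected`
#'   (list tp/fp/fn), `config`, `criteria`.
#' @export
make_scenario <- function(name, seed = 1L, calib = pixel_calibration(1.0)) {
  if (!is.character(name) || length(name) != 1L) {
    abort_input("scenario name must be a single string")
  }
  base <- function(count, width = 1000, large_rate = 0.01) {
    field_spec(width_um = width, height_um = width, target_count = count,
               large_vessel_rate = large_rate, seed = seed)
  }
  cfg <- postprocess_config()
  crit <- match_criteria()
  ds <- switch(
    name,
    "clean" = degrade_spec(seed = seed + 1L),
    "speck-noise" = degrade_spec(fp_speck_rate = 0.15, seed = seed + 1L),
    "fragmented-large" = degrade_spec(fragment_prob = 1, seed = seed + 1L),
    "low-prevalence" = degrade_spec(seed = seed + 1L),
    abort_input(sprintf("unknown scenario '%s'", name))
  )
  fs <- switch(
    name,
    "clean" = base(120),
    "speck-noise" = base(120),
    "fragmented-large" = base(100, large_rate = 0.08),
    "low-prevalence" = base(40)
  )
  truth <- generate_field(fs, calib)
  pred <- degrade(truth, ds)

  # expected outcome after the fixed pipeline, from the construction:
  # intact survivors match exactly; fragments and specks cannot match
  # anything; specks below the area threshold are filtered out.
  led <- pred$ledger
  intact <- led$truth$survived & !led$truth$fragmented
  idx <- match(led$pred$pred_id, pred$instances$id)
  pred_area <- pred$instances$area_um2[idx]
  in_hull <- if (nrow(truth$roi_points) >= 3) {
    hull <- convex_hull_roi(truth$roi_points)
    points_in_polygon(pred$instances$centroid_x_um[idx],
                      pred$instances$centroid_y_um[idx], hull)
  } else rep(TRUE, length(idx))
  surviving_fp <- sum(led$pred$origin != "true" & in_hull &
                        pred_area >= cfg$min_area_um2)
  expected <- list(
    tp = sum(intact),
    fp = surviving_fp,
    fn = sum(!intact),
    planted_specks = sum(led$pred$origin == "speck"),
    specks_below_threshold = sum(led$pred$origin == "speck" &
                                   pred_area < cfg$min_area_um2)
  )
  list(name = name, truth = truth, pred = pred,
       roi_points = truth$roi_points, ledger = led, expected = expected,
       config = cfg, criteria = crit, seed = seed)
}
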