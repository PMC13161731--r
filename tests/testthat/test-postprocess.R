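test_that("convex-hull proxy ROI contains all points and matches a brute-force oracle", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  set.seed(12)
  inner <- cbind(runif(10, 1, 9), runif(10, 1, 9))
  hull <- convex_hull_roi(rbind(sq, inner))
  expect_equal(nrow(hull$vertices), 4)
  expect_setequal(apply(hull$vertices, 1, paste, collapse = ","),
                  apply(sq, 1, paste, collapse = ","))
  tri <- cbind(c(0, 4, 2), c(0, 0, 3))
  expect_setequal(apply(convex_hull_roi(tri)$vertices, 1, paste, collapse = ","),
                  apply(tri, 1, paste, collapse = ","))
  # 200 random points: hull vertex set equals the O(n^3) pairwise oracle
  pts <- cbind(runif(200), runif(200))
  hv <- convex_hull_roi(pts)$vertices
  oracle <- pts[brute_hull_vertices(pts), , drop = FALSE]
  expect_setequal(apply(hv, 1, paste, collapse = ","),
                  apply(oracle, 1, paste, collapse = ","))
  expect_true(all(points_in_polygon(pts[, 1], pts[, 2], convex_hull_roi(pts))))
  # degenerate inputs are errors, not empty ROIs
  expect_error(convex_hull_roi(cbind(c(0, 1), c(0, 1))), class = "vq_input_error")
  expect_error(convex_hull_roi(cbind(0:5, 0:5)), class = "vq_input_error")
})

test_that("ROI restriction keeps boundary centroids and drops outside ones", {
  roi <- roi_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  inst <- disc_instances(x = c(5, 15, 10, 0, 5), y = c(5, 5, 5, 0, 10),
                         area = rep(20, 5))
  kept <- restrict_to_roi(inst, roi)
  # inside, edge and vertex points retained; outside removed
  expect_setequal(kept$id, c(1L, 3L, 4L, 5L))
})

test_that("minimum-area filter is strict below threshold only", {
  inst <- disc_instances(1:3, 1:3, c(3, 6, 7))
  expect_setequal(filter_min_area(inst, 6)$area_um2, c(6, 7))
  expect_equal(nrow(filter_min_area(inst, 1)), 3)
  set.seed(4)
  areas <- c(runif(40, 1, 5.9), runif(60, 6.1, 400))
  inst <- disc_instances(seq_along(areas) * 30, rep(1, 100), areas)
  expect_equal(nrow(filter_min_area(inst, 6)), 60)
  # retained count is non-increasing in the threshold
  counts <- vapply(2:8, function(t) nrow(filter_min_area(inst, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("NMS suppresses the smaller of a close pair and leaves distant pairs", {
  # radii 3 and 2 um, distance 1 um, gate 0.7 * 2 = 1.4 -> suppress smaller
  two <- disc_instances(x = c(0, 1), y = c(0, 0), area = pi * c(9, 4))
  out <- nms_merge(two, 0.7)
  expect_equal(out$id, 1L)
  # same pair at distance 2 um: both retained
  two$centroid_x_um[2] <- 2
  expect_equal(nrow(nms_merge(two, 0.7)), 2)
})

test_that("NMS equals a greedy-order oracle on near-gate chains and is idempotent", {
  greedy_oracle <- function(inst, f) {
    ord <- order(-inst$area_um2, inst$id)
    kept <- integer(0)
    for (i in ord) {
      gate_hit <- FALSE
      for (k in kept) {
        d <- sqrt((inst$centroid_x_um[i] - inst$centroid_x_um[k])^2 +
                  (inst$centroid_y_um[i] - inst$centroid_y_um[k])^2)
        if (d <= f * min(inst$eq_radius_um[i], inst$eq_radius_um[k])) {
          gate_hit <- TRUE
          break
        }
      }
      if (!gate_hit) kept <- c(kept, i)
    }
    sort(inst$id[kept])
  }
  set.seed(77)
  for (rep in 1:40) {
    n <- 5
    inst <- disc_instances(cumsum(runif(n, 0.5, 2.5)), rep(0, n),
                           runif(n, 10, 60))
    out <- nms_merge(inst, 0.7)
    expect_equal(sort(out$id), greedy_oracle(inst, 0.7))
    # idempotence and subset property
    expect_equal(nms_merge(out, 0.7), out)
    expect_true(all(out$id %in% inst$id))
    # post-condition: no two retained within the gate
    if (nrow(out) > 1) {
      d <- as.matrix(dist(out[, c("centroid_x_um", "centroid_y_um")]))
      gate <- outer(out$eq_radius_um, out$eq_radius_um, pmin) * 0.7
      expect_true(all(d[upper.tri(d)] > gate[upper.tri(gate)]))
    }
  }
})

test_that("NMS union mode merges cluster records area-weighted", {
  two <- disc_instances(x = c(0, 1), y = c(0, 0), area = c(30, 10))
  u <- nms_merge(two, 0.9, mode = "union")
  expect_equal(nrow(u), 1)
  expect_equal(u$area_um2, 40)
  expect_equal(u$centroid_x_um, (0 * 30 + 1 * 10) / 40)
  expect_true(is.na(u$perimeter_um))
})

test_that("the fixed pipeline runs ROI -> area -> NMS with exact audit counts", {
  set.seed(21)
  # a clean field on a coarse grid (separations far above any NMS gate):
  # no specks, no duplicates -> audit counts constant
  base <- disc_instances(x = rep(seq(10, 85, by = 15), times = 5)[1:30],
                         y = rep(seq(10, 70, by = 15), each = 6)[1:30],
                         area = runif(30, 10, 80))
  pts <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  clean <- apply_fixed_pipeline(base, pts)
  expect_true(all(clean$audit$retained == 30))
  # plant k specks below 6 um^2 inside the ROI
  k <- 7
  specks <- disc_instances(x = runif(k, 20, 80), y = runif(k, 20, 80),
                           area = runif(k, 1, 5.5), id = 100 + seq_len(k))
  withspecks <- apply_fixed_pipeline(rbind(base, specks), pts)
  expect_equal(withspecks$audit$removed[withspecks$audit$step == "min_area"], k)
  # plant m duplicate partners inside the NMS gate
  m <- 5
  dup <- base[seq_len(m), ]
  dup$id <- 200 + seq_len(m)
  dup$area_um2 <- dup$area_um2 * 0.8
  dup$eq_radius_um <- sqrt(dup$area_um2 / pi)
  dup$centroid_x_um <- dup$centroid_x_um + 0.1 * dup$eq_radius_um
  withdups <- apply_fixed_pipeline(rbind(base, dup), pts)
  expect_equal(withdups$audit$removed[withdups$audit$step == "nms"], m)
  # permissive configuration is the identity
  perm <- apply_fixed_pipeline(base, pts,
                               postprocess_config(min_area_um2 = 1e-9,
                                                  nms_factor = 1e-9))
  expect_equal(perm$instances, base)
  # pipeline is idempotent
  again <- apply_fixed_pipeline(withdups$instances, pts)
  expect_equal(again$instances, withdups$instances)
})
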