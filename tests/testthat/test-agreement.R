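test_that("bias and MAE separate signed and absolute errors", {
  t1 <- count_table(c("a", "b"), c(10, 20), c(10, 20))
  expect_equal(bias_mae(t1)$mean_bias, 0)
  expect_equal(bias_mae(t1)$mae, 0)
  t2 <- count_table(c("a", "b"), c(10, 20), c(8, 18))
  expect_equal(bias_mae(t2)$mean_bias, 2)
  expect_equal(bias_mae(t2)$mae, 2)
  t3 <- count_table(c("a", "b"), c(10, 14), c(12, 10))
  expect_equal(bias_mae(t3)$mean_bias, 1)
  expect_equal(bias_mae(t3)$mae, 3)
  expect_error(bias_mae(count_table(character(0), numeric(0), numeric(0))),
               class = "vq_input_error")
  # MAE >= |mean bias| on random tables; equality iff one sign
  set.seed(10)
  for (i in 1:30) {
    tab <- count_table(1:6, rpois(6, 50), rpois(6, 50))
    bm <- bias_mae(tab)
    expect_gte(bm$mae, abs(bm$mean_bias) - 1e-12)
    d <- tab$pred_count - tab$gt_count
    if (all(d >= 0) || all(d <= 0)) {
      expect_equal(bm$mae, abs(bm$mean_bias))
    }
  }
})

test_that("ICC(3,1) is the two-way consistency coefficient", {
  # identical columns with row variance -> 1 (EMS = 0)
  expect_equal(icc_3_1(cbind(c(1, 5, 9), c(1, 5, 9))), 1)
  # constant rater offset is ignored by the consistency form
  expect_equal(icc_3_1(cbind(c(1, 5, 9), c(3, 7, 11))), 1)
  # explicit mean-squares oracle, computed from scratch
  m <- cbind(c(10, 20, 30, 40), c(12, 19, 33, 38))
  n <- 4; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - grand)^2) - k * sum((rowMeans(m) - grand)^2) -
            n * sum((colMeans(m) - grand)^2)) / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(icc_3_1(m), oracle, tolerance = 1e-12)
  expect_equal(icc_3_1(count_table(1:4, m[, 1], m[, 2])), oracle,
               tolerance = 1e-12)
  # zero between-row variance -> undefined
  expect_true(is.na(icc_3_1(cbind(c(5, 5, 5), c(5, 5, 5)))))
  # invariances: shift either column, common positive rescaling
  expect_equal(icc_3_1(m + cbind(rep(7, 4), rep(0, 4))), oracle, tolerance = 1e-12)
  expect_equal(icc_3_1(m * 3.5), oracle, tolerance = 1e-12)
  expect_error(icc_3_1(matrix(1, 1, 2)), class = "vq_input_error")
})

test_that("Bland-Altman limits are symmetric with the n-1 SD estimator", {
  tab <- count_table(1:3, c(15, 25, 35), c(10, 20, 30))
  ba <- bland_altman(tab)
  expect_equal(ba$mean_diff, 5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(unname(ba$loa), c(5, 5))
  # antisymmetric differences
  tab <- count_table(1:2, c(10, 30), c(14, 26))
  ba <- bland_altman(tab)
  expect_equal(ba$mean_diff, 0)
  expect_equal(unname(ba$loa), c(-1.96, 1.96) * sd(c(-4, 4)))
  expect_error(bland_altman(count_table("a", 5, 5)), class = "vq_input_error")
  # exact identities: loa = mean +/- 1.96 sd, width 3.92 sd
  set.seed(3)
  for (i in 1:20) {
    tab <- count_table(1:5, rpois(5, 100), rpois(5, 100))
    ba <- bland_altman(tab)
    expect_equal(unname(ba$loa[1]), ba$mean_diff - 1.96 * ba$sd_diff, tolerance = 1e-9)
    expect_equal(unname(ba$loa[2]), ba$mean_diff + 1.96 * ba$sd_diff, tolerance = 1e-9)
    expect_equal(unname(diff(ba$loa)), 3.92 * ba$sd_diff, tolerance = 1e-9)
  }
})

test_that("proportional-bias regression recovers planted slopes", {
  # constant difference: both slopes 0
  tab <- count_table(1:6, c(105, 205, 305, 405, 505, 605),
                     c(100, 200, 300, 400, 500, 600),
                     roi_area_um2 = c(3, 1, 4, 1, 5, 9) * 1e6)
  pb <- proportional_bias(tab)
  expect_equal(pb$separate$slope[pb$separate$term == "mean_count"], 0,
               tolerance = 1e-9)
  # noise-free linear relation diff = 0.5 * mean recovered exactly:
  # diff = 0.5 * mean implies pred = 1.25 * mean, gt = 0.75 * mean
  mean_c <- c(100, 200, 300, 400)
  tab <- count_table(1:4, 1.25 * mean_c, 0.75 * mean_c,
                     roi_area_um2 = rep(2e6, 4))
  pb <- proportional_bias(tab)
  expect_equal(pb$separate$slope[pb$separate$term == "mean_count"], 0.5,
               tolerance = 1e-9)
  # planted slope 0.2 with noise SD 1: estimate within 3 standard errors
  set.seed(42)
  n <- 50
  gt <- round(runif(n, 50, 500))
  noise <- rnorm(n, 0, 1)
  # construct pred so that diff = 0.2 * mean + noise
  pred <- (gt * 1.1 + noise) / 0.9
  tab <- count_table(seq_len(n), pred, gt, roi_area_um2 = runif(n, 1e6, 9e6))
  fit <- lm(I(tab$pred_count - tab$gt_count) ~
              I((tab$pred_count + tab$gt_count) / 2))
  se <- summary(fit)$coefficients[2, 2]
  pb <- proportional_bias(tab)
  est <- pb$separate$slope[pb$separate$term == "mean_count"]
  expect_lt(abs(est - 0.2), 3 * se)
  # with 3 ROIs the joint fit has 0 residual df: p undefined, not a number
  t3 <- count_table(1:3, c(110, 220, 330), c(100, 200, 300),
                    roi_area_um2 = c(1e6, 3.7e6, 2.2e6))
  pbj <- proportional_bias(t3)$joint
  expect_true(all(is.na(pbj$p)))
})

test_that("agreement reports bundle all outcomes and serialise to JSON", {
  tab <- count_table(c("L01", "L02", "L03"), c(1800, 1600, 500),
                     c(1698, 1511, 447),
                     roi_area_um2 = c(12.65, 8.96, 3.48) * 1e6)
  rep <- agreement_report(tab)
  expect_equal(rep$ba_loa_low, rep$ba_mean_diff - 1.96 * rep$ba_sd, tolerance = 1e-9)
  expect_equal(rep$ba_loa_high, rep$ba_mean_diff + 1.96 * rep$ba_sd, tolerance = 1e-9)
  expect_gte(rep$mae, abs(rep$mean_bias))
  expect_equal(rep$percent$denominator, "gt_mean")
  p <- withr::local_tempfile(fileext = ".json")
  write_agreement_json(rep, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$mean_bias, rep$mean_bias)
  expect_equal(back$icc_3_1, rep$icc_3_1, tolerance = 1e-12)
  # pred == gt -> bias 0, ICC 1
  same <- agreement_report(count_table(1:3, c(5, 50, 500), c(5, 50, 500)))
  expect_equal(same$mean_bias, 0)
  expect_equal(same$icc_3_1, 1)
})
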