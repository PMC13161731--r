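#' ROI-level count tables
#'
#' Count agreement is assessed at the ROI level: one row per region with the
#' predicted and reference (ground-truth) vessel counts and the ROI area.
#'
#' @param roi_id Region identifiers.
#' @param pred_count,gt_count Non-negative integer counts.
#' @param roi_area_um2 ROI areas in um^2.
#' @return A validated data frame.
#' @export
count_table <- function(roi_id, pred_count, gt_count, roi_area_um2 = NA_real_) {
  out <- data.frame(roi_id = as.character(roi_id),
                    pred_count = as.numeric(pred_count),
                    gt_count = as.numeric(gt_count),
                    roi_area_um2 = rep_len(as.numeric(roi_area_um2), length(roi_id)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$roi_id)) abort_input("one row per ROI is required")
  if (any(out$pred_count < 0) || any(out$gt_count < 0)) {
    abort_input("counts must be non-negative")
  }
  out
}

#' Count bias and mean absolute error
#'
#' Per-ROI bias is `pred - gt`; the mean bias averages signed differences and
#' MAE averages their absolute values, so `MAE >= |mean bias|` always, with
#' equality iff all differences share a sign.
#'
#' @param table A [count_table()].
#' @return List with `per_roi` (roi_id, bias), `mean_bias`, `mae`.
#' @export
bias_mae <- function(table) {
  if (!nrow(table)) abort_input("count table is empty")
  bias <- table$pred_count - table$gt_count
  list(per_roi = data.frame(roi_id = table$roi_id, bias = bias),
       mean_bias = mean(bias), mae = mean(abs(bias)))
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency intraclass correlation
#' (Shrout-Fleiss ICC(3,1)): `(MSR - MSE) / (MSR + (k - 1) MSE)` from the
#' two-way ANOVA decomposition with k = 2 fixed raters (prediction and
#' reference). Consistency means a constant rater offset does not lower the
#' coefficient. Returns `NA` when the between-ROI variance is zero (the
#' coefficient is undefined, not 0).
#'
#' @param table A [count_table()], or an n x k numeric matrix of ratings.
#' @return The coefficient in (-1, 1], or `NA` when undefined.
#' @export
icc_3_1 <- function(table) {
  m <- if (is.data.frame(table)) cbind(table$pred_count, table$gt_count)
       else as.matrix(table)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) abort_input("ICC needs >= 2 rows and >= 2 raters")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 && mse <= 0) return(NA_real_) # no variance anywhere
  if (msr + (k - 1) * mse == 0) return(NA_real_)
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Bland-Altman limits of agreement helper
#'
#' Symmetric limits `mean_diff +/- 1.96 * sd_diff`. The multiplier 1.96 is
#' used literally (not a t quantile).
#'
#' @param mean_diff Mean of paired differences.
#' @param sd_diff Sample standard deviation of the differences.
#' @return Numeric `c(low, high)`.
#' @export
loa_limits <- function(mean_diff, sd_diff) {
  c(low = mean_diff - 1.96 * sd_diff, high = mean_diff + 1.96 * sd_diff)
}

#' Bland-Altman analysis of paired counts
#'
#' Differences are `pred - gt`; the SD uses the n-1 sample estimator and the
#' limits of agreement are `mean +/- 1.96 SD`.
#'
#' @param table A [count_table()] with >= 2 rows.
#' @return List with `mean_diff`, `sd_diff`, `loa` (`c(low, high)`),
#'   `mean_count` and `diff` vectors, and `n`.
#' @export
bland_altman <- function(table) {
  if (nrow(table) < 2L) abort_input("Bland-Altman needs >= 2 ROIs")
  d <- table$pred_count - table$gt_count
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = md, sd_diff = s, loa = loa_limits(md, s),
       mean_count = (table$pred_count + table$gt_count) / 2, diff = d,
       n = nrow(table))
}

#' Proportional-bias regression
#'
#' Ordinary least squares of the difference (pred - gt) on the mean count
#' `(pred + gt) / 2`, adjusting for ROI area; two-sided t-test p-value per
#' slope, significance flagged at p < 0.05. Both the joint fit (mean count
#' and area together) and the two single-covariate fits are returned: with
#' very few ROIs the joint fit has no residual degrees of freedom and its
#' p-values are undefined (`NA`), while the separate fits may still be
#' estimable.
#'
#' @param table A [count_table()]; area is required for the area term.
#' @return List with data frames `joint` and `separate`, each with columns
#'   term, slope, p, significant.
#' @export
proportional_bias <- function(table) {
  d <- table$pred_count - table$gt_count
  mc <- (table$pred_count + table$gt_count) / 2
  area <- table$roi_area_um2
  tidy_fit <- function(fit, terms) {
    sm <- suppressWarnings(summary(fit)$coefficients)
    out <- data.frame(term = terms, slope = NA_real_, p = NA_real_)
    for (i in seq_along(terms)) {
      rn <- terms[i]
      if (rn %in% rownames(sm)) {
        out$slope[i] <- sm[rn, 1]
        pv <- sm[rn, 4]
        out$p[i] <- if (is.nan(pv)) NA_real_ else pv
      } else {
        # coefficient dropped (collinear) or df exhausted
        cf <- coef(fit)
        if (rn %in% names(cf)) out$slope[i] <- cf[[rn]]
      }
    }
    out$significant <- !is.na(out$p) & out$p < 0.05
    out
  }
  have_area <- all(is.finite(area))
  joint <- if (have_area) {
    tidy_fit(lm(d ~ mc + area), c("mc", "area"))
  } else {
    tidy_fit(lm(d ~ mc), "mc")
  }
  sep <- rbind(
    tidy_fit(lm(d ~ mc), "mc"),
    if (have_area) tidy_fit(lm(d ~ area), "area")
  )
  rename <- function(x) {
    x$term[x$term == "mc"] <- "mean_count"
    x$term[x$term == "area"] <- "roi_area_um2"
    x
  }
  list(joint = rename(joint), separate = rename(sep))
}

#' Full ROI-level count-agreement report
#'
#' Bundles bias/MAE, ICC(3,1), Bland-Altman limits and the proportional-bias
#' regressions. Percent bias is reported relative to a configurable
#' denominator (mean reference count by default), and the convention used is
#' labelled in the output.
#'
#' @param table A [count_table()].
#' @param percent_denominator `"gt_mean"` (default) or `"pooled_mean"`.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(table,
                             percent_denominator = c("gt_mean", "pooled_mean")) {
  percent_denominator <- match.arg(percent_denominator)
  bm <- bias_mae(table)
  ba <- if (nrow(table) >= 2L) bland_altman(table) else NULL
  icc <- if (nrow(table) >= 2L) icc_3_1(table) else NA_real_
  pb <- proportional_bias(table)
  den <- switch(percent_denominator,
                gt_mean = mean(table$gt_count),
                pooled_mean = mean(c(table$gt_count, table$pred_count)))
  pct <- function(v) if (is.null(v) || den == 0) NULL else 100 * v / den
  structure(list(
    n_roi = nrow(table),
    per_roi_bias = bm$per_roi,
    mean_bias = bm$mean_bias,
    mae = bm$mae,
    icc_3_1 = icc,
    icc_definition = "two-way mixed, single measure, consistency (Shrout-Fleiss 3,1)",
    ba_mean_diff = if (is.null(ba)) NA_real_ else ba$mean_diff,
    ba_sd = if (is.null(ba)) NA_real_ else ba$sd_diff,
    ba_loa_low = if (is.null(ba)) NA_real_ else unname(ba$loa[1]),
    ba_loa_high = if (is.null(ba)) NA_real_ else unname(ba$loa[2]),
    percent = list(
      denominator = percent_denominator,
      mean_bias_pct = pct(bm$mean_bias),
      loa_low_pct = if (is.null(ba)) NULL else pct(unname(ba$loa[1])),
      loa_high_pct = if (is.null(ba)) NULL else pct(unname(ba$loa[2]))
    ),
    proportional_bias = pb
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d ROI(s)\n", x$n_roi))
  cat(sprintf("  mean bias %.3f (MAE %.3f), ICC(3,1) %s\n", x$mean_bias, x$mae,
              ifelse(is.na(x$icc_3_1), "undefined", sprintf("%.4f", x$icc_3_1))))
  cat(sprintf("  Bland-Altman %.3f [%.3f, %.3f]\n",
              x$ba_mean_diff, x$ba_loa_low, x$ba_loa_high))
  invisible(x)
}

#' @rdname agreement_report
#' @param report An `agreement_report`.
#' @param path Output JSON path.
#' @export
write_agreement_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname count_table
#' @param path CSV with columns roi_id, pred_count, gt_count, roi_area_um2.
#' @export
read_count_table_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "pred_count", "gt_count")
  if (!all(need %in% names(x))) {
    abort_input("counts CSV needs columns roi_id, pred_count, gt_count")
  }
  if (is.null(x$roi_area_um2)) x$roi_area_um2 <- NA_real_
  count_table(x$roi_id, x$pred_count, x$gt_count, x$roi_area_um2)
}
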