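#' Matching criteria for one-to-one instance assignment
#'
#' Two admissibility modes are supported. In `"geometric"` mode a predicted
#' instance p and a reference instance g may be paired iff both gates hold
#' strictly: centroid distance `d(p, g) < alpha * min(r_p, r_g)` and relative
#' area difference `|A_p - A_g| / A_g < tau`. In `"circle_iou"` mode the pair
#' is admissible iff the IoU of their equivalent circles reaches
#' `iou_threshold` (comparator configurable, default `>=`). `alpha = 1`
#' follows the normative centroid gate `d < min(r_p, r_g)`; the stricter
#' `alpha = 0.5` variant is covered by the sensitivity sweep.
#'
#' @param alpha Positive centroid-gate multiplier (default 1).
#' @param tau Positive maximum relative area difference (default 0.30).
#' @param mode `"geometric"` or `"circle_iou"`.
#' @param iou_threshold Equivalent-circle IoU threshold (default 0.50).
#' @param iou_comparator `">="` (default) or `">"`.
#' @return A `match_criteria` list.
#' @export
match_criteria <- function(alpha = 1.0, tau = 0.30,
                           mode = c("geometric", "circle_iou"),
                           iou_threshold = 0.50,
                           iou_comparator = c(">=", ">")) {
  mode <- match.arg(mode)
  iou_comparator <- match.arg(iou_comparator)
  if (!is.numeric(alpha) || alpha <= 0) abort_input("alpha must be positive")
  if (!is.numeric(tau) || tau <= 0) abort_input("tau must be positive")
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1) {
    abort_input("iou_threshold must lie in (0, 1]")
  }
  structure(list(alpha = as.numeric(alpha), tau = as.numeric(tau), mode = mode,
                 iou_threshold = as.numeric(iou_threshold),
                 iou_comparator = iou_comparator),
            class = "match_criteria")
}

#' Pairwise admissibility gate
#'
#' @param p,g Single-row instance records (predicted, reference).
#' @param criteria A [match_criteria()].
#' @return Logical: may the pair be matched?
#' @export
gate_pair <- function(p, g, criteria = match_criteria()) {
  gm <- gate_matrix(validate_instances(p), validate_instances(g), criteria)
  as.vector(gm$admissible)
}

# vectorised gates for all pred x ref pairs; returns distance and flags
gate_matrix <- function(preds, refs, criteria) {
  np <- nrow(preds); ng <- nrow(refs)
  if (np == 0L || ng == 0L) {
    z <- matrix(numeric(0), np, ng)
    return(list(distance = z, rel_area = z,
                admissible = matrix(logical(0), np, ng)))
  }
  dx <- outer(preds$centroid_x_um, refs$centroid_x_um, "-")
  dy <- outer(preds$centroid_y_um, refs$centroid_y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  if (ng && any(refs$area_um2 == 0)) abort_input("reference area must be positive")
  rel <- abs(outer(preds$area_um2, refs$area_um2, "-")) /
    matrix(refs$area_um2, np, ng, byrow = TRUE)
  if (criteria$mode == "geometric") {
    rmin <- outer(preds$eq_radius_um, refs$eq_radius_um, pmin)
    adm <- (d < criteria$alpha * rmin) & (rel < criteria$tau)
  } else {
    iou <- matrix(circle_iou(rep(preds$eq_radius_um, times = ng),
                             rep(refs$eq_radius_um, each = np),
                             as.vector(d)), np, ng)
    adm <- if (criteria$iou_comparator == ">=") iou >= criteria$iou_threshold
           else iou > criteria$iou_threshold
  }
  list(distance = d, rel_area = rel, admissible = adm)
}

#' Gated cost table for assignment
#'
#' Admissible cells carry the centroid distance as cost; inadmissible cells
#' are flagged forbidden. The assignment method itself needs no other
#' dissimilarity: the gates define feasibility, distance breaks the
#' remaining freedom.
#'
#' @param preds,refs Instance tables.
#' @param criteria A [match_criteria()].
#' @return List with matrices `cost` (um) and `forbidden` (logical), rows =
#'   predictions, columns = references.
#' @export
build_cost_matrix <- function(preds, refs, criteria = match_criteria()) {
  preds <- validate_instances(preds); refs <- validate_instances(refs)
  gm <- gate_matrix(preds, refs, criteria)
  list(cost = gm$distance, forbidden = !gm$admissible,
       rel_area = gm$rel_area,
       pred_ids = preds$id, ref_ids = refs$id)
}

# Shortest-augmenting-path solver for the square linear assignment problem
# (Jonker-Volgenant style with potentials, O(n^3)); inner loops vectorised.
# C must be finite. Returns row assigned to each column.
lap_square <- function(C) {
  n <- nrow(C)
  if (n == 0L) return(integer(0))
  VIRT <- n + 1L # virtual column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j]: row currently assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[VIRT] <- i
    j0 <- VIRT
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    way <- integer(n)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- C[i0, ] - u[i0] - v[seq_len(n)]
      upd <- !used[seq_len(n)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free <- which(!used[seq_len(n)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[usedj] <- v[usedj] - delta
      minv[!used[seq_len(n)]] <- minv[!used[seq_len(n)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == VIRT) break
    }
  }
  p[seq_len(n)]
}

#' Optimal one-to-one assignment over a gated cost table
#'
#' Among one-to-one assignments that never use a forbidden cell, returns one
#' of maximal cardinality; among those, total cost is minimal. Implemented by
#' padding to a square matrix in which every forbidden or padding cell costs
#' a sentinel strictly larger than the sum of all admissible costs, solving
#' the square problem exactly, then discarding sentinel pairs. The solver is
#' deterministic, so cost ties are broken reproducibly.
#'
#' @param table A list as returned by [build_cost_matrix()], or a numeric
#'   cost matrix (with optional logical `forbidden` matrix).
#' @param forbidden Optional logical matrix when `table` is a plain matrix.
#' @return Integer matrix with columns `row`, `col` (indices of matched
#'   pairs); zero rows when nothing can be matched.
#' @export
hungarian_assign <- function(table, forbidden = NULL) {
  if (is.list(table) && !is.data.frame(table)) {
    cost <- table$cost
    forbidden <- table$forbidden
  } else {
    cost <- as.matrix(table)
    if (is.null(forbidden)) forbidden <- !is.finite(cost)
  }
  np <- nrow(cost); ng <- ncol(cost)
  if (np == 0L || ng == 0L || all(forbidden)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  fin <- cost[!forbidden]
  big <- sum(fin) + max(fin, 1) + 1
  n <- max(np, ng)
  C <- matrix(big, n, n)
  C[seq_len(np), seq_len(ng)] <- ifelse(forbidden, big, cost)
  rows_of_col <- lap_square(C)
  pairs <- cbind(row = rows_of_col, col = seq_len(n))
  keep <- pairs[, 1] <= np & pairs[, 2] <= ng
  pairs <- pairs[keep, , drop = FALSE]
  ok <- !forbidden[pairs]
  pairs <- pairs[ok, , drop = FALSE]
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Match predicted against reference instances
#'
#' One-to-one assignment of predictions to references by the Hungarian
#' method over the gated cost table. Matched pairs are true positives;
#' unmatched predictions are false positives; unmatched references are false
#' negatives.
#'
#' @param preds,refs Instance tables sharing a calibration.
#' @param criteria A [match_criteria()].
#' @return An object of class `match_result`: list with `pairs` (data frame
#'   pred_id, ref_id, distance_um, rel_area_diff), `false_positives`,
#'   `false_negatives` (id vectors) and `criteria`.
#' @export
match_instances <- function(preds, refs, criteria = match_criteria()) {
  preds <- validate_instances(preds); refs <- validate_instances(refs)
  tab <- build_cost_matrix(preds, refs, criteria)
  pairs <- hungarian_assign(tab)
  pdf <- data.frame(
    pred_id = tab$pred_ids[pairs[, 1]],
    ref_id = tab$ref_ids[pairs[, 2]],
    distance_um = tab$cost[pairs],
    rel_area_diff = tab$rel_area[pairs]
  )
  structure(list(
    pairs = pdf,
    false_positives = setdiff(preds$id, pdf$pred_id),
    false_negatives = setdiff(refs$id, pdf$ref_id),
    criteria = criteria
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d | FP %d | FN %d (%s mode)\n",
              nrow(x$pairs), length(x$false_positives),
              length(x$false_negatives), x$criteria$mode))
  invisible(x)
}

#' Write a match result to CSV
#'
#' One row per pair plus rows for unmatched instances (status FP/FN with the
#' missing partner empty). The criteria are written to a JSON sidecar
#' `<path>.criteria.json`.
#'
#' @param m A `match_result`.
#' @param path Output CSV path.
#' @export
write_matches_csv <- function(m, path) {
  stopifnot(inherits(m, "match_result"))
  tp <- if (nrow(m$pairs)) cbind(m$pairs, status = "TP") else NULL
  fp <- if (length(m$false_positives)) {
    data.frame(pred_id = m$false_positives, ref_id = NA_integer_,
               distance_um = NA_real_, rel_area_diff = NA_real_, status = "FP")
  } else NULL
  fn <- if (length(m$false_negatives)) {
    data.frame(pred_id = NA_integer_, ref_id = m$false_negatives,
               distance_um = NA_real_, rel_area_diff = NA_real_, status = "FN")
  } else NULL
  out <- rbind(tp, fp, fn)
  if (is.null(out)) {
    out <- data.frame(pred_id = integer(0), ref_id = integer(0),
                      distance_um = numeric(0), rel_area_diff = numeric(0),
                      status = character(0))
  }
  write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(unclass(m$criteria), paste0(path, ".criteria.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
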