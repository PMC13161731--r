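# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own algorithms.

# all permutations of 1..n (n <= 7)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}

# exhaustive assignment oracle: maximal cardinality of admissible pairs,
# then minimal total cost, by enumerating all permutations of the padded
# square problem
brute_force_assignment <- function(cost, forbidden) {
  np <- nrow(cost); ng <- ncol(cost)
  n <- max(np, ng)
  P <- perms(n)
  best_card <- -1L
  best_cost <- Inf
  for (r in seq_len(nrow(P))) {
    p <- P[r, ]
    card <- 0L
    tot <- 0
    for (i in seq_len(np)) {
      j <- p[i]
      if (j <= ng && !forbidden[i, j]) {
        card <- card + 1L
        tot <- tot + cost[i, j]
      }
    }
    if (card > best_card || (card == best_card && tot < best_cost)) {
      best_card <- card
      best_cost <- tot
    }
  }
  list(cardinality = max(best_card, 0L),
       total_cost = if (best_card > 0) best_cost else 0)
}

# Monte-Carlo point-sampling estimate of the IoU of two discs (centres on
# the x axis at 0 and d), sampling the bounding box of the union
mc_circle_iou <- function(r1, r2, d, n = 1e6) {
  x0 <- min(-r1, d - r2); x1 <- max(r1, d + r2)
  y1 <- max(r1, r2)
  x <- runif(n, x0, x1)
  y <- runif(n, -y1, y1)
  in1 <- x^2 + y^2 <= r1^2
  in2 <- (x - d)^2 + y^2 <= r2^2
  u <- sum(in1 | in2)
  if (u == 0) return(0)
  sum(in1 & in2) / u
}

# pure-R flood-fill labelling oracle (queue-based BFS)
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        a <- cur[1] + offs[k, 1]; b <- cur[2] + offs[k, 2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- nxt
          queue <- rbind(queue, c(a, b))
        }
      }
    }
  }
  lab
}

# O(n^3) convex-hull oracle: a directed pair (i, j) is a hull edge iff all
# other points lie on its left (or on the segment); returns hull vertex set
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    if (all(cr >= -1e-12)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  which(on_hull)
}

# quick instance-table fixture: discs at given centres/areas
disc_instances <- function(x, y, area, id = seq_along(x)) {
  instance_records(id = id, centroid_x_um = x, centroid_y_um = y,
                   area_um2 = area)
}

# random gated instance sets for matching property tests
random_instance_pair <- function(np, ng, extent = 40) {
  preds <- disc_instances(runif(np, 0, extent), runif(np, 0, extent),
                          runif(np, 5, 120))
  refs <- disc_instances(runif(ng, 0, extent), runif(ng, 0, extent),
                         runif(ng, 5, 120))
  list(preds = preds, refs = refs)
}
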