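# Independent reference implementations used as oracles. These deliberately
# use brute-force formulations (explicit loops, no shared code with the
# package internals).

# convex hull area by gift wrapping + shoelace
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (length(hull) == 1) setdiff(seq_len(n), p) else seq_len(n)[-p]
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[best, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
        (pts[best, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      d_best <- sum((pts[best, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_q > d_best)) best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  xs <- pts[hull, 1]; ys <- pts[hull, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# two-group split by removing the largest edge of the Euclidean minimum
# spanning tree (Prim's algorithm, hand-rolled)
oracle_split_two <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  stopifnot(n >= 2)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, 0, 2)
  wts <- numeric(0)
  while (!all(in_tree)) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
    }
    edges <- rbind(edges, c(bi, bj))
    wts <- c(wts, best)
    in_tree[bj] <- TRUE
  }
  cut <- which.max(wts)
  keep <- edges[-cut, , drop = FALSE]
  # connected components of the remaining forest
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(keep))) {
      a <- comp[keep[k, 1]]; b <- comp[keep[k, 2]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  grp <- match(comp, unique(comp))
  list(a = which(grp == 1), b = which(grp == 2), gap = max(wts))
}

# covariance eigenvalues from the closed-form quadratic (independent of
# eigen())
oracle_linearity <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sxx <- sum((pts[, 1] - mx)^2) / (n - 1)
  syy <- sum((pts[, 2] - my)^2) / (n - 1)
  sxy <- sum((pts[, 1] - mx) * (pts[, 2] - my)) / (n - 1)
  tr <- sxx + syy
  disc <- sqrt(max((sxx - syy)^2 + 4 * sxy^2, 0))
  l1 <- (tr + disc) / 2
  l1 / tr
}

# Literal transcription of the printed iterative cleaning rules, coded
# directly from the procedure: (1) pairwise distances of segment start
# points; (2)+(3) single-linkage two-group split (via the MST oracle);
# (4) compare the between-group gap to the proximity maximum; (5) keep the
# anchor group, examine the other; (6) discard the examined group if it has
# too few points or is far too distant, test linearity otherwise; repeat
# until stable; days incorporated one at a time.
oracle_clean <- function(segments, p) {
  reason <- rep(NA_character_, nrow(segments))
  days <- sort(unique(segments$time_h))
  retained <- integer(0)
  for (d in days) {
    active <- c(retained, which(segments$time_h == d))
    active <- active[is.na(reason[active])]
    accepted <- integer(0)
    repeat {
      if (length(active) < 2) break
      pts <- cbind(segments$x_start[active], segments$y_start[active])
      s <- oracle_split_two(pts)
      if (s$gap <= p$proximity_max) break
      da <- min(abs(pts[s$a, 1] - p$center_x))
      db <- min(abs(pts[s$b, 1] - p$center_x))
      nearer_a <- da <= db
      anch <- if (p$anchor == "nearer") {
        if (nearer_a) s$a else s$b
      } else {
        if (nearer_a) s$b else s$a
      }
      oth <- setdiff(c(s$a, s$b), anch)
      lin <- if (length(oth) >= 3) {
        q <- pts[oth, , drop = FALSE]
        if (sum((q[, 1] - mean(q[, 1]))^2 + (q[, 2] - mean(q[, 2]))^2) == 0)
          0.5 else oracle_linearity(q)
      } else 0.5
      if (length(oth) < p$min_cluster_size) {
        reason[active[oth]] <- "too_few"
      } else if (s$gap > p$hard_max_factor * p$proximity_max) {
        reason[active[oth]] <- "too_far"
      } else if (lin < p$linearity_threshold) {
        reason[active[oth]] <- "nonlinear"
      } else {
        accepted <- c(accepted, active[oth])
      }
      active <- active[anch]
    }
    retained <- sort(unique(c(active, accepted)))
  }
  reason
}

# quick builders ------------------------------------------------------------

# segments data.frame from explicit start points (for cleaning tests)
seg_df <- function(x, y, time_h = 24) {
  data.frame(segment_id = seq_along(x), x_start = x, y_start = y,
             x_end = x, y_end = y + 5, gravity_angle = 0,
             length = 5, chord_len = 5, time_h = time_h)
}

# draw 1-px-wide polylines into a logical mask (0-based coords)
draw_mask <- function(nr, nc, segs) {
  m <- matrix(0, nr, nc)
  m <- rhizotrack:::.cpp_draw_segments(m, cbind(segs, 1), 0, FALSE)
  m > 0
}

# small noiseless growth/render defaults used across tests
small_growth <- function(...) {
  args <- utils::modifyList(
    list(rhizotron_width = 4, rhizotron_height = 8,
         primary_elongation_rate = 1, lateral_elongation_rate = 0.5,
         lateral_initiation_rate = 0.8, n_days = 6, rng_seed = 42),
    list(...))
  do.call(growth_params, args)
}

noiseless_render <- function(...) {
  args <- utils::modifyList(
    list(pixel_size = 0.02, occlusion_gap_rate = 0,
         speckle_density = 0, background_level = 0),
    list(...))
  do.call(render_params, args)
}
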