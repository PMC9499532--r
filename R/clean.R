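#' Format raw segments into gravity-referenced directed vectors
#'
#' Reproduces the formatting step that turns the raw measurement output into
#' an in-silico vector root system: folds the raw 0-180 degree orientation
#' to the 0-90 gravity angle (`theta_raw` if `<= 90`, else
#' `180 - theta_raw`), reconstructs the segment endpoints trigonometrically
#' from the bounding-box anchor, chord length, raw angle and lateral sign
#' (`dx = sign * L * sin(theta)`, `dy = L * cos(theta)`; the start point is
#' the bounding-box corner matched to the chord direction), and attaches
#' plant metadata from the key. If the raw table carries an
#' `acquisition_date`, imaging times are recomputed as hours since the
#' plant's `experiment_start_date`.
#'
#' @param raw data.frame of raw segments (see [extract_segments()]) with a
#'   `plant_id` column.
#' @param key plant metadata: `plant_id`, `genotype`, `replicate`, and
#'   optionally `experiment_start_date`.
#' @return data.frame of vector segments: raw columns plus `x_start`,
#'   `y_start`, `x_end`, `y_end`, `gravity_angle`, `genotype`, `replicate`.
#' @export
format_segments <- function(raw, key) {
  stopifnot(is.data.frame(raw), is.data.frame(key))
  if (nrow(raw) == 0) {
    out <- raw
    out$x_start <- out$y_start <- out$x_end <- out$y_end <- numeric(0)
    out$gravity_angle <- numeric(0)
    return(out)
  }
  if (!"plant_id" %in% names(raw)) raw$plant_id <- key$plant_id[1]
  missing_ids <- setdiff(unique(raw$plant_id), key$plant_id)
  if (length(missing_ids) > 0)
    stop("plant_id missing from key: ", paste(missing_ids, collapse = ", "))
  i <- match(raw$plant_id, key$plant_id)
  out <- raw
  out$genotype <- key$genotype[i]
  out$replicate <- key$replicate[i]
  if ("acquisition_date" %in% names(raw) &&
      "experiment_start_date" %in% names(key)) {
    out$time_h <- as.numeric(difftime(as.POSIXct(raw$acquisition_date),
                                      as.POSIXct(key$experiment_start_date[i]),
                                      units = "hours"))
  }
  out$gravity_angle <- gravity_angle_of(out$theta_raw)
  L <- if ("chord_len" %in% names(out)) out$chord_len else out$length
  sign <- if ("lateral_sign" %in% names(out)) out$lateral_sign else 1
  rad <- out$theta_raw * pi / 180
  dx <- sign * L * sin(rad)
  dy <- L * cos(rad)
  out$x_start <- ifelse(dx >= 0, out$bbox_x, out$bbox_x - dx)
  out$y_start <- ifelse(dy >= 0, out$bbox_y, out$bbox_y - dy)
  out$x_end <- out$x_start + dx
  out$y_end <- out$y_start + dy
  out
}

#' Split a point set into two groups by single-linkage clustering
#'
#' Single-linkage hierarchical clustering of the pairwise Euclidean
#' distances, tree cut into exactly two groups; equivalently, removal of the
#' largest edge of the Euclidean minimum spanning tree. The reported gap is
#' the single-linkage distance between the two groups (the height of the
#' final merge).
#'
#' @param points two-column matrix of `(x, y)` coordinates, `>= 2` rows.
#' @return list with integer index vectors `a` and `b` and the numeric
#'   `gap` between them.
#' @export
split_two <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points to split")
  if (n == 2) {
    return(list(a = 1L, b = 2L,
                gap = sqrt(sum((points[1, ] - points[2, ])^2))))
  }
  if (n <= 2000) {
    hc <- hclust(dist(points), method = "single")
    grp <- cutree(hc, k = 2)
    return(list(a = which(grp == 1), b = which(grp == 2),
                gap = hc$height[n - 1]))
  }
  # large point sets: the equivalent minimum-spanning-tree formulation
  # (cut the largest MST edge) runs in O(n) memory where the full distance
  # matrix would not fit
  split_two_mst(points)
}

# Prim's algorithm with O(n) memory; returns the same 2-cut as
# single-linkage clustering cut into two groups.
split_two_mst <- function(points) {
  n <- nrow(points)
  x <- points[, 1]; y <- points[, 2]
  mind <- rep(Inf, n)
  minfrom <- integer(n)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  d1 <- sqrt((x - x[1])^2 + (y - y[1])^2)
  upd <- d1 < mind
  mind[upd] <- d1[upd]; minfrom[upd] <- 1L
  mind[1] <- Inf
  edge_a <- integer(n - 1); edge_b <- integer(n - 1); edge_w <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    j <- which.min(mind)
    edge_a[k] <- minfrom[j]; edge_b[k] <- j; edge_w[k] <- mind[j]
    in_tree[j] <- TRUE
    mind[j] <- Inf
    dj <- sqrt((x - x[j])^2 + (y - y[j])^2)
    upd <- !in_tree & dj < mind
    mind[upd] <- dj[upd]; minfrom[upd] <- j
  }
  cut <- which.max(edge_w)
  # component containing edge_b[cut] after removing the cut edge
  adj_from <- c(edge_a[-cut], edge_b[-cut])
  adj_to <- c(edge_b[-cut], edge_a[-cut])
  ord <- order(adj_from)
  adj_from <- adj_from[ord]; adj_to <- adj_to[ord]
  starts <- c(1L, which(diff(adj_from) > 0) + 1L)
  node_start <- integer(n); node_end <- integer(n)
  node_start[adj_from[starts]] <- starts
  node_end[adj_from[starts]] <- c(starts[-1] - 1L, length(adj_from))
  in_b <- logical(n)
  queue <- edge_b[cut]
  in_b[queue] <- TRUE
  while (length(queue) > 0) {
    v <- queue[length(queue)]
    queue <- queue[-length(queue)]
    if (node_start[v] > 0) {
      nb <- adj_to[node_start[v]:node_end[v]]
      nb <- nb[!in_b[nb]]
      if (length(nb) > 0) {
        in_b[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  list(a = which(!in_b), b = which(in_b), gap = edge_w[cut])
}

#' Linearity of a point cluster
#'
#' Fraction of the scatter carried by the principal axis:
#' `lambda1 / (lambda1 + lambda2)` of the 2x2 covariance matrix of the
#' points. 1 for perfectly collinear points, 0.5 for isotropic clouds.
#'
#' @param points two-column matrix, at least 3 non-identical points.
#' @return score in `[0.5, 1]`.
#' @export
linearity_score <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  cv <- cov(points)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  tot <- sum(ev)
  if (tot <= 0) stop("degenerate input: zero scatter")
  max(ev) / tot
}

#' Cleaning parameters
#'
#' @param proximity_max maximum single-linkage gap (px) between clusters
#'   still considered one root system.
#' @param hard_max_factor a cluster separated by more than
#'   `hard_max_factor * proximity_max` (nearly twice the proximity maximum
#'   by default) is discarded outright.
#' @param min_cluster_size clusters with fewer points are discarded as
#'   likely noise (default 4).
#' @param linearity_threshold minimum [linearity_score()] for a distant
#'   cluster to be accepted as a root segment group.
#' @param center_x x of the sowing position (px); used to pick the anchor
#'   group.
#' @param anchor `"nearer"` keeps the group whose minimum `|x - center_x|`
#'   is smaller (the sowing position is at top-center); `"farther"` keeps
#'   the farther group instead.
#' @return a `clean_params` list.
#' @export
clean_params <- function(proximity_max = 100, hard_max_factor = 2,
                         min_cluster_size = 4, linearity_threshold = 0.85,
                         center_x = 750, anchor = c("nearer", "farther")) {
  stopifnot(proximity_max > 0, min_cluster_size >= 1)
  structure(list(proximity_max = proximity_max,
                 hard_max_factor = hard_max_factor,
                 min_cluster_size = as.integer(min_cluster_size),
                 linearity_threshold = linearity_threshold,
                 center_x = center_x,
                 anchor = match.arg(anchor)),
            class = "clean_params")
}

#' Remove non-root particles by iterative distance clustering
#'
#' The day-by-day cleaning of the vectorized root system, operating on
#' segment start points. The first imaging day is processed alone; each
#' subsequent day's segments are added to the retained set and the process
#' begins again. Within a pass the current point set is repeatedly split in
#' two by single-linkage clustering ([split_two()]): if the gap between the
#' groups is at most `proximity_max` everything left is kept and the pass
#' ends; otherwise the anchor group (by default the one nearer `center_x`,
#' where the seed was sown) is carried forward and the other group is
#' resolved - discarded as `too_few` if it has fewer than
#' `min_cluster_size` points, as `too_far` if the gap exceeds
#' `hard_max_factor * proximity_max`, as `nonlinear` if its
#' [linearity_score()] falls below `linearity_threshold`, and kept as a
#' plausible distant root group otherwise. Every decision is logged.
#'
#' @param segments data.frame of vector segments (needs `x_start`,
#'   `y_start`, `time_h`).
#' @param p a [clean_params()] object.
#' @return a `clean_result`: list with `true_root` and `removed`
#'   data.frames (`removed` gains a `removal_reason` column; together they
#'   partition the input) and a `decision_log` data.frame.
#' @export
clean_iterative <- function(segments, p = clean_params()) {
  stopifnot(inherits(p, "clean_params"))
  reason <- rep(NA_character_, nrow(segments))
  log_rows <- list()
  if (nrow(segments) > 0) {
    days <- sort(unique(segments$time_h))
    retained <- integer(0)
    for (d in days) {
      active <- c(retained, which(segments$time_h == d & is.na(reason)))
      active <- setdiff(active, which(!is.na(reason)))
      kept_final <- integer(0)
      step <- 0L
      while (length(active) >= 2) {
        pts <- cbind(segments$x_start[active], segments$y_start[active])
        s <- split_two(pts)
        step <- step + 1L
        if (s$gap <= p$proximity_max) {
          log_rows[[length(log_rows) + 1]] <- data.frame(
            time_h = d, step = step, n_a = length(s$a), n_b = length(s$b),
            gap = s$gap, action = "keep_all", reason = "gap <= proximity_max")
          break
        }
        da <- min(abs(pts[s$a, 1] - p$center_x))
        db <- min(abs(pts[s$b, 1] - p$center_x))
        nearer_is_a <- da <= db
        anchor_is_a <- if (p$anchor == "nearer") nearer_is_a else !nearer_is_a
        anchor <- if (anchor_is_a) s$a else s$b
        other <- if (anchor_is_a) s$b else s$a
        other_idx <- active[other]
        # degenerate clusters (< 3 points or zero scatter) cannot be scored
        # for linearity; they are treated as isotropic (score 0.5)
        lin <- function(q) {
          if (nrow(q) < 3) return(0.5)
          tryCatch(linearity_score(q), error = function(e) 0.5)
        }
        verdict <- if (length(other) < p$min_cluster_size) {
          "too_few"
        } else if (s$gap > p$hard_max_factor * p$proximity_max) {
          "too_far"
        } else if (lin(pts[other, , drop = FALSE]) <
                     p$linearity_threshold) {
          "nonlinear"
        } else {
          "keep"
        }
        log_rows[[length(log_rows) + 1]] <- data.frame(
          time_h = d, step = step, n_a = length(anchor), n_b = length(other),
          gap = s$gap,
          action = if (verdict == "keep") "keep_cluster" else "remove_cluster",
          reason = verdict)
        if (verdict == "keep") {
          kept_final <- c(kept_final, other_idx)
        } else {
          reason[other_idx] <- verdict
        }
        active <- active[anchor]
      }
      retained <- sort(unique(c(active, kept_final)))
    }
  }
  removed <- which(!is.na(reason))
  kept <- which(is.na(reason))
  res <- list(
    true_root = segments[kept, , drop = FALSE],
    removed = {
      r <- segments[removed, , drop = FALSE]
      r$removal_reason <- reason[removed]
      r
    },
    decision_log = if (length(log_rows))
      do.call(rbind, log_rows)
    else data.frame(time_h = numeric(0), step = integer(0),
                    n_a = integer(0), n_b = integer(0), gap = numeric(0),
                    action = character(0), reason = character(0)))
  class(res) <- "clean_result"
  res
}

#' @export
print.clean_result <- function(x, ...) {
  cat(sprintf("<clean_result: %d kept, %d removed (%s)>\n",
              nrow(x$true_root), nrow(x$removed),
              if (nrow(x$removed)) paste(names(table(x$removed$removal_reason)),
                                         table(x$removed$removal_reason),
                                         sep = ":", collapse = ", ")
              else "none"))
  invisible(x)
}
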