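#' Skeletonize a binary mask
#'
#' 8-connected morphological thinning (Zhang-Suen) to a one-pixel-wide
#' centreline; line endpoints are preserved.
#'
#' @param mask logical (or 0/1) matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  # pad with a zero border: the thinning kernel skips border pixels
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  t <- .cpp_thin(p)
  t[2:(nrow(m) + 1), 2:(ncol(m) + 1)] == 1L
}

#' Orientation of a chord in the 0-180 degree root convention
#'
#' Angle between the downward vertical (+y, the gravity direction) and the
#' chord from `p_start` to `p_end`: 0 = straight down, 90 = horizontal,
#' 180 = straight up. Chords with a negative x-component are first reflected
#' to point rightward (the chord is reversed), so down-right chords give
#' (0, 90) and up-right chords give (90, 180).
#'
#' @param p_start,p_end numeric `(x, y)` pairs, or two-column matrices of
#'   equal size.
#' @return orientation(s) in degrees, in `[0, 180]`.
#' @export
chord_orientation <- function(p_start, p_end) {
  p_start <- matrix(p_start, ncol = 2)
  p_end <- matrix(p_end, ncol = 2)
  dx <- p_end[, 1] - p_start[, 1]
  dy <- p_end[, 2] - p_start[, 2]
  if (any(dx == 0 & dy == 0)) stop("identical points have no orientation")
  flip <- dx < 0
  dx[flip] <- -dx[flip]
  dy[flip] <- -dy[flip]
  atan2(dx, dy) * 180 / pi
}

# fold a raw 0-180 orientation to the 0-90 gravity angle
gravity_angle_of <- function(theta_raw) {
  ifelse(theta_raw <= 90, theta_raw, 180 - theta_raw)
}

# Re-extend skeleton endpoints to the mask boundary. Morphological thinning
# retracts free line ends by about half the line width, which systematically
# shortens tips (and so depth/width/length). Each skeleton endpoint is
# continued along its local direction, pixel by pixel, while the mask stays
# foreground.
extend_skeleton_tips <- function(skel, mask, max_extend = 10L,
                                 tail_px = 4L) {
  fg <- which(skel)
  if (length(fg) == 0) return(skel)
  nr <- nrow(skel)
  neighbours <- function(y, x) {
    ys <- y + .nbr_off[, "dy"]; xs <- x + .nbr_off[, "dx"]
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= ncol(skel)
    cbind(ys[ok], xs[ok])
  }
  deg_of <- function(y, x) {
    nb <- neighbours(y, x)
    sum(skel[nb])
  }
  ends <- fg[vapply(fg, function(i) {
    y <- (i - 1L) %% nr + 1L; x <- (i - 1L) %/% nr + 1L
    deg_of(y, x) == 1L
  }, logical(1))]
  for (i in ends) {
    y <- (i - 1L) %% nr + 1L; x <- (i - 1L) %/% nr + 1L
    # walk back along the skeleton to estimate the tip direction
    py <- y; px <- x; cy <- y; cx <- x
    for (k in seq_len(tail_px)) {
      nb <- neighbours(cy, cx)
      nb <- nb[skel[nb] & !(nb[, 1] == py & nb[, 2] == px), , drop = FALSE]
      if (nrow(nb) != 1) break
      py <- cy; px <- cx
      cy <- nb[1, 1]; cx <- nb[1, 2]
    }
    d <- c(y - cy, x - cx)
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) next
    d <- d / nrm
    # greedy walk through the mask: step to the forward neighbour best
    # aligned with the tip direction until the mask ends
    wy <- y; wx <- x
    for (k in seq_len(max_extend)) {
      nb <- neighbours(wy, wx)
      ok <- mask[nb] & !skel[nb]
      if (!any(ok)) break
      nb <- nb[ok, , drop = FALSE]
      dots <- (nb[, 1] - wy) * d[1] + (nb[, 2] - wx) * d[2]
      if (max(dots) <= 0) break
      best <- which.max(dots)
      wy <- nb[best, 1]; wx <- nb[best, 2]
      skel[wy, wx] <- TRUE
    }
  }
  skel
}

# 8-neighbour offsets, axial first then diagonal, row-major within each
# (deterministic walk order)
.nbr_off <- cbind(dy = c(-1, 0, 0, 1, -1, -1, 1, 1),
                  dx = c(0, -1, 1, 0, -1, 1, -1, 1))

# circular 8-neighbour order (N, NE, E, SE, S, SW, W, NW) for the crossing
# number; a skeleton pixel is a true junction when the number of distinct
# skeleton arms entering its neighbourhood (0->1 transitions around the
# circle) is >= 3. Raw neighbour counts misclassify diagonal staircase
# pixels of a thin skeleton as branches; the crossing number does not.
.nbr_circ <- cbind(dy = c(-1, -1, 0, 1, 1, 1, 0, -1),
                   dx = c(0, 1, 1, 1, 0, -1, -1, -1))

# Decompose a skeleton into pixel paths: walks start at line endpoints
# (crossing number 1) in row-major order, then at any unvisited pixel; a
# walk stops on entering a junction (crossing number >= 3) or when no
# unvisited neighbour remains. Every skeleton pixel belongs to exactly one
# path.
skeleton_paths <- function(skel) {
  which_fg <- which(skel)
  n <- length(which_fg)
  if (n == 0) return(list())
  nr <- nrow(skel)
  yy <- (which_fg - 1L) %% nr          # 0-based row (y)
  xx <- (which_fg - 1L) %/% nr         # 0-based col (x)
  id <- matrix(0L, nr, ncol(skel))
  id[which_fg] <- seq_len(n)
  # neighbour ids in circular order
  nbrs <- matrix(0L, n, 8)
  for (k in 1:8) {
    y2 <- yy + .nbr_circ[k, "dy"]; x2 <- xx + .nbr_circ[k, "dx"]
    ok <- y2 >= 0 & y2 < nr & x2 >= 0 & x2 < ncol(skel)
    v <- integer(n)
    v[ok] <- id[cbind(y2[ok] + 1L, x2[ok] + 1L)]
    nbrs[, k] <- v
  }
  present <- nbrs > 0
  crossings <- integer(n)
  for (k in 1:8) {
    k2 <- if (k == 8) 1L else k + 1L
    crossings <- crossings + as.integer(!present[, k] & present[, k2])
  }
  deg <- rowSums(present)
  visited <- logical(n)
  ord <- order(yy, xx)                  # row-major
  starts <- c(ord[crossings[ord] == 1], ord[crossings[ord] != 1])
  paths <- vector("list", 0)
  for (s in starts) {
    if (visited[s]) next
    path <- integer(512)
    path[1] <- s
    np <- 1L
    visited[s] <- TRUE
    cur <- s
    repeat {
      if (crossings[cur] >= 3 && np > 1) break  # stop at a junction
      nx <- nbrs[cur, ]
      nx <- nx[nx > 0]
      nx <- nx[!visited[nx]]
      if (length(nx) == 0) break
      cur <- nx[1]
      visited[cur] <- TRUE
      np <- np + 1L
      if (np > length(path)) path <- c(path, integer(length(path)))
      path[np] <- cur
    }
    paths[[length(paths) + 1]] <- path[seq_len(np)]
  }
  lapply(paths, function(pth) cbind(x = xx[pth], y = yy[pth]))
}

#' Extract oriented root segments from a binary mask
#'
#' Re-implements the measurement core of the luminescence root image
#' analyzer: each connected piece of detected root becomes one or more
#' "root segments" described by the upper-left corner of their bounding
#' box, their skeleton arc length, and their chord orientation in the
#' 0-180 degree convention. The mask is skeletonized, the skeleton is split
#' at branch points, and the resulting arcs are cut into runs of at most
#' `max_segment_len` so each emitted segment is locally near-straight.
#' Arc length counts 1 per axial and `sqrt(2)` per diagonal pixel step.
#' Components whose skeleton has fewer than `min_skeleton_px` pixels are
#' dropped.
#'
#' @param mask logical (or 0/1) matrix; must be binary.
#' @param time_h acquisition time stamped on the segments.
#' @param max_segment_len maximum arc length of one segment, px.
#' @param min_skeleton_px minimum skeleton size of a component, px.
#' @return data.frame with columns `segment_id`, `bbox_x`, `bbox_y`
#'   (0-based upper-left corner), `length` (arc px), `theta_raw` (degrees,
#'   0-180), `time_h`, plus `chord_len` and `lateral_sign` (+1 if the
#'   traced chord points rightward, -1 leftward) used by the vectorization
#'   stage. Attribute `"pixels"` holds the per-segment skeleton pixel
#'   coordinates; every skeleton pixel of an emitted arc belongs to exactly
#'   one segment.
#' @export
extract_segments <- function(mask, time_h = NA_real_, max_segment_len = 40,
                             min_skeleton_px = 3) {
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary")
  empty <- data.frame(segment_id = integer(0), bbox_x = integer(0),
                      bbox_y = integer(0), length = numeric(0),
                      theta_raw = numeric(0), time_h = numeric(0),
                      chord_len = numeric(0), lateral_sign = integer(0))
  if (!any(mask != 0)) return(empty)
  skel <- skeletonize(mask)
  skel <- extend_skeleton_tips(skel, mask != 0)
  # drop tiny components before decomposition
  lab <- label_components(skel)
  sizes <- tabulate(lab[lab > 0])
  skel <- skel & matrix(sizes[pmax(lab, 1)] >= min_skeleton_px,
                        nrow(lab), ncol(lab)) & (lab > 0)
  if (!any(skel)) return(empty)
  paths <- skeleton_paths(skel)
  acc <- list(bbox_x = list(), bbox_y = list(), length = list(),
              theta_raw = list(), chord_len = list(), lateral_sign = list())
  members <- list()  # per-segment pixel membership (disjoint partition)
  for (pth in paths) {
    np <- nrow(pth)
    if (np < 2) next
    step <- sqrt(rowSums((pth[-1, , drop = FALSE] -
                            pth[-np, , drop = FALSE])^2))
    cum <- c(0, cumsum(step))
    # greedy split into runs of arc length <= max_segment_len; consecutive
    # runs share their boundary pixel geometrically (no arc length is lost)
    # but each pixel is a member of exactly one run (partition)
    cut0 <- 0
    bounds <- integer(0)
    for (i in seq_len(np)) {
      if (cum[i] - cut0 > max_segment_len + 1e-9) {
        bounds <- c(bounds, i - 1L)
        cut0 <- cum[i - 1L]
      }
    }
    lo_g <- c(1L, bounds)           # geometric start (shared pixel)
    lo_m <- c(1L, bounds + 1L)      # membership start (disjoint)
    hi <- c(bounds, np)
    for (r in seq_along(lo_g)) {
      i0 <- lo_g[r]; i1 <- hi[r]
      if (i1 - i0 < 1) next
      run <- pth[i0:i1, , drop = FALSE]
      p1 <- run[1, ]; p2 <- run[nrow(run), ]
      dxy <- p2 - p1
      if (all(dxy == 0)) next
      k <- length(acc$bbox_x) + 1L
      acc$bbox_x[[k]] <- min(run[, "x"])
      acc$bbox_y[[k]] <- min(run[, "y"])
      acc$length[[k]] <- cum[i1] - cum[i0]
      acc$theta_raw[[k]] <- chord_orientation(p1, p2)
      acc$chord_len[[k]] <- sqrt(sum(dxy^2))
      acc$lateral_sign[[k]] <- if (dxy[["x"]] < 0) -1L else 1L
      members[[k]] <- pth[lo_m[r]:i1, , drop = FALSE]
    }
  }
  if (length(acc$bbox_x) == 0) return(empty)
  out <- data.frame(segment_id = seq_along(acc$bbox_x),
                    bbox_x = unlist(acc$bbox_x),
                    bbox_y = unlist(acc$bbox_y),
                    length = unlist(acc$length),
                    theta_raw = unlist(acc$theta_raw),
                    time_h = time_h,
                    chord_len = unlist(acc$chord_len),
                    lateral_sign = unlist(acc$lateral_sign))
  attr(out, "pixels") <- members
  out
}
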