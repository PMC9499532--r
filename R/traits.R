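#' Length-weighted average gravity angle
#'
#' Vector segments are weighted by their length, so small segments
#' contribute less to the trait than long ones:
#' `sum(length_i * angle_i) / sum(length_i)`.
#'
#' @param angles gravity angles, degrees in `[0, 90]`.
#' @param lengths segment lengths (same length as `angles`).
#' @return weighted mean angle, degrees.
#' @export
weighted_average_angle <- function(angles, lengths) {
  if (length(angles) == 0) stop("no segments")
  stopifnot(length(angles) == length(lengths), all(lengths >= 0))
  sum(lengths * angles) / sum(lengths)
}

#' Area of the convex hull of a point set
#'
#' Smallest convex polygon containing all points, summarizing the soil area
#' explored by the root system; 0 for fewer than 3 distinct points or
#' collinear input.
#'
#' @param points two-column matrix of `(x, y)` coordinates.
#' @return hull area (px^2 for pixel coordinates).
#' @export
convex_hull_area <- function(points) {
  points <- as.matrix(points)
  points <- points[complete.cases(points), , drop = FALSE]
  if (nrow(points) < 3) return(0)
  h <- grDevices::chull(points)
  if (length(h) < 3) return(0)
  xs <- points[h, 1]; ys <- points[h, 2]
  # shoelace
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

vector_lengths <- function(segments) {
  sqrt((segments$x_end - segments$x_start)^2 +
         (segments$y_end - segments$y_start)^2)
}

#' Whole-root-system traits at one time point
#'
#' The seven whole-system traits over all segment endpoints: `width`
#' (`max x - min x`), `depth` (`max y - min y`; gravity is +y), center of
#' mass (length-weighted mean of segment midpoints), convex hull area,
#' depth-to-width ratio (`NA` when width is 0, never infinity), total
#' length (sum of vector lengths - an underestimate of true root length,
#' since gaps between disconnected segments are not counted), and
#' length-weighted average gravity angle.
#'
#' @param segments data.frame of vector segments at one `time_h` (needs
#'   `x_start`, `y_start`, `x_end`, `y_end`, `gravity_angle`).
#' @return one-row data.frame of the seven traits.
#' @export
whole_system_traits <- function(segments) {
  if (nrow(segments) == 0) stop("no segments")
  xs <- c(segments$x_start, segments$x_end)
  ys <- c(segments$y_start, segments$y_end)
  len <- vector_lengths(segments)
  width <- max(xs) - min(xs)
  depth <- max(ys) - min(ys)
  w <- if (sum(len) > 0) len / sum(len) else rep(1 / nrow(segments),
                                                 nrow(segments))
  data.frame(
    width = width,
    depth = depth,
    center_of_mass_x = sum(w * (segments$x_start + segments$x_end) / 2),
    center_of_mass_y = sum(w * (segments$y_start + segments$y_end) / 2),
    convexhull_area = convex_hull_area(cbind(xs, ys)),
    depth_width_ratio = if (width > 0) depth / width else NA_real_,
    total_length = sum(len),
    average_angle = weighted_average_angle(segments$gravity_angle, len))
}

#' New-growth traits between consecutive imaging days
#'
#' Count, per-day length, and length-weighted average gravity angle of the
#' segments derived from one tip-tracking (new growth) mask. Lengths are
#' normalized to a 24-hour day via the actual time gap.
#'
#' @param new_segments data.frame of vector segments of the new growth.
#' @param delta_t_h time gap to the previous imaging day, hours.
#' @return one-row data.frame: `n_new_segments`, `length_per_day`,
#'   `average_angle_per_day` (`NA` when there is no new growth).
#' @export
new_growth_traits <- function(new_segments, delta_t_h = 24) {
  if (nrow(new_segments) == 0) {
    return(data.frame(n_new_segments = 0L, length_per_day = 0,
                      average_angle_per_day = NA_real_))
  }
  len <- vector_lengths(new_segments)
  data.frame(
    n_new_segments = nrow(new_segments),
    length_per_day = sum(len) * 24 / delta_t_h,
    average_angle_per_day = weighted_average_angle(new_segments$gravity_angle,
                                                   len))
}

#' Trait table for one plant across all time points
#'
#' Combines [whole_system_traits()] on the cleaned cumulative vectors at
#' each time point with [new_growth_traits()] on the per-day new-growth
#' vectors into one row per time point (the `TraitRecord` schema). On the
#' first imaging day all segments count as new growth.
#'
#' @param true_root cleaned cumulative vector segments (all time points).
#' @param new_by_time named list of new-growth vector segment data.frames,
#'   names = `time_h`; may be `NULL`, in which case new-growth traits are
#'   `NA`.
#' @param plant_id,genotype,replicate metadata stamped on the rows.
#' @return data.frame, one row per time point.
#' @export
trait_records <- function(true_root, new_by_time = NULL,
                          plant_id = "plant", genotype = NA_character_,
                          replicate = NA_character_) {
  times <- sort(unique(true_root$time_h))
  rows <- lapply(seq_along(times), function(i) {
    t <- times[i]
    segs <- true_root[true_root$time_h == t, , drop = FALSE]
    whole <- whole_system_traits(segs)
    dt <- if (i == 1) 24 else times[i] - times[i - 1]
    ng <- if (!is.null(new_by_time) && as.character(t) %in% names(new_by_time))
      new_growth_traits(new_by_time[[as.character(t)]], dt)
    else data.frame(n_new_segments = NA_integer_, length_per_day = NA_real_,
                    average_angle_per_day = NA_real_)
    cbind(data.frame(plant_id = plant_id, genotype = genotype,
                     replicate = replicate, time_h = t),
          whole, ng)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
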