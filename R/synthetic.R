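#' Growth parameters for the synthetic rhizotron simulator
#'
#' Defines the stochastic growth model used to generate ground-truth root
#' systems: a primary root descends from the sowing position under gravity,
#' and first-order laterals initiate along it as a Poisson process, each
#' holding a gravity set-point angle that may drift with initiation day.
#' Lengths are in centimetres, rates per day, angles in degrees from the
#' downward vertical (0 = straight down, 90 = horizontal).
#'
#' @param primary_elongation_rate primary root elongation, cm/day.
#' @param lateral_elongation_rate lateral root elongation, cm/day.
#' @param lateral_initiation_rate expected laterals initiated per day per cm
#'   of branching-competent parent length.
#' @param lateral_gravity_setpoint gravity set-point angle of new laterals,
#'   degrees from vertical, in `[0, 90]`.
#' @param setpoint_drift change of the set-point for laterals born on later
#'   days, degrees/day (laterals born on day `d` aim at
#'   `setpoint + drift * (d - 1)`, clamped to `[0, 90]`).
#' @param tortuosity_sd per-step heading noise, degrees.
#' @param rhizotron_width,rhizotron_height rhizotron extent, cm.
#' @param seed_position x of the sowing position at the top edge, cm;
#'   defaults to top-center.
#' @param n_days number of simulated days (>= 1).
#' @param rng_seed integer seed; the whole simulation is deterministic in it.
#' @param step_length spatial resolution of deposited polyline points, cm.
#' @param apical_zone length behind the primary tip where no laterals
#'   initiate, cm.
#' @param gravitropic_gain per-step proportional correction of the heading
#'   toward the set-point, in `[0, 1]`.
#' @return a `growth_params` list.
#' @export
growth_params <- function(primary_elongation_rate = 1.5,
                          lateral_elongation_rate = 0.7,
                          lateral_initiation_rate = 0.5,
                          lateral_gravity_setpoint = 60,
                          setpoint_drift = 0,
                          tortuosity_sd = 2,
                          rhizotron_width = 15,
                          rhizotron_height = 30,
                          seed_position = rhizotron_width / 2,
                          n_days = 28,
                          rng_seed = 1,
                          step_length = 0.05,
                          apical_zone = 1,
                          gravitropic_gain = 0.2) {
  p <- list(primary_elongation_rate = primary_elongation_rate,
            lateral_elongation_rate = lateral_elongation_rate,
            lateral_initiation_rate = lateral_initiation_rate,
            lateral_gravity_setpoint = lateral_gravity_setpoint,
            setpoint_drift = setpoint_drift,
            tortuosity_sd = tortuosity_sd,
            rhizotron_width = rhizotron_width,
            rhizotron_height = rhizotron_height,
            seed_position = seed_position,
            n_days = as.integer(n_days),
            rng_seed = as.integer(rng_seed),
            step_length = step_length,
            apical_zone = apical_zone,
            gravitropic_gain = gravitropic_gain)
  if (p$n_days <= 0) stop("n_days must be a positive integer")
  rates <- c(primary_elongation_rate, lateral_elongation_rate,
             lateral_initiation_rate, tortuosity_sd)
  if (any(rates < 0)) stop("rates and noise levels must be >= 0")
  if (lateral_gravity_setpoint < 0 || lateral_gravity_setpoint > 90)
    stop("lateral_gravity_setpoint must lie in [0, 90]")
  if (rhizotron_width <= 0 || rhizotron_height <= 0 || step_length <= 0)
    stop("geometry parameters must be positive")
  class(p) <- "growth_params"
  p
}

# Heading convention: signed degrees from the downward vertical; positive
# headings lean toward +x. A root advances step_length along its heading
# each step and relaxes toward its (signed) set-point.
step_heading <- function(heading, setpoint, gain, sd) {
  heading + gain * (setpoint - heading) + (if (sd > 0) rnorm(1, 0, sd) else 0)
}

#' Simulate a ground-truth root system
#'
#' Grows one root system day by day inside the rhizotron rectangle. The
#' primary root starts at the sowing position heading straight down; laterals
#' initiate behind the primary tip (Poisson along the branching-competent
#' length) at the gravity set-point angle, on a random side, drifting by
#' `setpoint_drift` per birth day. Every deposited polyline point is stamped
#' with its deposition day, so the system at any earlier day is the prefix of
#' the final one (monotone growth). Roots that reach the rhizotron boundary
#' are clipped there and stop. Fully deterministic in `rng_seed`.
#'
#' @param params a [growth_params()] object.
#' @return a `ground_truth_root`: list with `points` (data.frame `root_id`,
#'   `parent_id`, `birth_day`, `point_index`, `x`, `y`, `deposit_day`, in cm)
#'   and `params`.
#' @export
simulate_root_growth <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  p <- params
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(p$rng_seed)

  W <- p$rhizotron_width; H <- p$rhizotron_height
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

  # each root: list(id, parent, birth, setpoint (signed), heading,
  #               x, y, day (per point), active, rate)
  primary <- list(id = 1L, parent = NA_integer_, birth = 1L,
                  setpoint = 0, heading = 0,
                  x = p$seed_position, y = 0, day = 1L,
                  active = TRUE, rate = p$primary_elongation_rate)
  roots <- list(primary)
  next_id <- 2L

  grow_root <- function(r, day) {
    if (!r$active) return(r)
    n_steps <- max(0L, as.integer(round(r$rate / p$step_length)))
    if (n_steps == 0L) return(r)
    n <- length(r$x)
    x <- r$x[n]; y <- r$y[n]; h <- r$heading
    nx <- numeric(0); ny <- numeric(0)
    for (s in seq_len(n_steps)) {
      h <- step_heading(h, r$setpoint, p$gravitropic_gain, p$tortuosity_sd)
      rad <- h * pi / 180
      x1 <- x + p$step_length * sin(rad)
      y1 <- y + p$step_length * cos(rad)
      hit <- x1 < 0 || x1 > W || y1 < 0 || y1 > H
      x1 <- clamp(x1, 0, W); y1 <- clamp(y1, 0, H)
      nx <- c(nx, x1); ny <- c(ny, y1)
      x <- x1; y <- y1
      if (hit) { r$active <- FALSE; break }
    }
    r$x <- c(r$x, nx); r$y <- c(r$y, ny)
    r$day <- c(r$day, rep(as.integer(day), length(nx)))
    r$heading <- h
    r
  }

  arc_pos <- function(r) {
    # cumulative arc length at each polyline point
    n <- length(r$x)
    if (n == 1) return(0)
    c(0, cumsum(sqrt(diff(r$x)^2 + diff(r$y)^2)))
  }

  for (day in seq_len(p$n_days)) {
    # 1. extend the primary
    roots[[1]] <- grow_root(roots[[1]], day)
    # 2. initiate laterals on the primary, behind the apical zone
    pr <- roots[[1]]
    s <- arc_pos(pr)
    competent <- max(0, s[length(s)] - p$apical_zone)
    if (p$lateral_initiation_rate > 0 && competent > 0) {
      n_new <- rpois(1, p$lateral_initiation_rate * competent)
      if (n_new > 0) {
        pos <- sort(runif(n_new, 0, competent))
        side <- ifelse(runif(n_new) < 0.5, -1, 1)
        sp <- clamp(p$lateral_gravity_setpoint +
                      p$setpoint_drift * (day - 1), 0, 90)
        for (k in seq_len(n_new)) {
          i <- findInterval(pos[k], s)
          # interpolate the birth point on the parent polyline
          if (i >= length(s)) {
            bx <- pr$x[length(s)]; by <- pr$y[length(s)]
          } else {
            f <- (pos[k] - s[i]) / max(s[i + 1] - s[i], 1e-12)
            bx <- pr$x[i] + f * (pr$x[i + 1] - pr$x[i])
            by <- pr$y[i] + f * (pr$y[i + 1] - pr$y[i])
          }
          roots[[length(roots) + 1]] <-
            list(id = next_id, parent = 1L, birth = as.integer(day),
                 setpoint = side[k] * sp, heading = side[k] * sp,
                 x = bx, y = by, day = as.integer(day),
                 active = TRUE, rate = p$lateral_elongation_rate)
          next_id <- next_id + 1L
        }
      }
    }
    # 3. extend existing laterals (including those born today)
    if (length(roots) > 1) {
      for (ri in 2:length(roots)) roots[[ri]] <- grow_root(roots[[ri]], day)
    }
  }

  pts <- do.call(rbind, lapply(roots, function(r) {
    data.frame(root_id = r$id, parent_id = r$parent, birth_day = r$birth,
               point_index = seq_along(r$x) - 1L,
               x = r$x, y = r$y, deposit_day = r$day)
  }))
  structure(list(points = pts, params = p), class = "ground_truth_root")
}

#' @export
print.ground_truth_root <- function(x, ...) {
  cat(sprintf("<ground_truth_root: %d roots, %d points, %d days>\n",
              length(unique(x$points$root_id)), nrow(x$points),
              x$params$n_days))
  invisible(x)
}

# polyline steps (consecutive point pairs within a root) visible at `day`,
# in pixel units; columns x0,y0,x1,y1,deposit_day (of the later point)
root_steps <- function(root, day, pixel_size) {
  pts <- root$points[root$points$deposit_day <= day, , drop = FALSE]
  out <- lapply(split(pts, pts$root_id), function(d) {
    d <- d[order(d$point_index), , drop = FALSE]
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(x0 = d$x[-n] / pixel_size, y0 = d$y[-n] / pixel_size,
               x1 = d$x[-1] / pixel_size, y1 = d$y[-1] / pixel_size,
               deposit_day = d$deposit_day[-1],
               root_id = d$root_id[-1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rendering parameters for synthetic luminescence frames
#'
#' Controls how a ground-truth root system is turned into a noisy 16-bit
#' luminescence image: root pixels are drawn as thick polylines whose
#' intensity halves every `age_decay_halflife` days (older tissue dims),
#' soil occlusion erases gaps along the roots, speckle noise flips isolated
#' pixels bright, and a fixed additive camera-background pattern (identical
#' across all frames of a batch; what blank subtraction removes) is added.
#'
#' @param pixel_size cm per pixel; the default 0.01 maps the 15 x 30 cm
#'   rhizotron to 1500 x 3000 px.
#' @param peak_intensity gray level of freshly deposited root tissue.
#' @param age_decay_halflife days for the signal of aging tissue to halve.
#' @param occlusion_gap_rate expected soil-occlusion gaps per cm of root;
#'   gap positions are fixed per batch (soil particles do not move).
#' @param occlusion_gap_length erased gap diameter, px.
#' @param speckle_density fraction of pixels hit by speckle noise per frame.
#' @param speckle_intensity_range length-2 gray-level range of speckles.
#' @param background_pattern_seed integer seed of the fixed camera pattern
#'   (and of the occlusion/speckle streams derived from it).
#' @param background_level mean gray level of the camera pattern.
#' @param line_width_px drawn root width, px (odd; default 5 is ~0.5 mm at
#'   the default scale).
#' @param bit_depth image bit depth (rendered values are clipped to it).
#' @return a `render_params` list.
#' @export
render_params <- function(pixel_size = 0.01,
                          peak_intensity = 30000,
                          age_decay_halflife = 7,
                          occlusion_gap_rate = 0.2,
                          occlusion_gap_length = 9,
                          speckle_density = 0.001,
                          speckle_intensity_range = c(2000, 20000),
                          background_pattern_seed = 1,
                          background_level = 300,
                          line_width_px = 5,
                          bit_depth = 16) {
  rp <- list(pixel_size = pixel_size, peak_intensity = peak_intensity,
             age_decay_halflife = age_decay_halflife,
             occlusion_gap_rate = occlusion_gap_rate,
             occlusion_gap_length = occlusion_gap_length,
             speckle_density = speckle_density,
             speckle_intensity_range = speckle_intensity_range,
             background_pattern_seed = as.integer(background_pattern_seed),
             background_level = background_level,
             line_width_px = as.integer(line_width_px),
             bit_depth = as.integer(bit_depth))
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (peak_intensity >= 2^rp$bit_depth)
    stop("peak_intensity must fit the bit depth")
  class(rp) <- "render_params"
  rp
}

render_dims <- function(root, rp) {
  c(nr = as.integer(ceiling(root$params$rhizotron_height / rp$pixel_size)),
    nc = as.integer(ceiling(root$params$rhizotron_width / rp$pixel_size)))
}

#' Fixed camera background pattern (blank frame)
#'
#' Returns exactly the additive fixed-pattern background of a rendered batch:
#' a smooth low-frequency vignette plus seeded per-pixel offsets, quantized
#' to integer gray levels. Identical for every frame rendered with the same
#' `background_pattern_seed`; this is the image the imager records with no
#' rhizotron present, and what [subtract_blank()] removes.
#'
#' @param rp a [render_params()] object.
#' @param dims image size `c(nrow, ncol)`; defaults to the rhizotron at
#'   `rp$pixel_size` for a 15 x 30 cm rhizotron only when `root` is given.
#' @param root optional `ground_truth_root` from which to take the size.
#' @return a `rhizo_frame` with `time_h = 0`, `plant_id = "blank"`.
#' @export
make_blank <- function(rp, dims = NULL, root = NULL) {
  stopifnot(inherits(rp, "render_params"))
  if (is.null(dims)) {
    if (is.null(root)) stop("supply dims or root")
    dims <- render_dims(root, rp)
  }
  nr <- dims[1]; nc <- dims[2]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rp$background_pattern_seed)
  ph <- runif(4, 0, 2 * pi)
  ry <- seq_len(nr) / nr; cx <- seq_len(nc) / nc
  smooth <- outer(0.5 + 0.25 * sin(2 * pi * ry + ph[1]) +
                    0.25 * sin(4 * pi * ry + ph[2]),
                  0.5 + 0.25 * sin(2 * pi * cx + ph[3]) +
                    0.25 * sin(4 * pi * cx + ph[4]))
  pat <- rp$background_level * smooth +
    matrix(runif(nr * nc, 0, rp$background_level / 4), nr, nc)
  pat <- round(pmin(pat, 2^rp$bit_depth - 1))
  storage.mode(pat) <- "integer"
  new_frame(pat, time_h = 0, plant_id = "blank")
}

# occlusion gap centers (px), fixed per batch: sampled along the fully grown
# root so the same soil particles occlude every frame
occlusion_centers <- function(root, rp) {
  if (rp$occlusion_gap_rate <= 0) return(NULL)
  steps <- root_steps(root, root$params$n_days, rp$pixel_size)
  if (is.null(steps)) return(NULL)
  len_cm <- sum(sqrt((steps$x1 - steps$x0)^2 +
                       (steps$y1 - steps$y0)^2)) * rp$pixel_size
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rp$background_pattern_seed + 1L)
  n_gap <- rpois(1, rp$occlusion_gap_rate * len_cm)
  if (n_gap == 0) return(NULL)
  slen <- sqrt((steps$x1 - steps$x0)^2 + (steps$y1 - steps$y0)^2)
  cum <- cumsum(slen)
  at <- runif(n_gap, 0, cum[length(cum)])
  i <- findInterval(at, c(0, cum), rightmost.closed = TRUE)
  i <- pmin(i, nrow(steps))
  f <- (at - c(0, cum)[i]) / pmax(slen[i], 1e-9)
  cbind(x = steps$x0[i] + f * (steps$x1[i] - steps$x0[i]),
        y = steps$y0[i] + f * (steps$y1[i] - steps$y0[i]))
}

#' Render one luminescence frame of a growing root system
#'
#' Draws all root tissue deposited up to `day` as thick polylines with
#' intensity `peak_intensity * 2^(-age / age_decay_halflife)` (age in days),
#' erases the batch-fixed occlusion gaps, adds per-frame speckle and the
#' fixed background pattern, and clips to the bit depth. Deterministic in
#' `(root, day, rp)`.
#'
#' @param root a `ground_truth_root`.
#' @param day imaging day, `1 <= day <= n_days`.
#' @param rp a [render_params()] object.
#' @return a `rhizo_frame` with `time_h = 24 * day`.
#' @export
render_frame <- function(root, day, rp) {
  stopifnot(inherits(root, "ground_truth_root"),
            inherits(rp, "render_params"))
  day <- as.integer(day)
  if (day < 1 || day > root$params$n_days)
    stop("day out of range 1..n_days")
  dims <- render_dims(root, rp)
  nr <- dims[1]; nc <- dims[2]
  img <- matrix(0, nr, nc)
  steps <- root_steps(root, day, rp$pixel_size)
  radius <- max(0L, (rp$line_width_px - 1L) %/% 2L)
  if (!is.null(steps) && nrow(steps) > 0) {
    age <- day - steps$deposit_day
    val <- rp$peak_intensity * 2^(-age / rp$age_decay_halflife)
    segs <- cbind(pmin(pmax(steps$x0, 0), nc - 1),
                  pmin(pmax(steps$y0, 0), nr - 1),
                  pmin(pmax(steps$x1, 0), nc - 1),
                  pmin(pmax(steps$y1, 0), nr - 1), val)
    img <- .cpp_draw_segments(img, segs, radius, FALSE, TRUE)
    occ <- occlusion_centers(root, rp)
    if (!is.null(occ)) {
      gr <- max(1L, as.integer(rp$occlusion_gap_length) %/% 2L)
      esegs <- cbind(occ[, "x"], occ[, "y"], occ[, "x"], occ[, "y"], 0)
      esegs[, c(1, 3)] <- pmin(pmax(esegs[, c(1, 3)], 0), nc - 1)
      esegs[, c(2, 4)] <- pmin(pmax(esegs[, c(2, 4)], 0), nr - 1)
      img <- .cpp_draw_segments(img, esegs, gr, TRUE)
    }
  }
  if (rp$speckle_density > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(rp$background_pattern_seed + 104729L * day)
    k <- round(rp$speckle_density * nr * nc)
    if (k > 0) {
      idx <- sample.int(nr * nc, k)
      img[idx] <- img[idx] + runif(k, rp$speckle_intensity_range[1],
                                   rp$speckle_intensity_range[2])
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (rp$background_level > 0)
    img <- img + make_blank(rp, dims = dims)$pixels
  img <- round(pmin(img, 2^rp$bit_depth - 1))
  storage.mode(img) <- "integer"   # halves the memory of long series
  new_frame(img, time_h = 24 * day, plant_id = "sim")
}

#' Render a whole imaging series
#'
#' @param root a `ground_truth_root`.
#' @param days integer vector of imaging days.
#' @param rp a [render_params()] object.
#' @param plant_id identifier stamped on the frames.
#' @return a [frame_series()].
#' @export
render_series <- function(root, days, rp, plant_id = "sim") {
  frames <- lapply(days, function(d) {
    f <- render_frame(root, d, rp)
    f$plant_id <- plant_id
    f
  })
  frame_series(frames)
}

#' Ground-truth trait record for a simulated root system
#'
#' Computes the nine root system architecture traits directly from the
#' ground-truth polylines (no imaging), in pixel units at `pixel_size`,
#' using the same definitions as the image-derived traits: extents and hull
#' over polyline points, length-weighted average gravity angle and center of
#' mass over polyline steps, and per-day new-growth summaries over the steps
#' deposited on `day`.
#'
#' @param root a `ground_truth_root`.
#' @param day day at which to evaluate (1..n_days).
#' @param pixel_size cm per pixel used to express traits in px.
#' @return one-row data.frame with the `TraitRecord` columns.
#' @export
ground_truth_traits <- function(root, day, pixel_size = 0.01) {
  stopifnot(inherits(root, "ground_truth_root"))
  day <- as.integer(day)
  if (day < 1 || day > root$params$n_days) stop("day out of range")
  steps <- root_steps(root, day, pixel_size)
  if (is.null(steps) || nrow(steps) == 0)
    stop("no deposited steps at this day")
  px <- c(steps$x0, steps$x1); py <- c(steps$y0, steps$y1)
  dx <- steps$x1 - steps$x0; dy <- steps$y1 - steps$y0
  len <- sqrt(dx^2 + dy^2)
  ang <- gravity_angle_of(atan2(abs(dx), dy) * 180 / pi)
  width <- max(px) - min(px)
  depth <- max(py) - min(py)
  mx <- (steps$x0 + steps$x1) / 2; my <- (steps$y0 + steps$y1) / 2
  w <- len / sum(len)
  new <- steps$deposit_day == day
  dt_h <- 24
  data.frame(
    plant_id = "truth", genotype = NA_character_, replicate = NA_character_,
    time_h = 24 * day,
    width = width, depth = depth,
    center_of_mass_x = sum(w * mx), center_of_mass_y = sum(w * my),
    convexhull_area = convex_hull_area(cbind(px, py)),
    depth_width_ratio = if (width > 0) depth / width else NA_real_,
    total_length = sum(len),
    average_angle = sum(len * ang) / sum(len),
    n_new_segments = sum(new),
    length_per_day = sum(len[new]) * 24 / dt_h,
    average_angle_per_day = if (any(new))
      sum(len[new] * ang[new]) / sum(len[new]) else NA_real_)
}

#' Write a rendered series, ground truth, and true traits to disk
#'
#' Frames go to 16-bit grayscale TIFF named `<plant_id>_d<day>.tif`, the
#' ground-truth polylines to `ground_truth.csv`
#' (`root_id,parent_id,birth_day,point_index,x,y,deposit_day`) and the true
#' traits to `truth_traits.csv` in the trait schema.
#'
#' @param root a `ground_truth_root`.
#' @param days imaging days to render.
#' @param rp a [render_params()] object.
#' @param dir output directory (created).
#' @param plant_id identifier used in file names.
#' @return `dir`, invisibly.
#' @export
write_synthetic_series <- function(root, days, rp, dir, plant_id = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxv <- 2^rp$bit_depth - 1
  for (d in days) {
    f <- render_frame(root, d, rp)
    tiff::writeTIFF(f$pixels / maxv,
                    file.path(dir, sprintf("%s_d%d.tif", plant_id, d)),
                    bits.per.sample = 16L)
  }
  blank <- make_blank(rp, dims = render_dims(root, rp))
  tiff::writeTIFF(blank$pixels / maxv, file.path(dir, "blank.tif"),
                  bits.per.sample = 16L)
  write.csv(root$points, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  tt <- do.call(rbind, lapply(days, function(d)
    ground_truth_traits(root, d, rp$pixel_size)))
  tt$plant_id <- plant_id
  write.csv(tt, file.path(dir, "truth_traits.csv"), row.names = FALSE)
  invisible(dir)
}
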