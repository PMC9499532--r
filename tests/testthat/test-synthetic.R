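test_that("unbranched, noise-free growth is a straight vertical polyline", {
  gp <- growth_params(lateral_initiation_rate = 0, tortuosity_sd = 0,
                      primary_elongation_rate = 1, n_days = 5,
                      rhizotron_width = 10, rhizotron_height = 20,
                      rng_seed = 1)
  root <- simulate_root_growth(gp)
  pts <- root$points
  expect_equal(unique(pts$root_id), 1L)
  expect_true(all(abs(pts$x - 5) < 1e-12))
  expect_equal(max(pts$y), 5, tolerance = 1e-9)  # n_days * rate
  expect_true(all(diff(pts$y) > 0))
})

test_that("simulation is deterministic in its seed", {
  gp <- small_growth()
  expect_identical(simulate_root_growth(gp), simulate_root_growth(gp))
  gp2 <- small_growth(rng_seed = 43)
  expect_false(identical(simulate_root_growth(gp)$points,
                         simulate_root_growth(gp2)$points))
})

test_that("set-point 90 with no drift or noise forces horizontal laterals", {
  gp <- growth_params(lateral_gravity_setpoint = 90, setpoint_drift = 0,
                      tortuosity_sd = 0, lateral_initiation_rate = 2,
                      primary_elongation_rate = 1,
                      lateral_elongation_rate = 0.5,
                      rhizotron_width = 30, rhizotron_height = 10,
                      n_days = 5, rng_seed = 2)
  root <- simulate_root_growth(gp)
  lats <- root$points[root$points$root_id != 1, ]
  expect_gt(nrow(lats), 0)
  for (rid in unique(lats$root_id)) {
    y <- lats$y[lats$root_id == rid]
    expect_lt(max(y) - min(y), 1e-9)  # constant depth = horizontal
  }
  # true average angle of lateral steps is 90 degrees
  tt <- ground_truth_traits(root, 5, 0.01)
  prim_len <- 5 / 0.01
  lat_ang <- 90
  expect_gt(tt$average_angle, 0)
  steps <- rhizotrack:::root_steps(root, 5, 0.01)
  lat_steps <- steps[steps$root_id != 1, ]
  ang <- atan2(abs(lat_steps$x1 - lat_steps$x0),
               lat_steps$y1 - lat_steps$y0) * 180 / pi
  expect_true(all(abs(ifelse(ang <= 90, ang, 180 - ang) - 90) < 1e-6))
})

test_that("growth is monotone and laterals start on their parent", {
  root <- simulate_root_growth(small_growth())
  pts <- root$points
  for (d in 2:root$params$n_days) {
    prev <- pts[pts$deposit_day <= d - 1, c("root_id", "point_index")]
    curr <- pts[pts$deposit_day <= d, c("root_id", "point_index")]
    expect_true(nrow(merge(prev, curr)) == nrow(prev))
  }
  expect_true(all(pts$x >= 0 & pts$x <= root$params$rhizotron_width))
  expect_true(all(pts$y >= 0 & pts$y <= root$params$rhizotron_height))
  # first point of every lateral lies on the primary polyline
  prim <- pts[pts$root_id == 1, ]
  for (rid in setdiff(unique(pts$root_id), 1)) {
    p0 <- pts[pts$root_id == rid & pts$point_index == 0, ]
    dmin <- Inf
    for (i in seq_len(nrow(prim) - 1)) {
      a <- c(prim$x[i], prim$y[i]); b <- c(prim$x[i + 1], prim$y[i + 1])
      v <- b - a; w <- c(p0$x, p0$y) - a
      t <- max(0, min(1, sum(v * w) / sum(v * v)))
      dmin <- min(dmin, sqrt(sum((w - t * v)^2)))
    }
    expect_lt(dmin, 1e-8)
  }
})

test_that("noiseless rendering covers exactly the deposited root", {
  root <- simulate_root_growth(small_growth())
  rp <- noiseless_render()
  f <- render_frame(root, 6, rp)
  pts <- root$points
  px <- pmin(pmax(round(pts$x / rp$pixel_size), 0), ncol(f$pixels) - 1)
  py <- pmin(pmax(round(pts$y / rp$pixel_size), 0), nrow(f$pixels) - 1)
  vals <- f$pixels[cbind(py + 1, px + 1)]
  expect_true(all(vals > 0))
  # far corners carry no signal
  expect_equal(f$pixels[nrow(f$pixels), 1], 0)
  expect_equal(f$pixels[nrow(f$pixels), ncol(f$pixels)], 0)
})

test_that("signal halves after one age-decay half-life", {
  gp <- growth_params(lateral_initiation_rate = 0, tortuosity_sd = 0,
                      primary_elongation_rate = 1, n_days = 8,
                      rhizotron_width = 10, rhizotron_height = 20,
                      rng_seed = 1)
  root <- simulate_root_growth(gp)
  H <- 7
  rp <- noiseless_render(age_decay_halflife = H, pixel_size = 0.01)
  f <- render_frame(root, H + 1, rp)
  # a pixel deposited on day 1, H days before the rendered day
  p <- root$points[root$points$deposit_day == 1, ][2, ]
  v <- f$pixels[round(p$y / rp$pixel_size) + 1, round(p$x / rp$pixel_size) + 1]
  expect_lt(abs(v - rp$peak_intensity / 2), 1.5)
})

test_that("the background pattern is fixed across frames of a batch", {
  root <- simulate_root_growth(small_growth())
  rp <- render_params(pixel_size = 0.02, occlusion_gap_rate = 0,
                      speckle_density = 0, background_level = 200)
  f3 <- render_frame(root, 3, rp)
  f6 <- render_frame(root, 6, rp)
  rp0 <- noiseless_render()
  r3 <- render_frame(root, 3, rp0)$pixels
  r6 <- render_frame(root, 6, rp0)$pixels
  off <- r3 == 0 & r6 == 0  # background-only pixels
  expect_identical(f3$pixels[off], f6$pixels[off])
  blank <- make_blank(rp, root = root)
  expect_identical(f3$pixels[off], blank$pixels[off])
})

test_that("blanks are deterministic per seed and differ across seeds", {
  rp1 <- render_params(background_pattern_seed = 1)
  rp2 <- render_params(background_pattern_seed = 2)
  d <- c(60, 30)
  expect_identical(make_blank(rp1, dims = d)$pixels,
                   make_blank(rp1, dims = d)$pixels)
  expect_false(identical(make_blank(rp1, dims = d)$pixels,
                         make_blank(rp2, dims = d)$pixels))
})

test_that("blank subtraction recovers the pure root signal", {
  root <- simulate_root_growth(small_growth())
  rp_bg <- render_params(pixel_size = 0.02, occlusion_gap_rate = 0,
                         speckle_density = 0, background_level = 200)
  f <- render_frame(root, 6, rp_bg)
  blank <- make_blank(rp_bg, root = root)
  pure <- render_frame(root, 6, noiseless_render())
  rec <- subtract_blank(f, blank)
  # off-root recovered pixels are exactly zero; on-root within rounding
  expect_true(all(rec$pixels[pure$pixels == 0] == 0))
  expect_lt(max(abs(rec$pixels - pure$pixels)), 2)
})

test_that("ground-truth traits match direct expectations on simple systems", {
  gp <- growth_params(lateral_initiation_rate = 0, tortuosity_sd = 0,
                      primary_elongation_rate = 1, n_days = 10,
                      rhizotron_width = 10, rhizotron_height = 20,
                      rng_seed = 1)
  root <- simulate_root_growth(gp)
  tt <- ground_truth_traits(root, 10, 0.01)
  expect_equal(tt$depth, 1000, tolerance = 1e-6)
  expect_equal(tt$total_length, 1000, tolerance = 1e-6)
  expect_equal(tt$average_angle, 0, tolerance = 1e-9)
  expect_equal(tt$width, 0)
  expect_true(is.na(tt$depth_width_ratio))
})

test_that("mirror-image laterals keep the center of mass at the seed x", {
  # hand-built ground truth: two equal laterals at +-45 degrees
  pts <- rbind(
    data.frame(root_id = 1, parent_id = NA, birth_day = 1,
               point_index = 0:2, x = 5, y = c(0, 1, 2), deposit_day = 1),
    data.frame(root_id = 2, parent_id = 1, birth_day = 1, point_index = 0:1,
               x = c(5, 6), y = c(1, 2), deposit_day = 1),
    data.frame(root_id = 3, parent_id = 1, birth_day = 1, point_index = 0:1,
               x = c(5, 4), y = c(1, 2), deposit_day = 1))
  root <- structure(list(points = pts,
                         params = growth_params(n_days = 1, rng_seed = 1)),
                    class = "ground_truth_root")
  tt <- ground_truth_traits(root, 1, 0.01)
  expect_equal(tt$center_of_mass_x, 500, tolerance = 1e-9)
})

test_that("ground-truth traits equal the traits module on the same vectors", {
  root <- simulate_root_growth(small_growth())
  ps <- 0.02
  tt <- ground_truth_traits(root, 6, ps)
  steps <- rhizotrack:::root_steps(root, 6, ps)
  theta <- chord_orientation(cbind(steps$x0, steps$y0),
                             cbind(steps$x1, steps$y1))
  segs <- data.frame(x_start = steps$x0, y_start = steps$y0,
                     x_end = steps$x1, y_end = steps$y1,
                     gravity_angle = ifelse(theta <= 90, theta, 180 - theta),
                     time_h = 24 * 6)
  ws <- whole_system_traits(segs)
  for (col in c("width", "depth", "center_of_mass_x", "center_of_mass_y",
                "convexhull_area", "depth_width_ratio", "total_length",
                "average_angle")) {
    expect_equal(tt[[col]], ws[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("written synthetic series round-trips through TIFF and CSV", {
  dir <- tempfile("sim")
  root <- simulate_root_growth(small_growth())
  rp <- noiseless_render()
  write_synthetic_series(root, c(3, 6), rp, dir, plant_id = "p01")
  expect_true(file.exists(file.path(dir, "p01_d3.tif")))
  expect_true(file.exists(file.path(dir, "blank.tif")))
  f <- rhizotrack:::read_frame_tiff(file.path(dir, "p01_d6.tif"), 144, "p01")
  direct <- render_frame(root, 6, rp)
  expect_lt(max(abs(f$pixels - direct$pixels)), 1.01)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), nrow(root$points))
  tt <- read.csv(file.path(dir, "truth_traits.csv"))
  expect_equal(nrow(tt), 2)
  unlink(dir, recursive = TRUE)
})
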