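test_that("raw angles fold to gravity angles and endpoints reconstruct", {
  key <- data.frame(plant_id = "p", genotype = "g", replicate = "r")
  raw <- data.frame(segment_id = 1:3, bbox_x = c(10, 10, 10),
                    bbox_y = c(20, 20, 20), length = 10, theta_raw = c(30, 150, 90),
                    time_h = 24, chord_len = 10, lateral_sign = 1L,
                    plant_id = "p")
  v <- format_segments(raw, key)
  expect_equal(v$gravity_angle, c(30, 30, 90))
  # theta 30: downward chord, start at the bbox corner, end lower right
  expect_equal(v$x_start[1], 10)
  expect_equal(v$y_start[1], 20)
  expect_equal(v$x_end[1], 10 + 10 * sin(30 * pi / 180))
  expect_equal(v$y_end[1], 20 + 10 * cos(30 * pi / 180))
  # theta 150: upward chord, start sits at the bottom of the bbox
  expect_equal(v$y_start[2], 20 + 10 * abs(cos(150 * pi / 180)))
  expect_lt(v$y_end[2], v$y_start[2])
  # theta 90: horizontal, y_end equals y_start
  expect_equal(v$y_end[3], v$y_start[3])
  expect_error(format_segments(transform(raw, plant_id = "zz"), key),
               "missing from key")
})

test_that("two-group splits agree with the MST largest-edge oracle", {
  pts <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  s <- split_two(pts)
  expect_setequal(s[[if (1 %in% s$a) "a" else "b"]], c(1, 2))
  expect_equal(s$gap, 100)
  s2 <- split_two(rbind(c(0, 0), c(5, 5)))
  expect_equal(sort(c(length(s2$a), length(s2$b))), c(1, 1))
  expect_error(split_two(rbind(c(1, 1))), "at least 2")
  set.seed(11)
  for (k in 1:25) {
    pts <- cbind(runif(sample(3:15, 1), 0, 100), runif(1, 0, 100))
    pts <- matrix(runif(2 * sample(3:15, 1), 0, 100), ncol = 2)
    s <- split_two(pts)
    o <- oracle_split_two(pts)
    expect_equal(s$gap, o$gap, tolerance = 1e-9)
    same <- setequal(s$a, o$a) || setequal(s$a, o$b)
    expect_true(same)
  }
})

test_that("collinear equally spaced points split at a maximal gap", {
  pts <- cbind(seq(0, 55, by = 5), 0)
  s <- split_two(pts)
  # both groups contiguous, and the cut removes a 5-unit gap
  expect_equal(s$gap, 5)
  expect_true(all(diff(sort(s$a)) == 1), all(diff(sort(s$b)) == 1))
})

test_that("linearity scores match an independent eigen oracle", {
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_equal(linearity_score(line), 1, tolerance = 1e-12)
  square <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(linearity_score(square), 0.5)
  set.seed(5)
  blob <- cbind(rnorm(200, sd = 3), rnorm(200, sd = 1))
  expect_lt(abs(linearity_score(blob) - oracle_linearity(blob)), 0.02)
  expect_error(linearity_score(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(linearity_score(matrix(1, 5, 2)), "zero scatter")
})

test_that("a compact root is kept whole while distant noise is removed", {
  p <- clean_params(proximity_max = 50, center_x = 30)
  base <- seg_df(x = rep(30, 12), y = seq(0, 55, by = 5))
  res <- clean_iterative(base, p)
  expect_equal(nrow(res$true_root), 12)
  expect_equal(nrow(res$removed), 0)
  # one isolated point 500 px away: removed, reason too_few
  plus1 <- seg_df(x = c(rep(30, 12), 530), y = c(seq(0, 55, by = 5), 30))
  res1 <- clean_iterative(plus1, p)
  expect_equal(nrow(res1$true_root), 12)
  expect_equal(res1$removed$removal_reason, "too_few")
  expect_equal(res1$removed$x_start, 530)
  # a compact distant 3-point blob: 3 < 4 = min_cluster_size
  plus3 <- seg_df(x = c(rep(30, 12), 530, 531, 532),
                  y = c(seq(0, 55, by = 5), 30, 31, 30))
  res3 <- clean_iterative(plus3, p)
  expect_equal(nrow(res3$true_root), 12)
  expect_true(all(res3$removed$removal_reason == "too_few"))
  expect_equal(nrow(res3$removed), 3)
})

test_that("cleaning partitions its input and is idempotent on kept roots", {
  set.seed(21)
  segs <- seg_df(x = c(rep(40, 10), rnorm(5, 400, 2)),
                 y = c(seq(0, 90, by = 10), rnorm(5, 300, 2)),
                 time_h = rep(c(24, 48), c(10, 5)))
  p <- clean_params(proximity_max = 50, center_x = 40)
  res <- clean_iterative(segs, p)
  expect_equal(nrow(res$true_root) + nrow(res$removed), nrow(segs))
  expect_length(intersect(res$true_root$segment_id,
                          res$removed$segment_id), 0)
  again <- clean_iterative(res$true_root, p)
  expect_equal(nrow(again$removed), 0)
  expect_equal(again$true_root$segment_id, res$true_root$segment_id)
})

test_that("far small clusters never disturb previously kept segments", {
  set.seed(31)
  for (k in 1:5) {
    base <- seg_df(x = rep(50, 8) + rnorm(8), y = seq(0, 70, by = 10))
    p <- clean_params(proximity_max = 50, center_x = 50)
    kept0 <- clean_iterative(base, p)$true_root$segment_id
    extra <- seg_df(x = runif(3, 800, 820), y = runif(3, 0, 50))
    extra$segment_id <- extra$segment_id + 100
    res <- clean_iterative(rbind(base, extra), p)
    expect_true(all(kept0 %in% res$true_root$segment_id))
    expect_true(all(res$removed$segment_id > 100))
  }
})

test_that("the anchor switch reproduces the literal farther-from-center rule", {
  # linear group at the center; linear group far off-center; gap > max
  near <- seg_df(x = rep(50, 6), y = seq(0, 50, by = 10))
  far <- seg_df(x = rep(500, 6), y = seq(0, 50, by = 10))
  far$segment_id <- far$segment_id + 10
  both <- rbind(near, far)
  keep_near <- clean_iterative(both, clean_params(
    proximity_max = 50, center_x = 50, hard_max_factor = 20,
    linearity_threshold = 2))  # force the linearity discard branch
  expect_true(all(keep_near$true_root$x_start == 50))
  keep_far <- clean_iterative(both, clean_params(
    proximity_max = 50, center_x = 50, hard_max_factor = 20,
    linearity_threshold = 2, anchor = "farther"))
  expect_true(all(keep_far$true_root$x_start == 500))
})

test_that("production cleaning agrees with the printed-steps transcription", {
  set.seed(41)
  for (k in 1:50) {
    n <- sample(4:15, 1)
    pts <- matrix(runif(2 * n, 0, 600), ncol = 2)
    segs <- seg_df(pts[, 1], pts[, 2],
                   time_h = sample(c(24, 48), n, replace = TRUE))
    p <- clean_params(proximity_max = sample(c(40, 80, 150), 1),
                      center_x = 300)
    res <- clean_iterative(segs, p)
    lab <- rep(NA_character_, n)
    lab[match(res$removed$segment_id, segs$segment_id)] <-
      res$removed$removal_reason
    expect_identical(lab, oracle_clean(segs, p))
  }
})
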