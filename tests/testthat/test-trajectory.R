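rand_traj <- function(n, arena, seed, fps = 25) {
  set.seed(seed)
  trajectory(runif(n, 0, arena$width), runif(n, 0, arena$height), fps = fps)
}

test_that("track length sums Euclidean inter-frame displacements", {
  expect_equal(track_length(trajectory(c(0, 3), c(0, 4))), 5)
  expect_equal(track_length(trajectory(rep(2, 10), rep(3, 10))), 0)
  expect_warning(tl <- track_length(trajectory(1, 1)), "single frame")
  expect_equal(tl, 0)

  set.seed(11)
  x <- runif(101, 0, 20)
  y <- runif(101, 0, 30)
  brute <- sum(vapply(1:100, function(i) {
    sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }, numeric(1)))
  expect_equal(track_length(trajectory(x, y)), brute)
})

test_that("area covered counts traversed grid cells exactly", {
  arena <- arena_spec()
  expect_equal(area_covered(trajectory(rep(10, 5), rep(15, 5)), arena), 1 / 600)

  ## a path sweeping every cell centre covers everything
  cx <- rep(seq(0.5, 19.5, by = 1), times = 30)
  cy <- rep(seq(0.5, 29.5, by = 1), each = 20)
  expect_equal(area_covered(trajectory(cx, cy), arena), 1)

  ## single 10 cm horizontal segment inside one row: 10 or 11 cells
  ## depending on phase (endpoints on gridlines belong to the upper cell
  ## under the half-open convention, so 4 -> 14 still touches 11 cells)
  tr <- trajectory(c(4.3, 14.3), c(7.5, 7.5))
  expect_equal(area_covered(tr, arena), 11 / 600)
  tr2 <- trajectory(c(4.25, 14.25), c(7.5, 7.5))
  expect_equal(area_covered(tr2, arena), 11 / 600)
  tr3 <- trajectory(c(4.0, 13.999), c(7.5, 7.5))
  expect_equal(area_covered(tr3, arena), 10 / 600)

  expect_error(area_covered(trajectory(c(5, 25), c(5, 5)), arena), "bounds")
})

test_that("grid coverage equals the dense supersampling oracle", {
  arena <- arena_spec()
  pool <- synthetic_step_pool(seed = 3)
  for (seed in 1:4) {
    tr <- random_swim(pool, arena, target_length = 600, seed = seed)
    ## quantise to a 0.25 cm tracking lattice so that no traversed cell
    ## holds less path than the oracle's sampling step can detect
    tr$x <- round(tr$x * 4) / 4
    tr$y <- round(tr$y * 4) / 4
    oracle <- supersample_cells(tr, arena, step = 0.01)
    expect_equal(area_covered(tr, arena), length(oracle) / arena$n_cells)
  }
  ## invariance to frame-rate supersampling of the same geometric path
  tr <- rand_traj(40, arena, 99)
  dense_x <- unlist(lapply(1:39, function(i) {
    seq(tr$x[i], tr$x[i + 1], length.out = 20)
  }))
  dense_y <- unlist(lapply(1:39, function(i) {
    seq(tr$y[i], tr$y[i + 1], length.out = 20)
  }))
  expect_equal(area_covered(trajectory(dense_x, dense_y, fps = 500), arena),
               area_covered(tr, arena))
})

test_that("freezing bouts respect the velocity threshold and duration rule", {
  fps <- 25
  arena <- arena_spec()
  ## constant 10 cm/s swim -> never below threshold
  n <- 30 * fps
  fast <- trajectory(seq(1, by = 10 / fps, length.out = n) %% 18,
                     rep(15, n), fps = fps)
  expect_equal(freezing_count(fast), 0L)

  ## one 3 s stationary bout, flanked by fast swimming
  seg <- function(k, speed) cumsum(rep(speed / fps, k))
  x <- c(seg(50, 10), rep(0, 3 * fps), seg(50, 10))
  x <- cumsum(abs(c(0, diff(x)))) / 3 + 1  # monotone, stays in arena
  tr <- trajectory(x %% 18, rep(10, length(x)), fps = fps)
  expect_equal(freezing_count(tr), 1L)

  ## bouts of 2.4 s and 2.6 s -> only the longer one counts
  still <- function(sec) rep(0, round(sec * fps))
  dx <- c(rep(10 / fps, 25), still(2.4), rep(10 / fps, 25), still(2.6),
          rep(10 / fps, 25))
  x <- 1 + cumsum(c(0, dx)) %% 17
  tr <- trajectory(x, rep(10, length(x)), fps = fps)
  expect_equal(freezing_count(tr), 1L)

  ## a terminal bout truncated by trial end still counts if long enough
  dx2 <- c(rep(10 / fps, 25), still(2.6))
  tr2 <- trajectory(1 + cumsum(c(0, dx2)), rep(10, length(dx2) + 1), fps = fps)
  expect_equal(freezing_count(tr2), 1L)

  ## appending stationary frames totalling < min_duration cannot create a
  ## new bout (it can only extend a terminal one)
  tr3 <- trajectory(c(tr2$x, rep(tr2$x[length(tr2$x)], 30)),
                    c(tr2$y, rep(10, 30)), fps = fps)
  expect_equal(freezing_count(tr3), freezing_count(tr2))  # 30/25 s < 2.5 s
  tr4 <- trajectory(c(fast$x, rep(fast$x[n], 30)), c(fast$y, rep(15, 30)),
                    fps = fps)
  expect_equal(freezing_count(tr4), 0L)
})

test_that("middle zone is half the arena and scored by dwell time", {
  arena <- arena_spec()
  m <- arena$middle
  expect_equal((m["xmax"] - m["xmin"]) * (m["ymax"] - m["ymin"]),
               0.5 * arena$width * arena$height,
               ignore_attr = TRUE)

  fps <- 25
  centre <- trajectory(rep(10, 270 * fps), rep(15, 270 * fps), fps = fps)
  expect_equal(time_in_middle(centre, arena), 270)
  expect_equal(mean_wall_distance(centre, arena), 10)

  wall <- trajectory(rep(0.5, 100), seq(1, 29, length.out = 100), fps = fps)
  expect_equal(time_in_middle(wall, arena), 0)
  corner <- trajectory(c(0, 0), c(0, 0), fps = fps)
  expect_equal(mean_wall_distance(corner, arena), 0)

  ## uniform positions spend about half the trial in the middle zone
  tr <- rand_traj(20000, arena, 5)
  expect_equal(time_in_middle(tr, arena) / (nrow(tr) / fps), 0.5,
               tolerance = 0.05)

  ## wall distance correlates strongly with middle-zone occupancy
  set.seed(21)
  stats <- t(vapply(1:60, function(i) {
    tr <- rand_traj(150, arena, 1000 + i)
    c(mid = time_in_middle(tr, arena), wd = mean_wall_distance(tr, arena))
  }, numeric(2)))
  expect_gt(cor(stats[, "mid"], stats[, "wd"]), 0.5)
})

test_that("shoaling tendency is near minus far third occupancy", {
  arena <- arena_spec()
  fps <- 25
  near <- trajectory(rep(10, 180 * fps), rep(25, 180 * fps), fps = fps)
  expect_equal(shoaling_tendency(near, arena, "high"), 180)
  expect_equal(shoaling_tendency(near, arena, "low"), -180)
  centre <- trajectory(rep(10, 50), rep(15, 50), fps = fps)
  expect_equal(shoaling_tendency(centre, arena), 0)
  tr <- rand_traj(20000, arena, 8)
  expect_lt(abs(shoaling_tendency(tr, arena)) / (nrow(tr) / fps), 0.05)
})

test_that("step pools aggregate per-frame displacements", {
  t1 <- trajectory(c(0, 1), c(0, 0))
  expect_equal(nrow(empirical_step_distribution(t1)), 1)
  t2 <- trajectory(c(0, 1, 1), c(0, 0, 2))
  pool12 <- empirical_step_distribution(list(t1, t2))
  pool21 <- empirical_step_distribution(list(t2, t1))
  expect_equal(nrow(pool12), (2 - 1) + (3 - 1))
  expect_equal(sort(pool12$dist), sort(pool21$dist))
  expect_error(empirical_step_distribution(list()), "at least one")
})

test_that("random swims respect bounds and the termination rule", {
  arena <- arena_spec()
  one_cm <- data.frame(dx = c(1, -1, 0, 0), dy = c(0, 0, 1, -1),
                       dist = rep(1, 4))
  class(one_cm) <- c("step_distribution", "data.frame")
  sw <- random_swim(one_cm, arena, target_length = 0.5, seed = 2)
  expect_equal(track_length(sw), 1)  # one accepted step, then stop

  pool <- synthetic_step_pool(seed = 3)
  sw2 <- random_swim(pool, arena, target_length = 2000, seed = 4)
  expect_true(all(sw2$x >= 0 & sw2$x <= 20 & sw2$y >= 0 & sw2$y <= 30))
  tl <- track_length(sw2)
  expect_gte(tl, 2000)
  expect_lt(tl, 2000 + max(pool$dist))

  ## same seed, same path
  sw3 <- random_swim(pool, arena, target_length = 2000, seed = 4)
  expect_identical(sw2, sw3)

  ## degenerate pool: steps larger than the arena are always rejected
  huge <- data.frame(dx = 50, dy = 0, dist = 50)
  class(huge) <- c("step_distribution", "data.frame")
  expect_error(random_swim(huge, arena, target_length = 10, seed = 1,
                           max_reject = 100), "degenerate")
})

test_that("area covered grows with target length toward saturation", {
  arena <- arena_spec()
  pool <- synthetic_step_pool(seed = 6)
  mean_area <- vapply(c(1000, 4000, 8000), function(L) {
    mean(vapply(1:20, function(i) {
      area_covered(random_swim(pool, arena, L, seed = 100 * L + i), arena)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_area) > 0))
  big <- area_covered(random_swim(pool, arena, 50000, seed = 77), arena)
  expect_gt(big, 0.95)
})

test_that("null area model fits its training swims and centres relative area", {
  arena <- arena_spec()
  pool <- synthetic_step_pool(seed = 10)
  null <- fit_null_area_model(pool, arena, length_range = c(500, 8000),
                              seed = 20)
  expect_gt(null$r_squared, 0.9)
  expect_equal(length(null$coefficients), 5)

  ## refit with same seed -> identical coefficients
  null2 <- fit_null_area_model(pool, arena, length_range = c(500, 8000),
                               seed = 20)
  expect_identical(null$coefficients, null2$coefficients)

  ## predictions non-decreasing away from the saturating top end of the
  ## range, where a quartic may wiggle by a fraction of a grid cell
  grid <- seq(500, 7000, length.out = 200)
  expect_true(all(diff(predict(null, grid)) > -1e-6))

  ## fresh swims scored against the model centre on zero
  fresh <- vapply(1:40, function(i) {
    L <- runif(1, 600, 7500)
    sw <- random_swim(pool, arena, L, seed = 5000 + i)
    relative_area(area_covered(sw, arena), track_length(sw), null)
  }, numeric(1))
  expect_lt(abs(mean(fresh)), 2 * sd(fresh) / sqrt(length(fresh)))

  ## a wall-following rectangular circuit covers far less area than a random
  ## swim of the same length, so its relative area is negative
  lap_x <- c(seq(1, 19, 0.5), rep(19, 56), seq(19, 1, -0.5), rep(1, 56))
  lap_y <- c(rep(1, 37), seq(1.5, 29, 0.5), rep(29, 37), seq(28.5, 1, -0.5))
  laps <- ceiling(4000 / 92)  # one lap is 92 cm
  circuit <- trajectory(rep(lap_x, laps), rep(lap_y, laps))
  ra <- relative_area(area_covered(circuit, arena), track_length(circuit), null)
  expect_lt(ra, 0)

  expect_equal(relative_area(predict(null, 3000), 3000, null), 0)
  expect_warning(relative_area(0.5, 9500, null), "outside")
})

test_that("emergence preparation censors, transforms and orients", {
  expect_equal(prepare_emergence(c(1, 950)), c(0, log(900)))
  expect_equal(prepare_emergence(1200, max_time = 900), log(900))
  expect_equal(prepare_emergence(c(10, 100), negate = TRUE),
               -log(c(10, 100)))
  expect_equal(order(prepare_emergence(c(10, 100), negate = TRUE)), c(2, 1))
  expect_error(prepare_emergence(c(5, 0)), "positive")
})
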