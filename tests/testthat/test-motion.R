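test_that("validity gaps partition the track into segments", {
  tr <- tip_track(0:4, 1:5, rep(0, 5), valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  kin <- segment_and_smooth(tr, window = 1, polyorder = 0)
  expect_equal(kin$segment_id, c(0L, 0L, 1L, 1L))
  expect_equal(kin$frame, c(0L, 1L, 3L, 4L))

  full <- segment_and_smooth(tip_track(0:4, 1:5, rep(0, 5)), window = 1)
  expect_equal(unique(full$segment_id), 0L)
  expect_error(segment_and_smooth(tip_track(0:1, 1:2, 1:2, valid = c(FALSE, FALSE))),
               "no valid frames")
  expect_error(segment_and_smooth(tip_track(0:9, 1:10, 1:10), window = 4),
               "odd")
})

test_that("straight constant-speed motion has vanishing acceleration and jerk", {
  n <- 50
  kin <- make_kin(3 * (0:(n - 1)), 4 * (0:(n - 1)), fps = 30)
  speed <- sqrt(kin$vx^2 + kin$vy^2)
  expect_equal(speed, rep(150, n), tolerance = 1e-9)
  expect_lt(max(abs(c(kin$ax, kin$ay, kin$jx, kin$jy))), 1e-9 * 150)
})

test_that("path distance sums Euclidean steps within segments only", {
  expect_equal(path_distance(make_kin(c(0, 3), c(0, 4))), 5)
  expect_equal(path_distance(make_kin(0, 0)), 0)
  # gap between (1,0) and (5,0) must not be bridged
  kin <- make_kin(c(0, 1, 3, 5, 6), rep(0, 5),
                  valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(path_distance(kin), 2)
  # chord bound within a segment
  set.seed(5)
  kin2 <- make_kin(cumsum(rnorm(30)), cumsum(rnorm(30)))
  chord <- sqrt(diff(range(kin2$x[c(1, 30)]))^2 + diff(kin2$y[c(1, 30)])^2)
  expect_gte(path_distance(kin2), chord)
})

test_that("NJI of a sampled minimum-jerk reach approaches the 360 closed form", {
  mj <- sample_min_jerk(d = 100, duration = 1, n = 1000)
  kin <- make_kin(mj$x, mj$y, fps = mj$fps)
  nji <- normalized_jerk_index(kin)
  expect_equal(nji, 360, tolerance = 0.01)
  # error decreases with sampling density
  err <- vapply(c(250, 1000, 4000), function(n) {
    mj <- sample_min_jerk(n = n)
    abs(normalized_jerk_index(make_kin(mj$x, mj$y, fps = mj$fps)) - 360)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("NJI is invariant to temporal and spatial rescaling", {
  mj <- sample_min_jerk(d = 100, duration = 1, n = 1000)
  ref <- normalized_jerk_index(make_kin(mj$x, mj$y, fps = mj$fps))
  mj2 <- sample_min_jerk(d = 300, duration = 10, n = 1000)
  scaled <- normalized_jerk_index(make_kin(mj2$x, mj2$y, fps = mj2$fps))
  expect_equal(scaled, ref, tolerance = 1e-6)
})

test_that("NJI is invariant under rotation and translation", {
  set.seed(8)
  mj <- sample_min_jerk(n = 400)
  x <- mj$x + 0.5 * sin(seq(0, 6 * pi, length.out = 400))
  y <- mj$y + 0.3 * cos(seq(0, 5 * pi, length.out = 400))
  ref <- normalized_jerk_index(make_kin(x, y, fps = mj$fps))
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 55
  yr <- sin(th) * x + cos(th) * y - 31
  expect_equal(normalized_jerk_index(make_kin(xr, yr, fps = mj$fps)), ref,
               tolerance = 1e-9)
})

test_that("jerk-level noise increases NJI in expectation", {
  set.seed(9)
  mj <- sample_min_jerk(d = 100, duration = 1, n = 500)
  mean_nji <- vapply(c(0, 0.05, 0.2), function(amp) {
    mean(vapply(1:20, function(i) {
      normalized_jerk_index(make_kin(mj$x + rnorm(500, 0, amp),
                                     mj$y, fps = mj$fps))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nji) > 0))
})

test_that("degenerate kinematic inputs raise informative errors", {
  still <- make_kin(rep(1, 10), rep(2, 10))
  expect_error(normalized_jerk_index(still), "stationary")
  expect_error(normalized_jerk_index(make_kin(0, 0)), "duration")
})
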