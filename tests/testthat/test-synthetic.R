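test_that("minimum-jerk segments have the closed-form profile", {
  mj <- min_jerk_segment(c(0, 0), c(100, 0), 1.001, 1000)  # 1001 samples
  # midpoint symmetry: displacement at tau = 0.5 is half the reach
  expect_equal(mj$x[501], 50, tolerance = 1e-9)
  # NJI of the sampled segment approaches 360
  fps <- (nrow(mj) - 1) / max(mj$time_s)
  expect_equal(normalized_jerk_index(make_kin(mj$x, mj$y, fps = fps)),
               360, tolerance = 0.01)
  # doubling the duration leaves the path (and its length) unchanged
  mj2 <- min_jerk_segment(c(0, 0), c(100, 0), 2, 1000)
  pd1 <- path_distance(make_kin(mj$x, mj$y, fps = 1000))
  pd2 <- path_distance(make_kin(mj2$x, mj2$y, fps = 1000))
  expect_equal(pd1, pd2)
  expect_equal(range(mj2$x), range(mj$x))
  expect_error(min_jerk_segment(c(5, 5), c(5, 5), 1, 100), "zero-length")
  expect_error(min_jerk_segment(c(0, 0), c(1, 1), 0, 100), "positive")
})

test_that("a perfectly skilled noiseless trial is clean and smooth", {
  cfg <- synthetic_config(jerk_noise_scale = 0, jitter_px = 0, gap_rate = 0,
                          tde_rate = 6, seed = 61)
  set.seed(61)
  tr <- synth_trial(1, cfg, "t")
  d <- relative_delta_va(tr$va)
  expect_equal(detect_tde(d)$count, 0L)
  expect_true(all(tr$right$valid))
  nji <- normalized_jerk_index(segment_and_smooth(tr$right, window = 1))
  expect_true(is.finite(nji) && nji > 0)
})

test_that("lower skill yields rougher motion and more deformation errors", {
  cfg <- synthetic_config()
  stats_at <- function(skill, n = 12) {
    set.seed(62)
    t(vapply(seq_len(n), function(i) {
      tr <- synth_trial(skill, cfg, "t")
      kin <- segment_and_smooth(tr$right, window = 7)
      c(nji = normalized_jerk_index(kin),
        tde = detect_tde(relative_delta_va(tr$va))$count)
    }, numeric(2)))
  }
  lo <- stats_at(0.2)
  hi <- stats_at(0.9)
  expect_gt(mean(lo[, "nji"]), mean(hi[, "nji"]))
  expect_gt(mean(lo[, "tde"]), mean(hi[, "tde"]))
})

test_that("rubric generation hits the scale limits and stays reliable", {
  cfg0 <- synthetic_config(rater_sd = 0)
  set.seed(63)
  expect_equal(average_scores(synth_rubric(1, cfg0))$total, 45)
  expect_equal(average_scores(synth_rubric(0, cfg0))$total, 9)
})

test_that("cohort generation is deterministic and correctly structured", {
  cfg <- synthetic_config(n_surgeons = 2, seed = 64)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$va, b$va)
  expect_identical(a$rubric, b$rubric)
  expect_equal(nrow(a$trials), 4L)
  expect_setequal(names(a$tracks),
                  paste0(rep(a$trials$trial, each = 2), "/",
                         c("right", "left")))
  c2 <- generate_cohort(synthetic_config(n_surgeons = 2, seed = 65))
  expect_false(identical(a$tracks, c2$tracks))
  expect_equal(names(c2$va), names(a$va))  # schema invariant to seed
})

test_that("default cohorts are bimodal with both labels present", {
  ds <- generate_cohort(synthetic_config(seed = 66))
  lab <- label_good_poor(average_scores(ds$rubric))
  expect_equal(nrow(lab), 14L)
  expect_true(all(c("good", "poor") %in% lab$label))
  expect_true(all(c("good", "poor") %in% ds$truth$label))
})

test_that("written cohorts read back into equivalent objects", {
  dir <- withr::local_tempdir()
  ds <- generate_cohort(synthetic_config(n_surgeons = 2,
                                         phase_durations_s = c(A = 2, B = 2,
                                                               C = 2, D = 3),
                                         seed = 67), dir = dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$tracks), names(ds$tracks))
  tr_a <- ds$tracks[[1]]
  tr_b <- back$tracks[[names(ds$tracks)[1]]]
  expect_equal(tr_b$x, tr_a$x, tolerance = 1e-9)
  expect_equal(tr_b$valid, tr_a$valid)
  expect_equal(back$va[[1]]$va, ds$va[[1]]$va)
  expect_equal(tibble::as_tibble(back$phases), tibble::as_tibble(ds$phases))
  expect_equal(back$truth$label, ds$truth$label)
})
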