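test_that("Spearman rho tracks monotone relationships and agrees with cor.test", {
  x <- c(0.3, 1.1, 2.5, 3.0, 4.2, 5.9)
  expect_equal(spearman_rho_p(x, exp(x))$rho, 1)
  expect_equal(spearman_rho_p(x, -x)$rho, -1)

  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(14)
    b <- 0.5 * a + rnorm(14)
    res <- spearman_rho_p(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman",
                                     exact = FALSE))
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  }
  # invariance under strictly increasing transforms of either variable
  a <- rnorm(12)
  b <- rnorm(12)
  expect_equal(spearman_rho_p(exp(a), b^3 + 5 * b)$rho,
               spearman_rho_p(a, b)$rho)

  expect_error(spearman_rho_p(1:3, 3:1), "at least 4")
  expect_warning(res <- spearman_rho_p(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("permutation p-values equal exhaustive enumeration for small n", {
  fixtures <- list(
    list(x = 1:5, y = c(2, 1, 4, 3, 5)),
    list(x = c(1, 2, 2, 4, 7), y = c(3, 1, 5, 2, 4)),   # ties in x
    list(x = 1:6, y = c(2, 4, 1, 3, 6, 5)),
    list(x = 1:7, y = c(3, 1, 2, 7, 4, 6, 5)))
  for (f in fixtures) {
    res <- spearman_rho_p(f$x, f$y, method = "permutation")
    expect_equal(res$p, brute_spearman_p(f$x, f$y), tolerance = 1e-12)
  }
  # the first fixture has the textbook rho of 0.8
  expect_equal(spearman_rho_p(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
})

test_that("screening flags parameters that carry rubric signal", {
  set.seed(42)
  surgeons <- sprintf("S%02d", 1:14)
  totals <- c(rnorm(7, 40, 2), rnorm(7, 24, 3))
  cats <- rubric_categories()
  scores <- tibble::tibble(surgeon = surgeons,
                           !!!setNames(as.list(rep(0, 9)), cats),
                           total = totals)
  for (ct in cats) scores[[ct]] <- totals / 9 + rnorm(14, 0, 0.2)

  informative <- make_cohort(setNames(totals + rnorm(14, 0, 0.5), surgeons))
  res <- screen_parameters(informative, scores)
  expect_equal(nrow(res), 9L)
  expect_true(all(res$significant))
  expect_true(all(abs(res$rho) <= 1))

  # a missing cell drops to n-1 pairs listwise
  informative$value[1] <- NA
  res2 <- screen_parameters(informative, scores)
  expect_equal(unique(res2$n), 13L)
  expect_error(screen_parameters(informative[1:3, ], scores), "fewer than 4")
})

test_that("pure-noise parameters are significant at about the alpha rate", {
  set.seed(43)
  surgeons <- sprintf("S%02d", 1:14)
  cats <- rubric_categories()
  scores <- tibble::tibble(surgeon = surgeons,
                           !!!setNames(as.list(rep(0, 9)), cats), total = 0)
  for (ct in cats) scores[[ct]] <- rnorm(14, 3)
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    noise <- make_cohort(setNames(rnorm(14), surgeons))
    hits <- hits + sum(screen_parameters(noise, scores)$significant)
  }
  rate <- hits / (9 * n_rep)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("feature selection on the published table reproduces Models 1-3", {
  screen <- read_screen_pvalues(reference_screen_path())
  expect_equal(nrow(screen), 7L * 5L * 9L)
  sel <- select_model_features(screen)

  m1 <- sel$model1[order(sel$model1$metric), ]
  expect_equal(m1$metric, c("max_dva", "n_tde"))
  expect_equal(m1$phase, c("B", "C"))
  expect_equal(m1$n_significant, c(2L, 6L))

  m2 <- sel$model2[order(sel$model2$metric, sel$model2$hand), ]
  expect_equal(paste(m2$metric, m2$hand, m2$phase),
               c("nji left All", "nji right C", "pd left All", "pd right All"))

  expect_equal(nrow(sel$model3), 6L)
  expect_equal(dplyr::bind_rows(sel$model1, sel$model2)[
    c("metric", "hand", "phase")], sel$model3[c("metric", "hand", "phase")])
})

test_that("selection degrades gracefully without significant cells", {
  screen <- read_screen_pvalues(reference_screen_path())
  none <- screen
  none$significant <- FALSE
  none$p <- 1
  expect_warning(expect_warning(sel <- select_model_features(none),
                                "Model 1"), "Model 2")
  expect_equal(nrow(sel$model3), 0L)

  one <- none
  one$significant[one$metric == "cv_va" & one$phase == "B" &
                    one$category == "efficiency"] <- TRUE
  expect_warning(sel1 <- select_model_features(one), "Model 2")
  expect_equal(sel1$model1$metric, "cv_va")
  expect_equal(sel1$model1$phase, "B")
})
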