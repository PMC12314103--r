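make_two_feature_cohort <- function(X, surgeons = sprintf("P%02d", seq_len(nrow(X)))) {
  co <- dplyr::bind_rows(
    tibble::tibble(surgeon = surgeons, metric = "pd", hand = "right",
                   phase = "All", value = X[, 1]),
    tibble::tibble(surgeon = surgeons, metric = "nji", hand = "right",
                   phase = "All", value = X[, 2]))
  class(co) <- c("cohort_table", class(co))
  co
}
two_features <- tibble::tibble(metric = c("pd", "nji"), hand = "right",
                               phase = "All")

test_that("LDA weights follow the pooled-covariance closed form", {
  set.seed(51)
  # classes separated along feature 1 only
  n <- 150
  X <- rbind(cbind(rnorm(n, 0), rnorm(n)), cbind(rnorm(n, 4), rnorm(n)))
  labels <- tibble::tibble(surgeon = sprintf("P%03d", 1:(2 * n)),
                           label = rep(c("good", "poor"), each = n))
  fit <- fit_lda(make_two_feature_cohort(X, surgeons = labels$surgeon),
                 two_features, labels)
  expect_lt(abs(fit$weights[2] / fit$weights[1]), 0.12)
  expect_lt(fit$weights[1], 0)  # good has smaller PD; score must rise toward good

  # 1D case reduces to (mean_good - mean_poor) / pooled variance
  x1 <- X[, 1]
  g <- seq_len(n); p <- n + seq_len(n)
  fit1 <- fit_lda(make_two_feature_cohort(cbind(x1, 0),
                                          surgeons = labels$surgeon),
                  two_features[1, ], labels)
  pooled <- ((n - 1) * var(x1[g]) + (n - 1) * var(x1[p])) / (2 * n - 2)
  expect_equal(unname(fit1$weights), (mean(x1[g]) - mean(x1[p])) / pooled)

  # orientation: score at the good mean exceeds score at the poor mean
  expect_gt(sum(fit$weights * fit$class_means$good) + fit$intercept,
            sum(fit$weights * fit$class_means$poor) + fit$intercept)
})

test_that("cross-check: weights are proportional to MASS::lda scaling", {
  set.seed(52)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 1.2), ncol = 2))
  labels <- tibble::tibble(surgeon = sprintf("P%02d", 1:60),
                           label = rep(c("good", "poor"), each = 30))
  fit <- fit_lda(make_two_feature_cohort(X), two_features, labels)
  ref <- MASS::lda(X, grouping = labels$label)$scaling
  ratio <- unname(fit$weights / drop(ref))
  expect_equal(ratio[1], ratio[2], tolerance = 1e-8)
})

test_that("a duplicated feature triggers the ridge and leaves scores intact", {
  set.seed(53)
  x <- c(rnorm(10, 0), rnorm(10, 3))
  labels <- tibble::tibble(surgeon = sprintf("P%02d", 1:20),
                           label = rep(c("good", "poor"), each = 10))
  co_dup <- make_two_feature_cohort(cbind(x, x))
  expect_message(fit_dup <- fit_lda(co_dup, two_features, labels), "ridge")
  co1 <- make_two_feature_cohort(cbind(x, 0))
  fit1 <- fit_lda(co1, two_features[1, ], labels)
  s_dup <- discriminant_score(fit_dup, co_dup)
  s1 <- discriminant_score(fit1, co1)
  expect_equal(unname(s_dup), unname(s1), tolerance = 1e-6)
})

test_that("degenerate classes are rejected", {
  labels <- tibble::tibble(surgeon = sprintf("P%02d", 1:20),
                           label = rep("good", 20))
  co <- make_two_feature_cohort(matrix(rnorm(40), ncol = 2))
  expect_error(fit_lda(co, two_features, labels), "both good and poor")
  labels$label[1] <- "poor"
  expect_error(fit_lda(co, two_features, labels), "2 surgeons per class")
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney statistic", {
  set.seed(54)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    scores <- sample(1:8, n, replace = TRUE) + rnorm(n) * sample(0:1, 1)
    labels <- sample(c("good", "poor"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("good", "poor")
    r <- roc_auc(scores, labels, n_boot = 0)
    expect_identical(r$auc, pairwise_auc(scores, labels))
    # trapezoidal area under the returned curve equals the rank AUC
    expect_equal(sum(diff(r$curve$fpr) *
                       (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2),
                 r$auc, tolerance = 1e-12)
  }
})

test_that("ROC endpoints, separation and null behaviour are correct", {
  r <- roc_auc(c(1, 2, 10, 11), c("poor", "poor", "good", "good"), n_boot = 50)
  expect_equal(r$auc, 1)
  expect_equal(r$curve[1, ], tibble::tibble(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$tpr) >= 0) && all(diff(r$curve$fpr) >= 0))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  # tie handling: scores [1,2,2,4] with one cross-class tie
  expect_equal(roc_auc(c(1, 2, 2, 4), c("poor", "poor", "good", "good"),
                       n_boot = 0)$auc,
               pairwise_auc(c(1, 2, 2, 4), c("poor", "poor", "good", "good")))

  set.seed(55)
  s <- rnorm(4000)
  lab <- sample(c("good", "poor"), 4000, replace = TRUE)
  expect_equal(roc_auc(s, lab, n_boot = 0)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:3, rep("good", 3)), "both good and poor")
})

test_that("the LDA ROC is invariant to affine feature rescaling", {
  set.seed(56)
  X <- rbind(matrix(rnorm(48, 0), ncol = 2), matrix(rnorm(48, 1.5), ncol = 2))
  labels <- tibble::tibble(surgeon = sprintf("P%02d", 1:48),
                           label = rep(c("good", "poor"), each = 24))
  co <- make_two_feature_cohort(X)
  X2 <- cbind(X[, 1] * 1e6 - 3, X[, 2] * 0.01 + 999)
  co2 <- make_two_feature_cohort(X2)
  auc1 <- roc_auc(discriminant_score(fit_lda(co, two_features, labels), co),
                  labels$label, n_boot = 0)$auc
  auc2 <- roc_auc(discriminant_score(fit_lda(co2, two_features, labels), co2),
                  labels$label, n_boot = 0)$auc
  expect_equal(auc1, auc2, tolerance = 1e-12)
})

test_that("fitted weights recover the population discriminant direction", {
  set.seed(57)
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  L <- chol(Sigma)
  dmu <- c(1.5, -0.5)
  n <- 400
  X <- rbind(matrix(rnorm(2 * n), ncol = 2) %*% L,
             sweep(matrix(rnorm(2 * n), ncol = 2) %*% L, 2, dmu, "+"))
  labels <- tibble::tibble(surgeon = sprintf("P%04d", 1:(2 * n)),
                           label = rep(c("poor", "good"), each = n))
  co <- make_two_feature_cohort(X, surgeons = labels$surgeon)
  fit <- fit_lda(co, two_features, labels)
  w_pop <- solve(Sigma, dmu)
  cosine <- sum(fit$weights * w_pop) /
    sqrt(sum(fit$weights^2) * sum(w_pop^2))
  expect_gt(cosine, 0.99)
})
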