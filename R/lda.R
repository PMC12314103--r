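#' Fit a Fisher linear discriminant between good and poor performers
#'
#' Equal-prior Fisher discriminant on the selected feature cells:
#' `weights = S_pooled^{-1} (mean_good - mean_poor)` with the pooled
#' within-class covariance (n-2 denominator), oriented so the score
#' increases toward the good class; the intercept centres the score at
#' the midpoint of the class means. A small ridge
#' (`1e-6 * trace/dim` on the diagonal) is added only when the pooled
#' covariance is singular, with a message. Surgeons with missing feature
#' cells are dropped listwise with a warning.
#'
#' @param cohort A `cohort_table` from [build_cohort_table()].
#' @param features Tibble of feature cells (`metric`, `hand`, `phase`),
#'   e.g. one of the models from [select_model_features()].
#' @param labels Tibble with columns `surgeon` and `label`
#'   (`"good"`/`"poor"`), e.g. from [label_good_poor()].
#' @return A `discriminant_model` list: `features`, `weights`,
#'   `intercept`, `class_means`, `pooled_covariance`, `surgeons`.
#' @export
fit_lda <- function(cohort, features, labels) {
  X <- cohort_matrix(cohort, features)
  lab <- setNames(labels$label, labels$surgeon)[rownames(X)]
  keep <- stats::complete.cases(X) & !is.na(lab)
  if (any(!keep))
    warning("dropping surgeon(s) with missing cells: ",
            paste(rownames(X)[!keep], collapse = ", "))
  X <- X[keep, , drop = FALSE]
  lab <- lab[keep]
  if (!all(c("good", "poor") %in% lab))
    stop("both good and poor labels are required", call. = FALSE)
  if (min(table(lab)) < 2L)
    stop("need at least 2 surgeons per class", call. = FALSE)
  Xg <- X[lab == "good", , drop = FALSE]
  Xp <- X[lab == "poor", , drop = FALSE]
  mu_g <- colMeans(Xg)
  mu_p <- colMeans(Xp)
  Sp <- ((nrow(Xg) - 1) * stats::cov(Xg) + (nrow(Xp) - 1) * stats::cov(Xp)) /
    (nrow(X) - 2)
  if (all(Sp == 0))
    stop("all selected features are constant within classes", call. = FALSE)
  # solve in standardized coordinates: feature scales differ by orders
  # of magnitude (NJI vs CV-VA), so conditioning is judged on the
  # correlation-scaled matrix, not the raw covariance
  sc <- sqrt(pmax(diag(Sp), .Machine$double.eps))
  R <- Sp / tcrossprod(sc)
  delta_s <- (mu_g - mu_p) / sc
  w_s <- tryCatch(if (rcond(R) < 1e-10) NULL else solve(R, delta_s),
                  error = function(e) NULL)
  if (is.null(w_s)) {
    ridge <- 1e-6 * sum(diag(R)) / ncol(R)
    message("pooled covariance is singular; adding ridge ", signif(ridge, 3))
    w_s <- solve(R + diag(ridge, ncol(R)), delta_s)
  }
  w <- w_s / sc
  structure(list(features = features, weights = w,
                 intercept = -sum(w * (mu_g + mu_p) / 2),
                 class_means = list(good = mu_g, poor = mu_p),
                 pooled_covariance = Sp, surgeons = rownames(X)),
            class = "discriminant_model")
}

#' Discriminant scores for a cohort
#'
#' @param model A `discriminant_model` from [fit_lda()].
#' @param cohort A `cohort_table` containing the model's features.
#' @return Named numeric vector of per-surgeon scores (higher = more
#'   good-like); the monotone statistic underlying the ROC.
#' @export
discriminant_score <- function(model, cohort) {
  X <- cohort_matrix(cohort, model$features)
  drop(X %*% model$weights) + model$intercept
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for
#' ties, which equals the trapezoidal area under the empirical ROC
#' curve; the 95% CI is a stratified bootstrap percentile interval
#' (classes resampled separately).
#'
#' @param scores Numeric scores, higher meaning more good-like.
#' @param labels `"good"`/`"poor"` per score; good is the positive class.
#' @param n_boot Bootstrap resamples (default 2000); 0 disables the CI.
#' @param conf Confidence level (default 0.95).
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, and `curve`,
#'   a tibble of (fpr, tpr) points from (0,0) to (1,1).
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, conf = 0.95) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  pos <- labels == "good"
  if (!any(pos) || all(pos))
    stop("both good and poor labels are required", call. = FALSE)
  auc_rank <- function(s, p) {
    r <- rank(s)
    n1 <- sum(p); n0 <- sum(!p)
    (sum(r[p]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_rank(scores, pos)
  # empirical curve: thresholds descending; tied scores move diagonally
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- tibble::tibble(fpr = c(0, fp[last] / sum(!pos)),
                          tpr = c(0, tp[last] / sum(pos)))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ig <- which(pos); ip <- which(!pos)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ig, length(ig), replace = TRUE),
               sample(ip, length(ip), replace = TRUE))
      auc_rank(scores[idx], pos[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, (1 + conf) / 2)))
  }
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], curve = curve),
            class = "roc_result")
}
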