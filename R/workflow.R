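#' Run the full skill-assessment workflow on a cohort dataset
#'
#' Chains every stage: per-trial parameter extraction across phases and
#' hands, first-two-trial aggregation, rubric averaging and good/poor
#' labelling, interrater reliability, Spearman screening,
#' discriminant-feature selection, and Fisher-discriminant fits with ROC
#' evaluation for the vessel-derived model (1), the motion-derived model
#' (2) and their union (3). When the dataset carries ground-truth labels
#' (synthetic cohorts), each model's scores are additionally evaluated
#' against them.
#'
#' @param dataset Cohort dataset ([generate_cohort()] / [read_cohort()]).
#' @param tde_threshold Deformation threshold on `|dva|` (default 1.13).
#' @param cutoff Rubric good/poor cutoff (default 35).
#' @param alpha Screening significance level (default 0.05).
#' @param screen_method p-value method for the screen.
#' @param n_boot Bootstrap resamples for ROC CIs (default 2000).
#' @param features Optional list of feature tibbles (`model1`, `model2`,
#'   `model3`) to use instead of data-driven selection.
#' @param ... Further arguments to [trial_parameters()].
#' @return List with `params`, `cohort`, `scores` (labelled),
#'   `reliability`, `screen`, `features`, and `fits` — one entry per
#'   non-empty model holding `model`, `scores`, `roc`, and `roc_truth`
#'   when ground truth is available.
#' @export
run_skill_pipeline <- function(dataset, tde_threshold = 1.13, cutoff = 35,
                               alpha = 0.05, screen_method = "t_approx",
                               n_boot = 2000, features = NULL, ...) {
  params <- extract_cohort_parameters(dataset,
                                      tde_threshold = tde_threshold, ...)
  cohort <- build_cohort_table(params)
  scores <- label_good_poor(average_scores(dataset$rubric), cutoff = cutoff)
  reliability <- rubric_alpha(dataset$rubric)
  screen <- screen_parameters(cohort, scores, alpha = alpha,
                              method = screen_method)
  if (is.null(features)) features <- select_model_features(screen)
  labels <- scores[c("surgeon", "label")]
  fits <- list()
  for (m in c("model1", "model2", "model3")) {
    feat <- features[[m]]
    if (is.null(feat) || nrow(feat) == 0L) next
    fit <- fit_lda(cohort, feat, labels)
    s <- discriminant_score(fit, cohort)
    lab <- setNames(labels$label, labels$surgeon)[names(s)]
    entry <- list(model = fit, scores = s,
                  roc = roc_auc(s, lab, n_boot = n_boot))
    if (!is.null(dataset$truth)) {
      tl <- setNames(dataset$truth$label, dataset$truth$surgeon)[names(s)]
      entry$roc_truth <- roc_auc(s, tl, n_boot = n_boot)
    }
    fits[[m]] <- entry
  }
  list(params = params, cohort = cohort, scores = scores,
       reliability = reliability, screen = screen, features = features,
       fits = fits)
}
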