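#' Representative rubric scores per surgeon
#'
#' For each surgeon, averages each of the nine category scores over all
#' (rater x trial) entries of the first `n_trials` trials; the total is
#' the sum of the nine category means (range 9-45).
#'
#' @param records Rubric tibble ([read_rubric_csv()] layout: `surgeon`,
#'   `trial`, `rater`, nine category columns).
#' @param n_trials Number of leading trials used (default 2).
#' @return A tibble of class `surgeon_scores`: `surgeon`, the nine
#'   category mean columns, and `total`.
#' @export
average_scores <- function(records, n_trials = 2) {
  records <- validate_rubric(records)
  cats <- rubric_categories()
  out <- lapply(split(records, records$surgeon), function(r) {
    trials <- sort(unique(r$trial))
    if (length(trials) < n_trials)
      stop(sprintf("surgeon %s has %d trial(s); %d required",
                   r$surgeon[1], length(trials), n_trials), call. = FALSE)
    r <- r[r$trial %in% trials[seq_len(n_trials)], , drop = FALSE]
    raters <- unique(r$rater)
    grid <- expand.grid(trial = trials[seq_len(n_trials)], rater = raters,
                        stringsAsFactors = FALSE)
    have <- paste(r$trial, r$rater)
    missing <- grid[!paste(grid$trial, grid$rater) %in% have, , drop = FALSE]
    if (nrow(missing))
      stop(sprintf("surgeon %s is missing rating(s): %s", r$surgeon[1],
                   paste(paste0("trial ", missing$trial, "/rater ",
                                missing$rater), collapse = ", ")),
           call. = FALSE)
    means <- colMeans(r[cats])
    tibble::tibble(surgeon = r$surgeon[1], !!!as.list(means),
                   total = sum(means))
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::arrange(out, .data$surgeon)
  class(out) <- unique(c("surgeon_scores", class(out)))
  out
}

#' Cronbach's alpha for interrater reliability
#'
#' `alpha = k/(k-1) * (1 - sum(var_j) / var(sum))` over `k` raters, with
#' sample variances taken across the rated performances. Equals 1 for
#' raters who agree up to a per-rater constant offset; near 0 for
#' independent-noise raters.
#'
#' @param ratings Numeric matrix with one row per rated performance and
#'   one column per rater.
#' @return Alpha, or `NA` (with a warning) when the variance of the
#'   rater sum is zero and alpha is undefined.
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L || nrow(ratings) < 2L)
    stop("need at least 2 raters and 2 rated performances", call. = FALSE)
  v_sum <- var(rowSums(ratings))
  if (v_sum == 0) {
    warning("variance of the rater sum is zero; alpha undefined")
    return(NA_real_)
  }
  k <- ncol(ratings)
  k / (k - 1) * (1 - sum(apply(ratings, 2, var)) / v_sum)
}

#' Interrater reliability of the rating scale, per category
#'
#' Computes Cronbach's alpha among raters for each technical category
#' (each rater contributing their mean score over the first `n_trials`
#' trials, across surgeons), plus a whole-scale alpha on rater totals.
#'
#' @param records Rubric tibble.
#' @param n_trials Number of leading trials averaged per rater.
#' @return Tibble with columns `category` (nine categories plus
#'   `"total"`) and `alpha`.
#' @export
rubric_alpha <- function(records, n_trials = 2) {
  records <- validate_rubric(records)
  cats <- rubric_categories()
  long <- tidyr::pivot_longer(records, dplyr::all_of(cats),
                              names_to = "category", values_to = "score")
  first2 <- dplyr::ungroup(dplyr::filter(
    dplyr::group_by(long, .data$surgeon),
    .data$trial %in% sort(unique(.data$trial))[seq_len(n_trials)]))
  per_rater <- dplyr::summarise(
    dplyr::group_by(first2, .data$surgeon, .data$rater, .data$category),
    score = mean(.data$score), .groups = "drop")
  alpha_of <- function(df) {
    wide <- tidyr::pivot_wider(df, id_cols = "surgeon",
                               names_from = "rater", values_from = "score")
    cronbach_alpha(as.matrix(wide[-1L]))
  }
  per_cat <- vapply(split(per_rater, per_rater$category), alpha_of,
                    numeric(1))
  totals <- dplyr::summarise(
    dplyr::group_by(per_rater, .data$surgeon, .data$rater),
    score = sum(.data$score), .groups = "drop")
  tibble::tibble(category = c(cats, "total"),
                 alpha = c(per_cat[cats], alpha_of(totals)))
}

#' Label surgeons as good or poor performers
#'
#' Applies the rubric cutoff to the total score: `total >= cutoff` is
#' labelled good, otherwise poor. The study cohort was bimodal around
#' the default cutoff of 35 points, so no surgeon sat on the boundary;
#' the boundary itself is defined here as good.
#'
#' @param scores A `surgeon_scores` tibble from [average_scores()] (any
#'   tibble with `surgeon` and `total` works).
#' @param cutoff Total-score cutoff (default 35).
#' @return `scores` with a `label` column (`"good"`/`"poor"`).
#' @export
label_good_poor <- function(scores, cutoff = 35) {
  if (any(!is.finite(scores$total)))
    stop("totals must be finite", call. = FALSE)
  scores$label <- ifelse(scores$total >= cutoff, "good", "poor")
  scores
}
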