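#' Compute all assessment parameters for one trial
#'
#' Evaluates the five parameters (CV-VA, Max-dVA, No. of TDE for the
#' vessel series; PD and NJI per hand) over each phase A-D and over the
#' whole trial ("All"). Delta-VA is computed once on the whole-trial
#' series (so the deformation threshold has the same meaning in every
#' phase) and then windowed; CV-VA and the kinematic metrics are
#' computed on the phase slice itself, so per-phase NJI uses phase-local
#' duration and path distance. Cells whose inputs are degenerate (e.g. a
#' hand with no valid detections inside a phase) are returned as `NA`
#' rather than dropped.
#'
#' @param track_right,track_left [tip_track()]s for the two hands.
#' @param va [va_series()] for the trial.
#' @param phases [phase_annotation()] covering the trial.
#' @param tde_threshold Threshold on `|dva|` defining a deformation error.
#' @param tde_mode `"excursion"` or `"per_sample"` counting.
#' @param smoothing_window,polyorder Passed to [segment_and_smooth()].
#' @param normalization Passed to [relative_delta_va()].
#' @return Long tibble with columns `trial`, `metric`, `hand`, `phase`,
#'   `value`.
#' @export
trial_parameters <- function(track_right, track_left, va, phases,
                             tde_threshold = 1.13,
                             tde_mode = c("excursion", "per_sample"),
                             smoothing_window = 7, polyorder = 2,
                             normalization = "trial_mean") {
  tde_mode <- match.arg(tde_mode)
  trial <- attr(va, "trial_id")
  quiet <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  dva_full <- quiet(relative_delta_va(va, normalization))
  tracks <- list(right = track_right, left = track_left)
  rows <- list()
  for (ph in phase_levels(include_all = TRUE)) {
    va_ph <- quiet(slice_by_phase(va, phases, ph))
    dva_ph <- if (inherits(dva_full, "dva_series"))
      quiet(slice_by_phase(dva_full, phases, ph)) else NA
    tde <- if (inherits(dva_ph, "dva_series"))
      quiet(detect_tde(dva_ph, tde_threshold, tde_mode)$count) else NA_real_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      trial = trial,
      metric = c("cv_va", "max_dva", "n_tde"),
      hand = NA_character_,
      phase = ph,
      value = c(
        if (inherits(va_ph, "va_series")) quiet(cv_va(va_ph)) else NA_real_,
        if (inherits(dva_ph, "dva_series"))
          quiet(max_abs_delta_va(dva_ph)) else NA_real_,
        as.numeric(tde)))
    for (h in c("right", "left")) {
      kin <- quiet(segment_and_smooth(
        slice_by_phase(tracks[[h]], phases, ph),
        window = smoothing_window, polyorder = polyorder))
      # PD on the boundary-extended slice: the step that begins in this
      # phase and lands on the next phase's first frame is counted here
      # (and only here), making per-phase PD sum to the whole-trial PD.
      kin_pd <- quiet(segment_and_smooth(
        slice_by_phase(tracks[[h]], phases, ph, include_boundary = TRUE),
        window = 1, polyorder = 0))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial = trial, metric = c("pd", "nji"), hand = h, phase = ph,
        value = c(
          # a phase with no valid detections of its own is missing, even
          # if the boundary frame from the next phase is detectable
          if (inherits(kin, "kinematic_series") &&
                inherits(kin_pd, "kinematic_series"))
            quiet(path_distance(kin_pd)) else NA_real_,
          if (inherits(kin, "kinematic_series"))
            quiet(normalized_jerk_index(kin)) else NA_real_))
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract parameters for every trial of a cohort
#'
#' @param dataset A cohort dataset as produced by [generate_cohort()] or
#'   [read_cohort()]: a list with `tracks` (named `"<trial>/<hand>"`),
#'   `va` (named by trial), `phases`, and `trials` (tibble with columns
#'   `trial`, `surgeon`, `trial_index`).
#' @param ... Passed to [trial_parameters()].
#' @return Long tibble of per-trial parameters with `surgeon` and
#'   `trial_index` attached.
#' @export
extract_cohort_parameters <- function(dataset, ...) {
  params <- purrr::pmap(dataset$trials, function(trial, surgeon, trial_index) {
    p <- trial_parameters(dataset$tracks[[paste0(trial, "/right")]],
                          dataset$tracks[[paste0(trial, "/left")]],
                          dataset$va[[trial]],
                          dataset$phases, ...)
    p$surgeon <- surgeon
    p$trial_index <- trial_index
    p
  })
  dplyr::bind_rows(params)
}

#' Aggregate per-trial parameters into a surgeon-level cohort table
#'
#' The representative value of each parameter for each surgeon is the
#' arithmetic mean of the first `trials_per_surgeon` trials (by
#' `trial_index`; later trials are ignored to avoid learning effects). A
#' cell is `NA` when any contributing trial is missing that parameter;
#' downstream statistics drop such pairs listwise.
#'
#' @param params Long tibble from [extract_cohort_parameters()] (columns
#'   `surgeon`, `trial_index`, `metric`, `hand`, `phase`, `value`).
#' @param trials_per_surgeon Number of leading trials averaged (default 2).
#' @return A tibble of class `cohort_table` with columns `surgeon`,
#'   `metric`, `hand`, `phase`, `value`, ordered deterministically.
#' @export
build_cohort_table <- function(params, trials_per_surgeon = 2) {
  counts <- dplyr::summarise(dplyr::group_by(params, .data$surgeon),
                             n = dplyr::n_distinct(.data$trial_index))
  short <- counts$surgeon[counts$n < trials_per_surgeon]
  if (length(short))
    stop("surgeon(s) with fewer than ", trials_per_surgeon, " trials: ",
         paste(short, collapse = ", "), call. = FALSE)
  first_trials <- dplyr::ungroup(dplyr::slice_min(
    dplyr::group_by(dplyr::distinct(params, .data$surgeon, .data$trial_index),
                    .data$surgeon),
    .data$trial_index, n = trials_per_surgeon))
  kept <- dplyr::semi_join(params, first_trials,
                           by = c("surgeon", "trial_index"))
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$surgeon, .data$metric, .data$hand,
                    .data$phase),
    value = if (dplyr::n() != trials_per_surgeon || anyNA(.data$value))
      NA_real_ else mean(.data$value),
    .groups = "drop")
  out <- dplyr::arrange(out, .data$surgeon, .data$metric, .data$hand,
                        .data$phase)
  class(out) <- unique(c("cohort_table", class(out)))
  out
}

#' Extract a surgeon-by-feature matrix from a cohort table
#'
#' @param cohort A `cohort_table` from [build_cohort_table()].
#' @param features Tibble with columns `metric`, `hand`, `phase`
#'   selecting the feature cells.
#' @return Numeric matrix, one row per surgeon (rownames), one column per
#'   feature (labelled `"<parameter>/<phase>"`).
#' @export
cohort_matrix <- function(cohort, features) {
  cols <- purrr::pmap(features, function(metric, hand, phase, ...) {
    cell <- cohort[cohort$metric == metric & cohort$phase == phase &
                     (is.na(hand) & is.na(cohort$hand) |
                        !is.na(hand) & !is.na(cohort$hand) &
                        cohort$hand == hand), , drop = FALSE]
    if (nrow(cell) == 0L)
      stop(sprintf("feature %s/%s absent from cohort table",
                   param_label(metric, hand), phase), call. = FALSE)
    setNames(cell$value, cell$surgeon)
  })
  surgeons <- sort(unique(cohort$surgeon))
  mat <- vapply(cols, function(v) v[surgeons], numeric(length(surgeons)))
  rownames(mat) <- surgeons
  colnames(mat) <- paste0(param_label(features$metric, features$hand), "/",
                          features$phase)
  mat
}
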