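#' @importFrom rlang .data
#' @importFrom stats sd var median rnorm runif rpois rlnorm qnorm pt setNames
#' @importFrom utils head tail
NULL

#' Nine technical categories of the criteria-based rating scale
#'
#' Category identifiers, in the fixed order used throughout the package:
#' instrument handling, respect for tissue, efficiency, suture handling,
#' suturing technique, quality of knot, final product, operation flow and
#' overall performance. Each is rated 1-5 by each rater.
#'
#' @return Character vector of length 9.
#' @export
rubric_categories <- function() {
  c("instrument_handling", "respect_for_tissue", "efficiency",
    "suture_handling", "suturing_technique", "quality_of_knot",
    "final_product", "operation_flow", "overall_performance")
}

# Phase labels in temporal order; "All" denotes the whole-trial window.
phase_levels <- function(include_all = FALSE) {
  if (include_all) c("A", "B", "C", "D", "All") else c("A", "B", "C", "D")
}

#' Construct an instrument tip track
#'
#' A tip track holds the per-frame 2D position of one instrument tip
#' (right or left hand) in one trial, with a validity flag that is FALSE
#' whenever the tool was outside the field of view and no detection
#' exists. Coordinates are pixels with origin at the top-left; frames are
#' 0-based and time is `frame / fps`.
#'
#' @param frame Integer vector of 0-based frame indices, strictly increasing.
#' @param x,y Numeric pixel coordinates; must be finite wherever `valid`.
#' @param valid Logical vector; FALSE marks detection gaps.
#' @param trial_id Trial identifier.
#' @param hand `"right"` or `"left"`.
#' @param fps Frames per second (> 0).
#' @return A tibble of class `tip_track` with columns `frame`, `time_s`,
#'   `x`, `y`, `valid` and attributes `trial_id`, `hand`, `fps`.
#' @export
tip_track <- function(frame, x, y, valid = rep(TRUE, length(frame)),
                      trial_id = "trial", hand = c("right", "left"),
                      fps = 30) {
  hand <- match.arg(hand)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  frame <- as.integer(frame)
  if (length(frame) == 0L)
    stop("tip track must contain at least one frame", call. = FALSE)
  if (any(diff(frame) <= 0L))
    stop(sprintf("frame indices must be strictly increasing (trial %s, %s hand)",
                 trial_id, hand), call. = FALSE)
  valid <- as.logical(valid)
  if (any(valid & (!is.finite(x) | !is.finite(y))))
    stop(sprintf("non-finite coordinates on valid frames (trial %s, %s hand)",
                 trial_id, hand), call. = FALSE)
  out <- tibble::tibble(frame = frame, time_s = frame / fps,
                        x = as.numeric(x), y = as.numeric(y), valid = valid)
  structure(out, trial_id = trial_id, hand = hand, fps = fps,
            class = c("tip_track", class(out)))
}

#' Construct a vessel-area series
#'
#' Per-frame pixel count of the segmented vessel region (VA) for one
#' trial. Frames are 0-based and strictly increasing.
#'
#' @param frame Integer vector of 0-based frame indices.
#' @param va Non-negative numeric pixel counts.
#' @param trial_id Trial identifier.
#' @param fps Frames per second (> 0).
#' @return A tibble of class `va_series` with columns `frame`, `va` and
#'   attributes `trial_id`, `fps`.
#' @export
va_series <- function(frame, va, trial_id = "trial", fps = 30) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  frame <- as.integer(frame)
  if (length(frame) == 0L)
    stop("vessel-area series is empty", call. = FALSE)
  if (any(diff(frame) <= 0L))
    stop(sprintf("frame indices must be strictly increasing (trial %s)",
                 trial_id), call. = FALSE)
  va <- as.numeric(va)
  if (any(!is.finite(va)) || any(va < 0))
    stop(sprintf("vessel areas must be finite and non-negative (trial %s)",
                 trial_id), call. = FALSE)
  out <- tibble::tibble(frame = frame, va = va)
  structure(out, trial_id = trial_id, fps = fps,
            class = c("va_series", class(out)))
}

# Internal constructor for a delta-VA series (one sample per forward
# difference of the parent VA series; sample f spans frames [f, f+1)).
new_dva_series <- function(frame, dva, trial_id, fps) {
  out <- tibble::tibble(frame = as.integer(frame), dva = as.numeric(dva))
  structure(out, trial_id = trial_id, fps = fps,
            class = c("dva_series", class(out)))
}

#' Construct phase annotations
#'
#' Half-open frame intervals `[start_frame, end_frame)` labelling the four
#' phases of the suturing task: A (grasping and inserting the needle),
#' B (pushing and extracting the needle), C (pulling the threads to the
#' first knot), D (tying three knots and cutting the threads). Within a
#' trial, intervals of distinct phases must not overlap and must appear in
#' A -> D temporal order.
#'
#' @param trial Trial identifier per row.
#' @param phase Character vector with values in `A`-`D`.
#' @param start_frame,end_frame Integer frame bounds, `start < end`.
#' @return A tibble of class `phase_annotation`.
#' @export
phase_annotation <- function(trial, phase, start_frame, end_frame) {
  out <- tibble::tibble(trial = as.character(trial),
                        phase = as.character(phase),
                        start_frame = as.integer(start_frame),
                        end_frame = as.integer(end_frame))
  validate_phase_annotation(out)
}

validate_phase_annotation <- function(ann) {
  bad <- setdiff(unique(ann$phase), phase_levels())
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(ann$start_frame >= ann$end_frame))
    stop("phase intervals must satisfy start_frame < end_frame", call. = FALSE)
  for (tr in unique(ann$trial)) {
    a <- ann[ann$trial == tr, , drop = FALSE]
    if (anyDuplicated(a$phase))
      stop(sprintf("duplicated phase annotation in trial %s", tr), call. = FALSE)
    a <- a[order(a$start_frame), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start_frame[-1L] < a$end_frame[-nrow(a)]))
      stop(sprintf("overlapping phase intervals in trial %s", tr), call. = FALSE)
    if (is.unsorted(match(a$phase, phase_levels())))
      stop(sprintf("phases must occur in A->D order in trial %s", tr),
           call. = FALSE)
  }
  class(ann) <- unique(c("phase_annotation", class(ann)))
  ann
}

# Display label for a parameter cell, e.g. "Rt-PD", "No. of TDE", "CV-VA".
param_label <- function(metric, hand = NA_character_) {
  base <- c(cv_va = "CV-VA", max_dva = "Max-dVA", n_tde = "No. of TDE",
            pd = "PD", nji = "NJI")[metric]
  prefix <- ifelse(is.na(hand), "",
                   ifelse(hand == "right", "Rt-",
                          ifelse(hand == "left", "Lt-", "")))
  paste0(prefix, base)
}

# Inverse of param_label(): returns list(metric, hand).
parse_param_label <- function(label) {
  map <- c("CV-VA" = "cv_va", "Max-dVA" = "max_dva", "No. of TDE" = "n_tde",
           "Rt-PD" = "pd", "Lt-PD" = "pd", "Rt-NJI" = "nji", "Lt-NJI" = "nji")
  if (any(is.na(map[label])))
    stop("unknown parameter label(s): ",
         paste(unique(label[is.na(map[label])]), collapse = ", "), call. = FALSE)
  hand <- rep(NA_character_, length(label))
  hand[startsWith(label, "Rt-")] <- "right"
  hand[startsWith(label, "Lt-")] <- "left"
  list(metric = unname(map[label]), hand = hand)
}
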