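#' Relative vessel-area change per second (delta-VA)
#'
#' Normalizes the VA series (by default to its within-trial mean) and
#' takes forward differences scaled to per-second units:
#' `dva[f] = (va_norm[f+1] - va_norm[f]) / dt`. The result is
#' dimensionless per second, which puts an order-1 tissue-deformation
#' threshold on a meaningful scale regardless of image resolution.
#'
#' @param series A [va_series()] with at least 2 frames.
#' @param normalization `"trial_mean"` (default), `"first_frame"`, or
#'   `"none"` (raw pixel change per second).
#' @return A `dva_series` tibble with columns `frame` (the left frame of
#'   each forward difference) and `dva`; length is one less than the
#'   input.
#' @export
relative_delta_va <- function(series,
                              normalization = c("trial_mean", "first_frame",
                                                "none")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(series, "va_series"))
  if (nrow(series) < 2L)
    stop("delta-VA requires at least 2 frames", call. = FALSE)
  fps <- attr(series, "fps")
  denom <- switch(normalization,
                  trial_mean = mean(series$va),
                  first_frame = series$va[1L],
                  none = 1)
  if (normalization != "none" && denom <= 0)
    stop("vessel-area normalization constant is zero", call. = FALSE)
  va_norm <- series$va / denom
  dt <- diff(series$frame) / fps
  new_dva_series(head(series$frame, -1L), diff(va_norm) / dt,
                 trial_id = attr(series, "trial_id"), fps = fps)
}

#' Coefficient of variation of vessel area (CV-VA)
#'
#' Sample standard deviation (n-1 denominator) of the VA series divided
#' by its mean; scale-invariant by construction.
#'
#' @param series A [va_series()] with at least 2 frames and positive mean.
#' @return Dimensionless non-negative scalar.
#' @export
cv_va <- function(series) {
  stopifnot(inherits(series, "va_series"))
  if (nrow(series) < 2L)
    stop("CV-VA requires at least 2 frames", call. = FALSE)
  m <- mean(series$va)
  if (m <= 0) stop("CV-VA undefined for zero-mean series", call. = FALSE)
  sd(series$va) / m
}

#' Maximum absolute delta-VA
#'
#' @param dva A `dva_series` from [relative_delta_va()].
#' @return The largest `|dva|` over the series (>= 0).
#' @export
max_abs_delta_va <- function(dva) {
  stopifnot(inherits(dva, "dva_series"))
  if (nrow(dva) == 0L)
    stop("empty delta-VA series", call. = FALSE)
  max(abs(dva$dva))
}

#' Detect tissue-deformation errors (TDE)
#'
#' A TDE is an excursion of delta-VA beyond the cohort threshold
#' (default 1.13, the published mean +/- 1.96 SD bound). In `excursion`
#' mode each maximal run of consecutive samples with `|dva| > threshold`
#' and common sign counts once; in `per_sample` mode every exceeding
#' sample counts. Samples exactly at the threshold never trigger.
#'
#' @param dva A `dva_series`.
#' @param threshold Positive threshold on `|dva|`.
#' @param counting_mode `"excursion"` (default) or `"per_sample"`.
#' @return A list with `count` (integer) and `events`, a tibble with one
#'   row per excursion: `start_frame`, `end_frame` (half-open, in parent
#'   frame indices), `peak_dva` and `sign`.
#' @export
detect_tde <- function(dva, threshold = 1.13,
                       counting_mode = c("excursion", "per_sample")) {
  counting_mode <- match.arg(counting_mode)
  stopifnot(inherits(dva, "dva_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  x <- dva$dva
  state <- ifelse(abs(x) > threshold, sign(x), 0)
  events <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                           peak_dva = numeric(), sign = character())
  if (length(x) && any(state != 0)) {
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    events <- tibble::tibble(
      start_frame = dva$frame[starts[keep]],
      end_frame = dva$frame[ends[keep]] + 1L,
      peak_dva = mapply(function(a, b) x[a:b][which.max(abs(x[a:b]))],
                        starts[keep], ends[keep]),
      sign = ifelse(r$values[keep] > 0, "positive", "negative"))
  }
  count <- if (counting_mode == "excursion") nrow(events)
           else sum(abs(x) > threshold)
  list(count = as.integer(count), events = events)
}

#' Cohort-level tissue-deformation threshold
#'
#' Pools delta-VA samples across all trials by all surgeons and returns
#' the mean +/- 1.96 SD bound as a single positive magnitude,
#' `max(|m - 1.96 s|, |m + 1.96 s|)` with the sample SD. Used to refresh
#' the TDE threshold on a new cohort; the published cohort yielded 1.13.
#'
#' @param all_dva A list of `dva_series` (or a bare numeric vector of
#'   pooled samples).
#' @return Positive scalar threshold.
#' @export
cohort_tde_threshold <- function(all_dva) {
  pooled <- if (is.numeric(all_dva)) all_dva
            else unlist(lapply(all_dva, function(d) d$dva), use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) < 2L)
    stop("need at least 2 pooled delta-VA samples", call. = FALSE)
  m <- mean(pooled)
  s <- sd(pooled)
  max(abs(m - 1.96 * s), abs(m + 1.96 * s))
}
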