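#' Restrict a series or track to one surgical phase
#'
#' Slices an object to the half-open frame window `[start, end)` of the
#' requested phase (or, for `"All"`, to the union of the annotated phase
#' windows). Frame indices are re-anchored to start at 0 and validity
#' flags are preserved.
#'
#' For a `dva_series`, sample `f` represents the forward difference over
#' frames `[f, f+1)` and is assigned to the phase containing `f`; the
#' difference that spans a phase join belongs to no single phase (it is
#' only seen by whole-trial windows).
#'
#' @param x A [tip_track()], [va_series()] or `dva_series`.
#' @param annotations A [phase_annotation()] tibble covering `x`'s trial.
#' @param phase One of `"A"`, `"B"`, `"C"`, `"D"`, `"All"`.
#' @param include_boundary If TRUE, additionally include the first frame
#'   of the following window, so that steps beginning inside the phase
#'   are fully represented. Used for additive metrics (path distance);
#'   leave FALSE for everything else.
#' @return An object of the same class, restricted and re-anchored.
#' @export
slice_by_phase <- function(x, annotations, phase, include_boundary = FALSE) {
  UseMethod("slice_by_phase")
}

phase_window <- function(x, annotations, phase) {
  trial <- attr(x, "trial_id")
  ann <- annotations
  if (!is.null(trial) && trial %in% ann$trial)
    ann <- ann[ann$trial == trial, , drop = FALSE]
  if (identical(phase, "All"))
    return(c(min(ann$start_frame), max(ann$end_frame)))
  row <- ann[ann$phase == phase, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("phase %s is not annotated for trial %s", phase,
                 trial %||% "?"), call. = FALSE)
  c(row$start_frame, row$end_frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
slice_by_phase.tip_track <- function(x, annotations, phase,
                                     include_boundary = FALSE) {
  w <- phase_window(x, annotations, phase)
  end <- w[2L] + as.integer(include_boundary)
  keep <- x$frame >= w[1L] & x$frame < end
  if (!any(keep))
    stop(sprintf("phase %s window contains no frames", phase), call. = FALSE)
  tip_track(x$frame[keep] - w[1L], x$x[keep], x$y[keep], x$valid[keep],
            trial_id = attr(x, "trial_id"), hand = attr(x, "hand"),
            fps = attr(x, "fps"))
}

#' @export
slice_by_phase.va_series <- function(x, annotations, phase,
                                     include_boundary = FALSE) {
  w <- phase_window(x, annotations, phase)
  end <- w[2L] + as.integer(include_boundary)
  keep <- x$frame >= w[1L] & x$frame < end
  if (!any(keep))
    stop(sprintf("phase %s window contains no frames", phase), call. = FALSE)
  va_series(x$frame[keep] - w[1L], x$va[keep],
            trial_id = attr(x, "trial_id"), fps = attr(x, "fps"))
}

#' @export
slice_by_phase.dva_series <- function(x, annotations, phase,
                                      include_boundary = FALSE) {
  w <- phase_window(x, annotations, phase)
  # sample f spans [f, f+1); the last in-phase sample starts at end-2
  end <- w[2L] - 1L + as.integer(include_boundary)
  keep <- x$frame >= w[1L] & x$frame < end
  new_dva_series(x$frame[keep] - w[1L], x$dva[keep],
                 trial_id = attr(x, "trial_id"), fps = attr(x, "fps"))
}
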