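#' Read instrument tip tracks from CSV
#'
#' Expects a header with columns `trial`, `hand`, `frame`, `x`, `y`,
#' `valid`. Rows with `valid = 0` are retained with the validity flag
#' cleared, so detection gaps stay visible to the kinematic chain.
#'
#' @param path CSV file path.
#' @param fps Frames per second used to derive `time_s`.
#' @return A list of [tip_track()] objects, one per `(trial, hand)` pair,
#'   named `"<trial>/<hand>"`.
#' @export
read_tip_track <- function(path, fps = 30) {
  df <- read_csv_checked(path, c("trial", "hand", "frame", "x", "y", "valid"))
  bad_hand <- setdiff(unique(df$hand), c("right", "left"))
  if (length(bad_hand))
    stop("hand must be 'right' or 'left'; found: ",
         paste(bad_hand, collapse = ", "), call. = FALSE)
  groups <- split(df, paste(df$trial, df$hand, sep = "/"))
  out <- lapply(groups, function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    if (anyDuplicated(g$frame))
      stop(sprintf("duplicate frame index in trial %s, %s hand",
                   g$trial[1], g$hand[1]), call. = FALSE)
    tip_track(g$frame, g$x, g$y, valid = g$valid != 0,
              trial_id = as.character(g$trial[1]), hand = g$hand[1], fps = fps)
  })
  out[order(names(out))]
}

#' Read a vessel-area series from a directory of label masks
#'
#' Reads single-channel label images (PNG) named with zero-padded frame
#' numbers and counts, per frame, the pixels equal to `vessel_label`.
#' All frames must share the same dimensions.
#'
#' @param dir Directory containing the per-frame masks.
#' @param vessel_label Integer pixel value encoding the vessel class.
#' @param fps Frames per second.
#' @param trial_id Trial identifier attached to the series.
#' @return A [va_series()].
#' @export
read_vessel_masks <- function(dir, vessel_label = 1L, fps = 30,
                              trial_id = basename(dir)) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no PNG masks found in ", dir, call. = FALSE)
  nums <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
  if (any(is.na(nums)))
    stop("mask filenames must contain a frame number", call. = FALSE)
  files <- files[order(nums)]
  nums <- sort(nums)
  dims <- NULL
  va <- vapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # grey PNGs may carry alpha
    if (is.null(dims)) dims <<- dim(img)
    else if (!identical(dim(img), dims))
      stop("inconsistent mask dimensions: ", basename(f), call. = FALSE)
    sum(round(img * 255) == vessel_label)
  }, numeric(1))
  va_series(nums, va, trial_id = trial_id, fps = fps)
}

#' Read pre-extracted vessel-area series from CSV
#'
#' Alternative input for when masks have already been reduced to
#' per-frame pixel counts. Columns: `trial`, `frame`, `va`.
#'
#' @param path CSV file path.
#' @param fps Frames per second.
#' @return A named list of [va_series()], one per trial.
#' @export
read_va_csv <- function(path, fps = 30) {
  df <- read_csv_checked(path, c("trial", "frame", "va"))
  if (any(df$va < 0))
    stop("vessel areas must be non-negative", call. = FALSE)
  out <- lapply(split(df, df$trial), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    va_series(g$frame, g$va, trial_id = as.character(g$trial[1]), fps = fps)
  })
  out[order(names(out))]
}

#' Write vessel-area series to CSV
#'
#' @param series A [va_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_va_csv <- function(series, path) {
  if (inherits(series, "va_series")) series <- list(series)
  df <- dplyr::bind_rows(lapply(series, function(s)
    tibble::tibble(trial = attr(s, "trial_id"), frame = s$frame, va = s$va)))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read phase annotations from CSV
#'
#' Columns: `trial`, `phase` (A-D), `start_frame` (inclusive),
#' `end_frame` (exclusive). Overlapping or out-of-order intervals are
#' rejected.
#'
#' @param path CSV file path.
#' @return A [phase_annotation()] tibble.
#' @export
read_phase_csv <- function(path) {
  df <- read_csv_checked(path, c("trial", "phase", "start_frame", "end_frame"))
  phase_annotation(df$trial, df$phase, df$start_frame, df$end_frame)
}

#' Write phase annotations to CSV
#' @param ann A [phase_annotation()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_csv <- function(ann, path) {
  readr::write_csv(tibble::as_tibble(ann)[c("trial", "phase", "start_frame",
                                            "end_frame")], path)
  invisible(path)
}

#' Read rubric score records from CSV
#'
#' One row per (surgeon, trial, rater) with the nine category columns of
#' [rubric_categories()], each scored 1-5.
#'
#' @param path CSV file path.
#' @return A tibble with columns `surgeon`, `trial`, `rater` and the nine
#'   category columns.
#' @export
read_rubric_csv <- function(path) {
  df <- read_csv_checked(path, c("surgeon", "trial", "rater",
                                 rubric_categories()))
  validate_rubric(df)
}

validate_rubric <- function(df) {
  sc <- as.matrix(df[rubric_categories()])
  if (any(!is.finite(sc)) || any(sc < 1 | sc > 5) || any(sc != round(sc)))
    stop("rubric scores must be integers in [1, 5]", call. = FALSE)
  df$surgeon <- as.character(df$surgeon)
  df$rater <- as.character(df$rater)
  df
}

#' Write rubric score records to CSV
#' @param records Rubric tibble as returned by [read_rubric_csv()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rubric_csv <- function(records, path) {
  readr::write_csv(records[c("surgeon", "trial", "rater", rubric_categories())],
                   path)
  invisible(path)
}

#' Write a tidy per-trial or per-surgeon parameter table
#'
#' Long format with one row per (surgeon, trial, parameter, phase) cell;
#' the parameter column carries display labels such as `Rt-PD` or
#' `No. of TDE`.
#'
#' @param table Long tibble with columns `metric`, `hand`, `phase`,
#'   `value` and any of `surgeon`, `trial`, `trial_index`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path) {
  keep <- intersect(c("surgeon", "trial", "trial_index"), names(table))
  out <- tibble::tibble(table[keep],
                        parameter = param_label(table$metric, table$hand),
                        phase = table$phase, value = table$value)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a tidy parameter table written by [write_parameter_table()]
#' @param path CSV file path.
#' @return Long tibble with `metric` and `hand` recovered from the labels.
#' @export
read_parameter_table <- function(path) {
  df <- read_csv_checked(path, c("parameter", "phase", "value"))
  mh <- parse_param_label(df$parameter)
  df$metric <- mh$metric
  df$hand <- mh$hand
  df$parameter <- NULL
  if ("surgeon" %in% names(df)) df$surgeon <- as.character(df$surgeon)
  tibble::as_tibble(df)
}

# Shared CSV reader: checks required columns, rejects empty files.
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L) stop("empty input file: ", path, call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
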