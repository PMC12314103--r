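#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the pipeline targets: 14
#' surgeons, two scored trials each, a bimodal latent-skill distribution
#' (an experienced cluster and a novice cluster), four-phase trials at
#' 30 fps, and three raters on the nine-category 1-5 scale. Degradation
#' channels (trajectory jerk noise, extra detour submovements,
#' vessel-deformation events, slower execution) all scale with
#' `1 - skill`.
#'
#' @param n_surgeons Number of surgeons (default 14).
#' @param trials_per_surgeon Trials generated per surgeon (default 2).
#' @param fps Frames per second (default 30).
#' @param skill Optional numeric vector of per-surgeon latent skills in
#'   \[0, 1\]; by default half the cohort is drawn around 0.8 and half
#'   around 0.3 (SD 0.07, clipped), giving a bimodal rubric-total
#'   distribution with both labels present at the 35-point cutoff.
#' @param phase_durations_s Mean duration in seconds of phases A-D at
#'   skill 1; defaults c(A=10, B=15, C=15, D=30) for a single stitch.
#' @param time_dilation Relative slow-down of a skill-0 surgeon
#'   (default 0.8, i.e. 80% longer phases).
#' @param jerk_noise_scale Per-frame jerk-level tremor noise SD in
#'   px/s^3 at skill 0 (default 2000, which after triple integration and
#'   drift removal injects roughly 1.5 px of tremor-band positional
#'   noise at 30 fps).
#' @param detour_rate Mean number of extra detour submovements per phase
#'   at skill 0 (default 8).
#' @param tde_rate Mean number of vessel-deformation events per trial at
#'   skill 0 (default 6).
#' @param tde_amplitude Relative vessel-area excursion amplitude
#'   (default 0.3).
#' @param va_baseline_px Baseline vessel area in pixels (default 20000).
#' @param rater_sd Rubric rater noise SD on the 1-5 scale (default 0.5).
#' @param jitter_px Detection jitter SD in pixels added to every frame
#'   (default 0.3).
#' @param gap_rate Mean number of out-of-view validity gaps per hand per
#'   trial (default 1.5; each lasts 0.2-0.8 s).
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_surgeons = 14, trials_per_surgeon = 2,
                             fps = 30, skill = NULL,
                             phase_durations_s = c(A = 10, B = 15, C = 15,
                                                   D = 30),
                             time_dilation = 0.8,
                             jerk_noise_scale = 2000, detour_rate = 8,
                             tde_rate = 6, tde_amplitude = 0.3,
                             va_baseline_px = 20000, rater_sd = 0.5,
                             jitter_px = 0.3, gap_rate = 1.5, seed = 1) {
  cfg <- list(n_surgeons = n_surgeons, trials_per_surgeon = trials_per_surgeon,
              fps = fps, skill = skill,
              phase_durations_s = phase_durations_s,
              time_dilation = time_dilation,
              jerk_noise_scale = jerk_noise_scale, detour_rate = detour_rate,
              tde_rate = tde_rate, tde_amplitude = tde_amplitude,
              va_baseline_px = va_baseline_px, rater_sd = rater_sd,
              jitter_px = jitter_px, gap_rate = gap_rate, seed = seed)
  rates <- c(cfg$jerk_noise_scale, cfg$detour_rate, cfg$tde_rate,
             cfg$tde_amplitude, cfg$rater_sd, cfg$jitter_px, cfg$gap_rate)
  if (any(rates < 0) || cfg$fps <= 0 || any(cfg$phase_durations_s <= 0))
    stop("rates and scales must be non-negative; fps and durations positive",
         call. = FALSE)
  if (!is.null(skill) && (any(skill < 0 | skill > 1) ||
                          length(skill) != n_surgeons))
    stop("`skill` must have one value in [0, 1] per surgeon", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Sample a minimum-jerk reaching segment
#'
#' Straight-line reach with the minimum-jerk displacement profile
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`, which has zero velocity and
#' acceleration at both endpoints and a normalized jerk index of exactly
#' 360 in the sampling-density limit.
#'
#' @param p0,p1 Numeric length-2 start and end positions (px).
#' @param duration_s Movement duration in seconds (> 0).
#' @param fps Sampling rate.
#' @return Tibble with columns `time_s`, `x`, `y`.
#' @export
min_jerk_segment <- function(p0, p1, duration_s, fps) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  if (all(p0 == p1))
    stop("zero-length reach: start and end coincide", call. = FALSE)
  n <- max(2L, round(duration_s * fps))
  tau <- seq(0, 1, length.out = n)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  tibble::tibble(time_s = tau * duration_s,
                 x = p0[1] + (p1[1] - p0[1]) * s,
                 y = p0[2] + (p1[2] - p0[2]) * s)
}

min_jerk_profile <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Remove a quadratic trend from v in blocks of `block` samples, so
# triple-integrated jerk noise keeps its jerk content but cannot walk
# the trajectory away (integration constants up to acceleration are
# re-zeroed every block).
block_detrend <- function(v, block = 30L) {
  n <- length(v)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1L, n)
    if (length(idx) >= 3L) {
      tt <- seq_along(idx)
      fit <- stats::lm.fit(cbind(1, tt, tt^2), v[idx])
      v[idx] <- fit$residuals
    } else v[idx] <- 0
  }
  v
}

# One hand's trajectory for one trial: a chain of minimum-jerk
# submovements between waypoints, plus skill-scaled jerk noise,
# detection jitter and out-of-view gaps.
synth_hand_track <- function(skill, n_frames_per_phase, cfg, hand, trial_id) {
  fps <- cfg$fps
  dt <- 1 / fps
  centre <- if (hand == "right") c(400, 250) else c(320, 230)
  radius <- if (hand == "right") 70 else 45
  pos <- NULL
  cur <- centre + runif(2, -radius, radius)
  xs <- ys <- numeric(0)
  for (Fp in n_frames_per_phase) {
    k <- 6L + rpois(1, cfg$detour_rate * (1 - skill))
    wp <- cbind(centre[1] + runif(k, -radius, radius),
                centre[2] + runif(k, -radius, radius))
    lens <- as.vector(stats::rmultinom(1, Fp - 1L, rep(1, k) / k))
    px <- py <- numeric(Fp)
    px[1] <- cur[1]; py[1] <- cur[2]
    at <- 1L
    for (i in seq_len(k)) {
      if (lens[i] == 0L) next
      tau <- seq_len(lens[i]) / lens[i]
      s <- min_jerk_profile(tau)
      px[at + seq_len(lens[i])] <- cur[1] + (wp[i, 1] - cur[1]) * s
      py[at + seq_len(lens[i])] <- cur[2] + (wp[i, 2] - cur[2]) * s
      at <- at + lens[i]
      cur <- wp[i, ]
    }
    xs <- c(xs, px); ys <- c(ys, py)
  }
  n <- length(xs)
  jn <- cfg$jerk_noise_scale * (1 - skill)
  if (jn > 0) {
    xs <- xs + block_detrend(cumsum(cumsum(cumsum(rnorm(n, 0, jn)))) * dt^3)
    ys <- ys + block_detrend(cumsum(cumsum(cumsum(rnorm(n, 0, jn)))) * dt^3)
  }
  if (cfg$jitter_px > 0) {
    xs <- xs + rnorm(n, 0, cfg$jitter_px)
    ys <- ys + rnorm(n, 0, cfg$jitter_px)
  }
  valid <- rep(TRUE, n)
  for (g in seq_len(rpois(1, cfg$gap_rate))) {
    len <- round(runif(1, 0.2, 0.8) * fps)
    start <- sample.int(max(1L, n - len), 1L)
    valid[start:min(n, start + len - 1L)] <- FALSE
  }
  if (!any(valid)) valid[1] <- TRUE
  tip_track(seq_len(n) - 1L, xs, ys, valid, trial_id = trial_id,
            hand = hand, fps = fps)
}

# Vessel-area series for one trial: baseline with slow drift and mild
# segmentation noise, plus skill-scaled deformation events (a sharp
# area drop over ~0.1 s followed by a slow exponential recovery), placed
# preferentially in phases B and C.
synth_va_series <- function(skill, phases, cfg, trial_id) {
  fps <- cfg$fps
  n <- max(phases$end_frame)
  t <- (seq_len(n) - 1L) / fps
  drift <- 0.02 * sin(2 * pi * t / 47 + runif(1, 0, 2 * pi)) +
    0.015 * sin(2 * pi * t / 23 + runif(1, 0, 2 * pi))
  rel <- 1 + drift + rnorm(n, 0, 0.002)
  n_ev <- rpois(1, cfg$tde_rate * (1 - skill))
  bump <- numeric(n)
  if (n_ev > 0) {
    probs <- c(A = 0.10, B = 0.35, C = 0.45, D = 0.10)[phases$phase]
    for (e in seq_len(n_ev)) {
      ph <- phases[sample.int(nrow(phases), 1L, prob = probs), ]
      margin <- round(2 * fps)
      lo <- ph$start_frame + 1L
      hi <- max(lo, ph$end_frame - margin)
      f0 <- sample(lo:hi, 1L)
      amp <- cfg$tde_amplitude * runif(1, 0.7, 1.3)
      drop_len <- max(2L, round(0.1 * fps))
      rec_len <- round(2 * fps)
      idx_d <- f0:min(n, f0 + drop_len - 1L)
      bump[idx_d] <- bump[idx_d] + amp * seq_along(idx_d) / drop_len
      idx_r <- (f0 + drop_len):min(n, f0 + drop_len + rec_len - 1L)
      if (length(idx_r))
        bump[idx_r] <- bump[idx_r] +
          amp * exp(-(seq_along(idx_r) - 1L) / (0.5 * fps))
    }
  }
  va <- pmax(0, round(cfg$va_baseline_px * (rel - bump)))
  va_series(seq_len(n) - 1L, va, trial_id = trial_id, fps = fps)
}

#' Generate one synthetic trial
#'
#' @param skill Latent skill in \[0, 1\].
#' @param config A [synthetic_config()].
#' @param trial_id Identifier for the generated trial.
#' @return List with `right` and `left` [tip_track()]s, `va`
#'   ([va_series()]) and `phases` ([phase_annotation()]).
#' @export
synth_trial <- function(skill, config = synthetic_config(),
                        trial_id = "trial") {
  stopifnot(skill >= 0, skill <= 1)
  fps <- config$fps
  dur <- config$phase_durations_s *
    (1 + config$time_dilation * (1 - skill)) * rlnorm(4, 0, 0.1)
  frames <- pmax(round(dur * fps), round(2 * fps))
  ends <- cumsum(frames)
  phases <- phase_annotation(trial = rep(trial_id, 4), phase = phase_levels(),
                             start_frame = c(0L, head(ends, -1L)),
                             end_frame = ends)
  list(right = synth_hand_track(skill, frames, config, "right", trial_id),
       left = synth_hand_track(skill, frames, config, "left", trial_id),
       va = synth_va_series(skill, phases, config, trial_id),
       phases = phases)
}

#' Generate rubric scores for one surgeon
#'
#' Each rater's score in each category and trial is
#' `round(1 + 4 * skill + Normal(0, rater_sd))` clipped to \[1, 5\],
#' independently per rater, trial and category.
#'
#' @param skill Latent skill in \[0, 1\].
#' @param config A [synthetic_config()].
#' @param surgeon Surgeon identifier.
#' @param trials Trial identifiers to score.
#' @param raters Rater identifiers (default three raters).
#' @return Rubric tibble ([read_rubric_csv()] layout).
#' @export
synth_rubric <- function(skill, config = synthetic_config(),
                         surgeon = "S01", trials = c("T1", "T2"),
                         raters = c("R1", "R2", "R3")) {
  stopifnot(skill >= 0, skill <= 1)
  grid <- expand.grid(trial = trials, rater = raters,
                      stringsAsFactors = FALSE)
  cats <- rubric_categories()
  sc <- matrix(pmin(5, pmax(1, round(
    1 + 4 * skill + rnorm(nrow(grid) * length(cats), 0, config$rater_sd)))),
    nrow = nrow(grid))
  colnames(sc) <- cats
  tibble::tibble(surgeon = surgeon, trial = grid$trial, rater = grid$rater,
                 tibble::as_tibble(sc))
}

#' Generate a full synthetic cohort
#'
#' Draws (or takes) per-surgeon latent skills, generates every trial's
#' tracks, vessel-area series and phase annotations plus the three-rater
#' rubric, and optionally writes everything to disk in the CSV formats
#' the readers consume. A fixed seed reproduces the cohort exactly; each
#' surgeon uses an independent substream derived from it.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, [write_cohort()] is
#'   called on the result.
#' @return A list of class `synthetic_cohort`: `tracks` (named
#'   `"<trial>/<hand>"`), `va` (named by trial), `phases`, `trials`
#'   (trial/surgeon/trial_index map), `rubric`, `truth` (surgeon, skill
#'   and intended label), `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL) {
  set.seed(config$seed)
  n <- config$n_surgeons
  skill <- config$skill
  if (is.null(skill)) {
    n_hi <- ceiling(n / 2)
    skill <- pmin(1, pmax(0, c(rnorm(n_hi, 0.8, 0.07),
                               rnorm(n - n_hi, 0.3, 0.07))))
  }
  surgeons <- sprintf("S%02d", seq_len(n))
  tracks <- list()
  va <- list()
  phases <- list()
  trials_map <- list()
  rubric <- list()
  for (i in seq_len(n)) {
    set.seed((config$seed * 97L + i * 7919L) %% .Machine$integer.max)
    trial_ids <- sprintf("%s_T%d", surgeons[i], seq_len(config$trials_per_surgeon))
    for (k in seq_len(config$trials_per_surgeon)) {
      tr <- synth_trial(skill[i], config, trial_id = trial_ids[k])
      tracks[[paste0(trial_ids[k], "/right")]] <- tr$right
      tracks[[paste0(trial_ids[k], "/left")]] <- tr$left
      va[[trial_ids[k]]] <- tr$va
      phases[[trial_ids[k]]] <- tr$phases
    }
    trials_map[[i]] <- tibble::tibble(trial = trial_ids,
                                      surgeon = surgeons[i],
                                      trial_index = seq_along(trial_ids))
    rubric[[i]] <- synth_rubric(skill[i], config, surgeon = surgeons[i],
                                trials = trial_ids)
  }
  out <- structure(list(
    tracks = tracks, va = va,
    phases = validate_phase_annotation(dplyr::bind_rows(phases)),
    trials = dplyr::bind_rows(trials_map),
    rubric = dplyr::bind_rows(rubric),
    truth = tibble::tibble(surgeon = surgeons, skill = skill,
                           label = ifelse(skill >= 0.5, "good", "poor")),
    config = config), class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a cohort dataset to disk
#'
#' Emits `tracks.csv`, `va.csv`, `phases.csv`, `rubric.csv`,
#' `trials.csv` and `truth.csv` in the formats the package readers
#' consume.
#'
#' @param dataset A `synthetic_cohort` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- dplyr::bind_rows(lapply(dataset$tracks, function(t)
    tibble::tibble(trial = attr(t, "trial_id"), hand = attr(t, "hand"),
                   frame = t$frame, x = t$x, y = t$y,
                   valid = as.integer(t$valid))))
  readr::write_csv(tr, file.path(dir, "tracks.csv"))
  write_va_csv(dataset$va, file.path(dir, "va.csv"))
  write_phase_csv(dataset$phases, file.path(dir, "phases.csv"))
  write_rubric_csv(dataset$rubric, file.path(dir, "rubric.csv"))
  readr::write_csv(dataset$trials, file.path(dir, "trials.csv"))
  if (!is.null(dataset$truth))
    readr::write_csv(dataset$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a cohort dataset from disk
#'
#' Inverse of [write_cohort()].
#'
#' @param dir Directory holding the cohort CSVs.
#' @param fps Frames per second for the tracks and series.
#' @return A `synthetic_cohort`-shaped list usable by
#'   [extract_cohort_parameters()] and [run_skill_pipeline()].
#' @export
read_cohort <- function(dir, fps = 30) {
  truth_path <- file.path(dir, "truth.csv")
  trials <- read_csv_checked(file.path(dir, "trials.csv"),
                             c("trial", "surgeon", "trial_index"))
  trials$trial <- as.character(trials$trial)
  trials$surgeon <- as.character(trials$surgeon)
  structure(list(
    tracks = read_tip_track(file.path(dir, "tracks.csv"), fps = fps),
    va = read_va_csv(file.path(dir, "va.csv"), fps = fps),
    phases = read_phase_csv(file.path(dir, "phases.csv")),
    trials = trials,
    rubric = read_rubric_csv(file.path(dir, "rubric.csv")),
    truth = if (file.exists(truth_path))
      readr::read_csv(truth_path, show_col_types = FALSE)),
    class = "synthetic_cohort")
}
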