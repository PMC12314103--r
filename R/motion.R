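# Finite differences: 2nd-order central with high-order one-sided ends.
# Written here because the jerk estimate applies this three times: with
# low-order edges the compounded endpoint error dominates the squared-
# jerk integral (jerk peaks at movement endpoints), so the edges use
# 3rd-order one-sided stencils when the segment allows.
fd_gradient <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(NA_real_, n))
  if (n == 2L) return(rep((y[2L] - y[1L]) / dt, 2L))
  g <- numeric(n)
  g[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)
  if (n >= 4L) {
    g[1L] <- (-11 * y[1L] + 18 * y[2L] - 9 * y[3L] + 2 * y[4L]) / (6 * dt)
    g[n] <- (11 * y[n] - 18 * y[n - 1L] + 9 * y[n - 2L] - 2 * y[n - 3L]) /
      (6 * dt)
  } else {
    g[1L] <- (-3 * y[1L] + 4 * y[2L] - y[3L]) / (2 * dt)
    g[n] <- (3 * y[n] - 4 * y[n - 1L] + y[n - 2L]) / (2 * dt)
  }
  g
}

#' Segment a tip track and differentiate it
#'
#' Valid frames are partitioned into maximal contiguous runs
#' (detection gaps split segments; derivatives never span a gap, since a
#' tool outside the field of view leaves no trustworthy motion to
#' bridge). Within each segment of at least `window` frames the positions
#' are smoothed by a Savitzky-Golay filter of order `polyorder`; shorter
#' segments pass through unsmoothed. Velocity, acceleration and jerk are
#' obtained by repeated finite differencing within segments (central
#' differences, second-order one-sided at segment ends).
#'
#' @param track A [tip_track()].
#' @param window Odd smoothing window in frames; `1` disables smoothing.
#' @param polyorder Polynomial order of the smoother (< `window`).
#' @return A tibble of class `kinematic_series` with columns `frame`,
#'   `time_s`, `x`, `y`, `vx`, `vy`, `ax`, `ay`, `jx`, `jy`,
#'   `segment_id`; one row per valid frame.
#' @export
segment_and_smooth <- function(track, window = 7, polyorder = 2) {
  stopifnot(inherits(track, "tip_track"))
  if (window %% 2 != 1 || (window > 1 && window <= polyorder))
    stop("`window` must be odd and greater than `polyorder`", call. = FALSE)
  v <- track[track$valid, , drop = FALSE]
  if (nrow(v) == 0L)
    stop("track has no valid frames", call. = FALSE)
  fps <- attr(track, "fps")
  dt <- 1 / fps
  # contiguous valid frames (consecutive indices) form one segment
  seg <- cumsum(c(1L, diff(v$frame) != 1L)) - 1L
  pieces <- lapply(split(seq_len(nrow(v)), seg), function(idx) {
    x <- v$x[idx]; y <- v$y[idx]
    n <- length(idx)
    if (window > 1 && n >= window) {
      x <- signal::sgolayfilt(x, p = polyorder, n = window)
      y <- signal::sgolayfilt(y, p = polyorder, n = window)
    }
    vx <- fd_gradient(x, dt); vy <- fd_gradient(y, dt)
    ax <- fd_gradient(vx, dt); ay <- fd_gradient(vy, dt)
    jx <- fd_gradient(ax, dt); jy <- fd_gradient(ay, dt)
    tibble::tibble(frame = v$frame[idx], time_s = v$time_s[idx],
                   x = x, y = y, vx = vx, vy = vy, ax = ax, ay = ay,
                   jx = jx, jy = jy)
  })
  out <- dplyr::bind_rows(pieces, .id = "segment_id")
  out$segment_id <- as.integer(out$segment_id)
  out <- out[c("frame", "time_s", "x", "y", "vx", "vy", "ax", "ay",
               "jx", "jy", "segment_id")]
  structure(out, trial_id = attr(track, "trial_id"),
            hand = attr(track, "hand"), fps = fps,
            class = c("kinematic_series", class(out)))
}

#' Path distance of a tip trajectory
#'
#' Total Euclidean distance travelled, summed over consecutive positions
#' within each segment; detection gaps contribute nothing (motion across
#' a gap is never fabricated).
#'
#' @param kin A `kinematic_series` from [segment_and_smooth()].
#' @return Path distance in pixels (>= 0).
#' @export
path_distance <- function(kin) {
  stopifnot(inherits(kin, "kinematic_series"))
  if (nrow(kin) == 0L) stop("empty kinematic series", call. = FALSE)
  sum(vapply(split(kin, kin$segment_id), function(s) {
    if (nrow(s) < 2L) return(0)
    sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
  }, numeric(1)))
}

#' Normalized jerk index (NJI)
#'
#' Dimensionless motion-smoothness measure
#' `NJI = 1/2 * t^5 / D^2 * integral(|da/dt|^2 dt)`, where `t` is the
#' procedural time (total valid duration, summed over segments), `D` the
#' path distance and the squared jerk magnitude is integrated by the
#' trapezoid rule within segments. An ideal single minimum-jerk reach
#' scores 360; rougher motion scores higher. The `t^5 / D^2` factor makes
#' the index invariant to the duration and amplitude of the movement.
#'
#' @param kin A `kinematic_series` from [segment_and_smooth()].
#' @return Dimensionless scalar (>= 0).
#' @export
normalized_jerk_index <- function(kin) {
  stopifnot(inherits(kin, "kinematic_series"))
  if (nrow(kin) == 0L) stop("empty kinematic series", call. = FALSE)
  segs <- split(kin, kin$segment_id)
  t_total <- sum(vapply(segs, function(s)
    max(s$time_s) - min(s$time_s), numeric(1)))
  if (t_total <= 0)
    stop("total valid duration is zero", call. = FALSE)
  D <- path_distance(kin)
  if (D <= 0)
    stop("stationary tip: path distance is zero, NJI undefined",
         call. = FALSE)
  integral <- sum(vapply(segs, function(s) {
    ok <- is.finite(s$jx) & is.finite(s$jy)
    if (sum(ok) < 2L) return(0)
    pracma::trapz(s$time_s[ok], s$jx[ok]^2 + s$jy[ok]^2)
  }, numeric(1)))
  0.5 * t_total^5 / D^2 * integral
}
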