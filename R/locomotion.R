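#' Swim trajectory
#'
#' @param x_mm,y_mm Positions in millimetres.
#' @param fps Frame rate in Hz (50 for the tracking rig emulated here).
#' @return A `swim_trajectory` data frame with columns `t_s`, `x_mm`, `y_mm`.
#' @export
swim_trajectory <- function(x_mm, y_mm, fps = 50) {
  stopifnot(length(x_mm) == length(y_mm), length(x_mm) >= 1, fps > 0,
            all(is.finite(x_mm)), all(is.finite(y_mm)))
  structure(data.frame(t_s = (seq_along(x_mm) - 1) / fps, x_mm = x_mm, y_mm = y_mm),
            fps = fps, class = c("swim_trajectory", "data.frame"))
}

#' Instantaneous swim velocity series
#'
#' Frame-to-frame Euclidean displacement times the frame rate, smoothed
#' with a centred moving average of `smooth_frames` frames (odd; windows
#' are truncated at the ends). Smoothing suppresses single-frame centroid
#' jitter of the tracker.
#'
#' @param traj A [swim_trajectory()].
#' @param smooth_frames Odd moving-average window (1 = no smoothing).
#' @return Numeric vector of length `nrow(traj) - 1`, in mm/s.
#' @export
compute_velocity_series <- function(traj, smooth_frames = 5) {
  stopifnot(inherits(traj, "swim_trajectory"), nrow(traj) >= 2,
            smooth_frames >= 1, smooth_frames %% 2 == 1)
  fps <- attr(traj, "fps")
  dt <- diff(traj$t_s)
  if (any(abs(dt - 1 / fps) > 1e-9))
    stop("trajectory timestamps are not uniform at 1/fps")
  v <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2) * fps
  if (smooth_frames == 1) return(v)
  half <- (smooth_frames - 1) / 2
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Locomotor summary: velocity, distance, darting
#'
#' Mean of the smoothed velocity series, total path length, and the
#' percentage of frames whose velocity exceeds the darting threshold.
#' The threshold stands in for the burst-movement detector of commercial
#' tracking software; one shared value must be used across all cohorts
#' being compared.
#'
#' @param traj A [swim_trajectory()].
#' @param dart_threshold_mm_s High-velocity threshold defining darting.
#' @param smooth_frames Velocity smoothing window (see
#'   [compute_velocity_series()]).
#' @return A list with `mean_velocity_mm_s`, `total_distance_mm`,
#'   `darting_pct`, `dart_threshold_mm_s`.
#' @export
locomotion_metrics <- function(traj, dart_threshold_mm_s = 20, smooth_frames = 5) {
  v <- compute_velocity_series(traj, smooth_frames)
  fps <- attr(traj, "fps")
  list(mean_velocity_mm_s = mean(v),
       total_distance_mm = sum(sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)),
       darting_pct = 100 * mean(v > dart_threshold_mm_s),
       dart_threshold_mm_s = dart_threshold_mm_s)
}
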