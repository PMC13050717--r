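#' Trajectory-generator configuration
#'
#' A random-heading swim at cruising speed, interrupted by Poisson-
#' scheduled darting bursts at high speed, inside a circular arena (a
#' 24-well plate well) with reflecting walls.
#'
#' @param fps Frame rate, Hz.
#' @param duration_s Recording length, seconds.
#' @param base_speed_mm_s Cruising speed, mm/s.
#' @param dart_rate_per_min Expected darting bursts per minute.
#' @param dart_speed_mm_s Speed during a burst (> base speed).
#' @param dart_duration_s Burst duration, seconds.
#' @param arena_radius_mm Arena radius, mm.
#' @param turn_rate_deg_s SD of the heading random walk, degrees/s.
#' @return A `trajectory_config`.
#' @export
trajectory_config <- function(fps = 50, duration_s = 3600,
                              base_speed_mm_s = 0.2, dart_rate_per_min = 0.5,
                              dart_speed_mm_s = 30, dart_duration_s = 0.25,
                              arena_radius_mm = 7.8, turn_rate_deg_s = 90) {
  stopifnot(fps > 0, duration_s > 0, base_speed_mm_s >= 0,
            dart_speed_mm_s > base_speed_mm_s, dart_rate_per_min >= 0,
            dart_duration_s > 0, arena_radius_mm > 0)
  structure(list(fps = fps, duration_s = duration_s,
                 base_speed_mm_s = base_speed_mm_s,
                 dart_rate_per_min = dart_rate_per_min,
                 dart_speed_mm_s = dart_speed_mm_s,
                 dart_duration_s = dart_duration_s,
                 arena_radius_mm = arena_radius_mm,
                 turn_rate_deg_s = turn_rate_deg_s),
            class = "trajectory_config")
}

#' Simulate a swim trajectory
#'
#' Headings follow a Gaussian random walk; frame speeds are the cruising
#' speed except during darting bursts, whose onsets are a Poisson process.
#' At the arena wall the heading is reflected about the boundary normal,
#' so every position stays within the arena radius and frame-to-frame
#' speeds are preserved.
#'
#' @param cfg A [trajectory_config()].
#' @param seed Integer seed.
#' @return A [swim_trajectory()].
#' @export
simulate_trajectory <- function(cfg, seed) {
  stopifnot(inherits(cfg, "trajectory_config"))
  set.seed(fold_seed(seed))
  nf <- round(cfg$duration_s * cfg$fps)
  dt <- 1 / cfg$fps
  ## per-frame speed schedule
  speed <- rep(cfg$base_speed_mm_s, nf)
  p_start <- cfg$dart_rate_per_min / 60 * dt
  if (cfg$dart_rate_per_min > 0) {
    starts <- which(stats::runif(nf) < p_start)
    len <- max(1L, round(cfg$dart_duration_s * cfg$fps))
    for (s in starts) speed[s:min(s + len - 1L, nf)] <- cfg$dart_speed_mm_s
  }
  dtheta <- stats::rnorm(nf, 0, cfg$turn_rate_deg_s * pi / 180 * dt)
  theta0 <- stats::runif(1, 0, 2 * pi)
  r0 <- cfg$arena_radius_mm * 0.5 * sqrt(stats::runif(1))
  a0 <- stats::runif(1, 0, 2 * pi)
  x <- y <- numeric(nf + 1)
  x[1] <- r0 * cos(a0); y[1] <- r0 * sin(a0)
  th <- theta0
  R <- cfg$arena_radius_mm
  for (i in seq_len(nf)) {
    th <- th + dtheta[i]
    step <- speed[i] * dt
    nx <- x[i] + step * cos(th)
    ny <- y[i] + step * sin(th)
    if (nx * nx + ny * ny > R * R) {
      ## reflect the heading about the boundary normal and retake the step
      phi <- atan2(y[i], x[i])
      th <- pi + 2 * phi - th
      nx <- x[i] + step * cos(th)
      ny <- y[i] + step * sin(th)
      if (nx * nx + ny * ny > R * R) {   # started on the wall; step inward
        th <- phi + pi
        nx <- x[i] + step * cos(th)
        ny <- y[i] + step * sin(th)
      }
    }
    x[i + 1] <- nx; y[i + 1] <- ny
  }
  swim_trajectory(x, y, cfg$fps)
}
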