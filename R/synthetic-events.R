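#' Event-train configuration
#'
#' Parameters of the planted calcium-event process of one cohort: a
#' Poisson number of events placed uniformly over the recording subject to
#' a hard minimum separation, with truncated-normal amplitudes and a
#' compound unit-peak kernel (see [calcium_kernel()]).
#'
#' @param rate Expected events per recording (dimensionless count).
#' @param duration_s Recording length, seconds.
#' @param min_separation_s Minimum gap between event peaks, seconds.
#' @param amplitude_mean,amplitude_sd Planted peak amplitude distribution
#'   (dF/F0 percent), truncated at zero.
#' @param rise_tau_s,decay_tau_s Kernel time constants, seconds
#'   (decay > rise > 0).
#' @param plateau_weight,plateau_sigma_s Plateau component of the kernel.
#' @return An `event_train_config`.
#' @export
event_train_config <- function(rate, duration_s = 1800, min_separation_s = 60,
                               amplitude_mean, amplitude_sd = 0.25 * amplitude_mean,
                               rise_tau_s = 2, decay_tau_s = 12,
                               plateau_weight = 0, plateau_sigma_s = 0) {
  stopifnot(rate >= 0, duration_s > 0, min_separation_s > 0,
            amplitude_mean > 0, amplitude_sd >= 0,
            decay_tau_s > rise_tau_s, rise_tau_s > 0, plateau_weight >= 0)
  structure(list(rate = rate, duration_s = duration_s,
                 min_separation_s = min_separation_s,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 plateau_weight = plateau_weight, plateau_sigma_s = plateau_sigma_s),
            class = "event_train_config")
}

#' Noise and baseline-drift configuration
#'
#' @param noise_sd Additive white noise SD, dF/F0 percent.
#' @param drift_amp Amplitude of the slow sinusoidal baseline drift,
#'   dF/F0 percent.
#' @param drift_period_s Drift period; must exceed 200 s so the drift lies
#'   below the 0.005 Hz high-pass cutoff.
#' @return A `noise_drift_config`.
#' @export
noise_drift_config <- function(noise_sd = 0.1, drift_amp = 0.5, drift_period_s = 900) {
  stopifnot(noise_sd >= 0, drift_amp >= 0, drift_period_s > 1 / 0.005)
  structure(list(noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_period_s = drift_period_s),
            class = "noise_drift_config")
}

#' Bilateral synchrony configuration
#'
#' @param rho_homotopic_mb,rho_homotopic_fb Target left-right Pearson
#'   correlations for midbrain and forebrain (in `[-1, 1]`).
#' @param p_shared Probability that a planted event appears bilaterally in
#'   the movie renderer.
#' @return A `synchrony_config`.
#' @export
synchrony_config <- function(rho_homotopic_mb, rho_homotopic_fb, p_shared = 0.9) {
  stopifnot(abs(rho_homotopic_mb) <= 1, abs(rho_homotopic_fb) <= 1,
            p_shared >= 0, p_shared <= 1)
  structure(list(rho_homotopic_mb = rho_homotopic_mb,
                 rho_homotopic_fb = rho_homotopic_fb, p_shared = p_shared),
            class = "synchrony_config")
}

fold_seed <- function(s) {
  as.integer(round(s) %% (.Machine$integer.max - 1))
}

#' Simulate a ground-truthed event train
#'
#' Draws a Poisson event count, places events uniformly over the recording
#' and redraws the placement until all gaps respect `min_separation_s`
#' (configuration resampling keeps the count exactly Poisson; deleting
#' offenders would bias the mean count low). Amplitudes are normal,
#' redrawn where nonpositive.
#'
#' @param cfg An [event_train_config()].
#' @param seed Integer seed fixing all randomness.
#' @return A `ground_truth` data frame with columns `event_time_s` (sorted)
#'   and `amplitude`, carrying `cfg` as an attribute.
#' @export
simulate_event_train <- function(cfg, seed) {
  stopifnot(inherits(cfg, "event_train_config"))
  if (cfg$rate * cfg$min_separation_s > 0.5 * cfg$duration_s)
    stop("rate too high for min_separation_s: expected count x separation exceeds half the duration")
  set.seed(fold_seed(seed))
  n <- stats::rpois(1, cfg$rate)
  times <- numeric(0)
  if (n > 0) {
    for (attempt in seq_len(1000)) {
      times <- sort(stats::runif(n, 0, cfg$duration_s))
      if (n < 2 || all(diff(times) >= cfg$min_separation_s)) break
      if (attempt == 1000) stop("could not place events at the requested separation")
    }
  }
  amps <- numeric(0)
  if (n > 0) {
    amps <- stats::rnorm(n, cfg$amplitude_mean, cfg$amplitude_sd)
    while (any(amps <= 0))
      amps[amps <= 0] <- stats::rnorm(sum(amps <= 0), cfg$amplitude_mean, cfg$amplitude_sd)
  }
  structure(data.frame(event_time_s = times, amplitude = amps),
            cfg = cfg, class = c("ground_truth", "data.frame"))
}

#' Render a whole-brain trace from a ground-truth event train
#'
#' The trace is the superposition of the planted events' kernels plus a
#' slow sinusoidal baseline drift (random phase) and additive white noise,
#' sampled at `fs`.
#'
#' @param truth A `ground_truth` from [simulate_event_train()].
#' @param cfg The [event_train_config()] (defaults to the one carried by
#'   `truth`).
#' @param noise A [noise_drift_config()].
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed for drift phase and noise.
#' @param provenance Provenance tag for the trace.
#' @return A [ca_trace()].
#' @export
synthesize_trace <- function(truth, cfg = attr(truth, "cfg"), noise = noise_drift_config(),
                             fs = 2, seed = 1, provenance = "whole_brain") {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "event_train_config"),
            inherits(noise, "noise_drift_config"), fs > 0)
  tt <- seq(0, cfg$duration_s - 1 / fs, by = 1 / fs)
  x <- numeric(length(tt))
  for (i in seq_len(nrow(truth))) {
    x <- x + truth$amplitude[i] *
      calcium_kernel(tt - truth$event_time_s[i], cfg$rise_tau_s, cfg$decay_tau_s,
                     cfg$plateau_weight, cfg$plateau_sigma_s)
  }
  set.seed(fold_seed(seed))
  if (noise$drift_amp > 0)
    x <- x + noise$drift_amp * sin(2 * pi * tt / noise$drift_period_s +
                                     stats::runif(1, 0, 2 * pi))
  if (noise$noise_sd > 0)
    x <- x + stats::rnorm(length(tt), 0, noise$noise_sd)
  ca_trace(x, fs, provenance)
}
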