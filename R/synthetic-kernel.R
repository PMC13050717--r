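## Event kernel and the deterministic preset calibration.
##
## Planted events use a compound unit-peak kernel: a difference-of-
## exponentials transient (the classic GCaMP rise/decay shape) riding on a
## Gaussian plateau centred at the transient peak. The plateau carries the
## prolonged, minutes-long envelope of seizure-like events while the
## transient carries the fast in-band structure; their relative weight is
## what the calibration solves for.

#' Evaluate the unit-peak event kernel
#'
#' @param rel_t Times relative to event onset, seconds (kernel is 0 for
#'   `rel_t < 0` when `plateau_weight = 0`).
#' @param rise_tau_s,decay_tau_s Exponential time constants (decay > rise).
#' @param plateau_weight Weight of the Gaussian plateau relative to the
#'   unit-peak transient (0 = pure difference of exponentials).
#' @param plateau_sigma_s Plateau half-duration scale, seconds.
#' @return Kernel values, normalised so the compound peak is 1.
#' @export
calcium_kernel <- function(rel_t, rise_tau_s, decay_tau_s,
                           plateau_weight = 0, plateau_sigma_s = 0) {
  stopifnot(decay_tau_s > rise_tau_s, rise_tau_s > 0, plateau_weight >= 0)
  dexp1 <- function(t) ifelse(t >= 0, exp(-t / decay_tau_s) - exp(-t / rise_tau_s), 0)
  ## analytic peak of the transient
  tp <- log(decay_tau_s / rise_tau_s) * rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s)
  fpk <- dexp1(tp)
  k <- dexp1(rel_t) / fpk
  if (plateau_weight > 0 && plateau_sigma_s > 0) {
    k <- k + plateau_weight * exp(-(rel_t - tp)^2 / (2 * plateau_sigma_s^2))
    ## compound peak on a dense grid (flat near the top; 0.25 s is ample)
    td <- seq(tp - 4 * plateau_sigma_s, tp + 4 * plateau_sigma_s + 4 * decay_tau_s, by = 0.25)
    kd <- dexp1(td) / fpk + plateau_weight * exp(-(td - tp)^2 / (2 * plateau_sigma_s^2))
    k <- k / max(kd)
  }
  k
}

## Filter attenuation and position-averaged in-band energy of the unit
## kernel, measured with the same filter and spectral estimator the
## pipeline applies. `eb` is in (dF/F0%)^2 * s for a unit-amplitude event.
kernel_pipeline_props <- function(rise, decay, w, sigp, duration_s = 1800, fs = 2,
                                  cutoff_hz = 0.005, band = c(0.01, 1),
                                  taper = 0.1, n_positions = 48) {
  tt <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  kmid <- calcium_kernel(tt - duration_s / 2, rise, decay, w, sigp)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "high")
  att <- max(zero_phase_filter(bf$b, bf$a, kmid))
  pos <- (seq_len(n_positions) - 0.5) / n_positions * duration_s
  ebs <- vapply(pos, function(p0) {
    tr <- ca_trace(calcium_kernel(tt - p0, rise, decay, w, sigp), fs, "kernel")
    integrated_low_freq_power(roi_power_spectrum(tr, taper = taper), band) * duration_s
  }, numeric(1))
  c(att = att, eb = mean(ebs))
}

#' Calibrate an event-train configuration to printed cohort statistics
#'
#' Given a cohort's printed detected event rate, mean detected amplitude,
#' and integrated 0.01-1 Hz band power, this solves deterministically for
#' the two free kernel parameters so that the full pipeline (high-pass
#' filter, pooled-threshold peak detection, tapered periodogram) recovers
#' the printed values in expectation:
#'
#' * the plateau weight is found by root-finding so that the kernel's
#'   position-averaged in-band energy over its squared filter attenuation
#'   equals the band-power budget left after additive noise,
#'   `(P - noise_sd^2) * T / (rate * amp^2 * (1 + cv^2))`;
#' * the planted amplitude mean is the printed amplitude divided by the
#'   kernel's measured zero-phase filter attenuation (the detector reads
#'   amplitudes off the filtered trace).
#'
#' The computation uses no random numbers and no pipeline output; it is a
#' forward-model solve repeated identically on every call.
#'
#' @param rate Expected detected events per recording.
#' @param amplitude Target mean detected amplitude, dF/F0 percent.
#' @param band_power Target integrated 0.01-1 Hz power.
#' @param rise_tau_s,decay_tau_s Transient time constants.
#' @param plateau_sigma_s Plateau scale, seconds.
#' @param noise_sd Additive white noise SD of the cohort, dF/F0 percent.
#' @param duration_s,fs Recording length and frame rate.
#' @param amplitude_cv Coefficient of variation of planted amplitudes.
#' @param min_separation_s Minimum event separation.
#' @return An [event_train_config()] with the solved `plateau_weight` and
#'   planted `amplitude_mean`, carrying the calibration targets and the
#'   measured attenuation as attributes.
#' @export
calibrate_event_train <- function(rate, amplitude, band_power,
                                  rise_tau_s, decay_tau_s, plateau_sigma_s,
                                  noise_sd, duration_s = 1800, fs = 2,
                                  amplitude_cv = 0.25, min_separation_s = 60) {
  stopifnot(rate > 0, amplitude > 0, band_power > noise_sd^2)
  key <- paste(rate, amplitude, band_power, rise_tau_s, decay_tau_s,
               plateau_sigma_s, noise_sd, duration_s, fs, amplitude_cv, sep = "|")
  cached <- .tadcal_cache[[key]]
  if (!is.null(cached)) return(cached)
  R_target <- (band_power - noise_sd^2) * duration_s /
    (rate * amplitude^2 * (1 + amplitude_cv^2))
  fobj <- function(w) {
    u <- kernel_pipeline_props(rise_tau_s, decay_tau_s, w, plateau_sigma_s,
                               duration_s, fs)
    u[["eb"]] / u[["att"]]^2 - R_target
  }
  w <- stats::uniroot(fobj, c(0, 10), tol = 1e-3)$root
  u <- kernel_pipeline_props(rise_tau_s, decay_tau_s, w, plateau_sigma_s,
                             duration_s, fs)
  planted <- amplitude / u[["att"]]
  cfg <- event_train_config(rate = rate, duration_s = duration_s,
                            min_separation_s = min_separation_s,
                            amplitude_mean = planted,
                            amplitude_sd = amplitude_cv * planted,
                            rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                            plateau_weight = w, plateau_sigma_s = plateau_sigma_s)
  attr(cfg, "calibration") <- list(target_amplitude = amplitude,
                                   target_band_power = band_power,
                                   attenuation = u[["att"]],
                                   in_band_energy = u[["eb"]])
  .tadcal_cache[[key]] <- cfg
  cfg
}

.tadcal_cache <- new.env(parent = emptyenv())
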