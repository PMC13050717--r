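## Cohort-level drivers: these compose the per-animal primitives into the
## study's group analyses and are what the analysis scripts and the
## acceptance machinery call.

#' Per-animal seeds for a cohort
#'
#' Expands one master seed into reproducible per-animal seeds by a fixed
#' offset scheme: `master * 10000 + offset + 1:n`. Conventional offsets
#' (0, 100, 200, ...) keep the cohorts' streams disjoint.
#'
#' @param master Master seed (small integer).
#' @param offset Cohort offset.
#' @param n Number of animals.
#' @return Integer vector of length `n`.
#' @export
cohort_seeds <- function(master, offset, n) {
  vapply(master * 10000 + offset + seq_len(n), fold_seed, integer(1))
}

#' Simulate a cohort of whole-brain traces
#'
#' @param preset A [cohort_preset()].
#' @param seeds Per-animal seeds (default `cohort_seeds(1, 0, n_animals)`).
#' @return List of [ca_trace()] objects with ground truth attached.
#' @export
simulate_cohort_traces <- function(preset, seeds = cohort_seeds(1, 0, preset$n_animals)) {
  lapply(seeds, function(s) simulate_whole_brain_trace(preset, s))
}

#' Event and spectral metrics for a cohort of traces
#'
#' Applies the uniform pipeline to every trace: high-pass filter, event
#' detection against the supplied fixed threshold, event summary, and
#' integrated 0.01-1 Hz power of the raw trace's spectrum on the common
#' grid.
#'
#' @param traces List of [ca_trace()] objects.
#' @param threshold A `threshold_model` (or numeric threshold).
#' @param cutoff_hz High-pass cutoff.
#' @param min_width_s,min_distance_s Peak constraints.
#' @param band Integration band, Hz.
#' @return Data frame with one row per animal: `animal`, `count`,
#'   `mean_amplitude`, `band_power`.
#' @export
analyze_cohort_traces <- function(traces, threshold, cutoff_hz = 0.005,
                                  min_width_s = 5, min_distance_s = 5,
                                  band = c(0.01, 1)) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    filt <- highpass_filter(tr, cutoff_hz)
    ev <- detect_events(filt, threshold, min_width_s, min_distance_s)
    sm <- summarize_events(ev, length(tr$values) / tr$fs)
    pw <- integrated_low_freq_power(animal_mean_spectrum(roi_power_spectrum(tr)), band)
    data.frame(animal = i, count = sm$count, mean_amplitude = sm$mean_amplitude,
               band_power = pw)
  })
  do.call(rbind, rows)
}

#' Full two-cohort comparison in trace space
#'
#' Simulates (or accepts) a control and an experimental cohort, derives
#' the pooled-control threshold from the filtered control traces, applies
#' it uniformly, and returns per-animal metrics plus the threshold model.
#'
#' @param control_traces,case_traces Lists of [ca_trace()] objects.
#' @param multiplier Threshold multiplier.
#' @param ... Passed to [analyze_cohort_traces()].
#' @return List with `threshold` and data frames `control`, `case`.
#' @export
run_cohort_comparison <- function(control_traces, case_traces, multiplier = 3, ...) {
  filt_controls <- lapply(control_traces, highpass_filter)
  thr <- derive_global_threshold(filt_controls, multiplier)
  list(threshold = thr,
       control = analyze_cohort_traces(control_traces, thr, ...),
       case = analyze_cohort_traces(case_traces, thr, ...))
}

#' Homotopic synchrony of a simulated cohort (mixing model)
#'
#' For each animal, synthesises a shared trace from the preset, mixes a
#' left/right pair at the preset's homotopic correlation for the chosen
#' region, and measures the Pearson correlation.
#'
#' @param preset A [cohort_preset()].
#' @param region `"mb"` or `"fb"`.
#' @param seeds Per-animal seeds.
#' @return Data frame `animal`, `r`.
#' @export
cohort_synchrony <- function(preset, region = c("mb", "fb"),
                             seeds = cohort_seeds(1, 200, preset$n_animals)) {
  region <- match.arg(region)
  rho <- if (region == "mb") preset$synchrony$rho_homotopic_mb else
    preset$synchrony$rho_homotopic_fb
  rows <- lapply(seq_along(seeds), function(i) {
    shared <- simulate_whole_brain_trace(preset, seeds[i])
    pair <- mix_correlated_pair(shared, rho, seeds[i] + 6e8)
    data.frame(animal = i, r = stats::cor(pair$left$values, pair$right$values))
  })
  do.call(rbind, rows)
}

#' Locomotion metrics of a simulated cohort
#'
#' @param preset A [cohort_preset()] (its `trajectory` configuration is
#'   used).
#' @param seeds Per-animal seeds.
#' @param dart_threshold_mm_s Shared darting threshold.
#' @return Data frame `animal`, `mean_velocity_mm_s`, `total_distance_mm`,
#'   `darting_pct`.
#' @export
cohort_locomotion <- function(preset, seeds = cohort_seeds(1, 600, preset$n_animals),
                              dart_threshold_mm_s = 20) {
  rows <- lapply(seq_along(seeds), function(i) {
    traj <- simulate_trajectory(preset$trajectory, seeds[i])
    m <- locomotion_metrics(traj, dart_threshold_mm_s)
    data.frame(animal = i, mean_velocity_mm_s = m$mean_velocity_mm_s,
               total_distance_mm = m$total_distance_mm,
               darting_pct = m$darting_pct)
  })
  do.call(rbind, rows)
}
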