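#!/usr/bin/env Rscript
## Preset calibration record: how the three synthetic cohorts are pinned to
## the published group statistics. For each cohort the published detected
## event rate, mean detected amplitude, and integrated 0.01-1 Hz power fix
## the free kernel parameters (plateau weight by root-finding on in-band
## energy over squared filter attenuation; planted amplitude = published
## amplitude / attenuation). This script recomputes the calibration from
## scratch and tabulates it.

suppressPackageStartupMessages(library(tadcal))
dir.create("results", showWarnings = FALSE)

rows <- lapply(c("control", "crispant", "crispant_losartan"), function(nm) {
  p <- cohort_preset(nm)
  cal <- attr(p$event_train, "calibration")
  data.frame(preset = nm, n_animals = p$n_animals,
             target_event_rate = p$targets$event_count,
             target_amplitude_pct = p$targets$amplitude,
             target_band_power = p$targets$band_power,
             rise_tau_s = p$event_train$rise_tau_s,
             decay_tau_s = p$event_train$decay_tau_s,
             plateau_sigma_s = p$event_train$plateau_sigma_s,
             plateau_weight = round(p$event_train$plateau_weight, 4),
             filter_attenuation = round(cal$attenuation, 4),
             planted_amplitude_pct = round(p$event_train$amplitude_mean, 3),
             noise_sd_pct = p$noise$noise_sd)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/preset_calibration.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nThe plateau carries the prolonged envelope of seizure-like events;\n",
    "its weight rises from control to treated cohorts because the published\n",
    "band power per event falls relative to the published amplitude.\n", sep = "")
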