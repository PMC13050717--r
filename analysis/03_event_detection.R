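#!/usr/bin/env Rscript
## Event detection and cohort comparison: pooled-control threshold, event
## counts and amplitudes for control vs CRISPant, and the losartan-treated
## contrast of the drug experiment.

suppressPackageStartupMessages(library(tadcal))
dir.create("results", showWarnings = FALSE)
master <- 1

ctrl <- cohort_preset("control"); cri <- cohort_preset("crispant")
los <- cohort_preset("crispant_losartan")
cmp <- run_cohort_comparison(
  simulate_cohort_traces(ctrl, cohort_seeds(master, 0, ctrl$n_animals)),
  simulate_cohort_traces(cri, cohort_seeds(master, 100, cri$n_animals)))
write_threshold_json(cmp$threshold, "results/threshold.json")
los_m <- analyze_cohort_traces(
  simulate_cohort_traces(los, cohort_seeds(master, 700, los$n_animals)),
  cmp$threshold)

metrics <- rbind(cbind(cohort = "control", cmp$control),
                 cbind(cohort = "crispant", cmp$case),
                 cbind(cohort = "crispant_losartan", los_m))
write.csv(metrics, "results/event_metrics.csv", row.names = FALSE)

summ <- function(v) sprintf("%.2f +/- %.2f", mean(v, na.rm = TRUE),
                            sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
cat(sprintf("threshold: %.3f dF/F0%% (3 x pooled control SD)\n", cmp$threshold$threshold))
cat(sprintf("event counts: control %s, crispant %s per 30 min\n",
            summ(cmp$control$count), summ(cmp$case$count)))
cat(sprintf("amplitudes:   control %s, crispant %s dF/F0%%\n",
            summ(cmp$control$mean_amplitude), summ(cmp$case$mean_amplitude)))

## the statistical policy of the study: Shapiro-Wilk gate, then rank test
## or Welch
tests <- rbind(
  data.frame(comparison = "count_control_vs_crispant",
             p = compare_groups(cmp$control$count, cmp$case$count)$chosen$p_value),
  data.frame(comparison = "amplitude_control_vs_crispant",
             p = compare_groups(cmp$control$mean_amplitude[!is.na(cmp$control$mean_amplitude)],
                                cmp$case$mean_amplitude)$chosen$p_value),
  data.frame(comparison = "count_crispant_vs_losartan",
             p = welch_t(cmp$case$count, los_m$count)$p_value),
  data.frame(comparison = "amplitude_crispant_vs_losartan",
             p = welch_t(cmp$case$mean_amplitude[!is.na(cmp$case$mean_amplitude)],
                         los_m$mean_amplitude[!is.na(los_m$mean_amplitude)])$p_value))
write.csv(tests, "results/event_tests.csv", row.names = FALSE)
print(tests, row.names = FALSE)
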