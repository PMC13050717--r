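#!/usr/bin/env Rscript
## Locomotor phenotyping: cohort swim velocities and darting, and the
## paired before/after losartan contrast (same animals, Wilcoxon paired).

suppressPackageStartupMessages(library(tadcal))
dir.create("results", showWarnings = FALSE)
master <- 1
n_pairs <- 11

cri <- cohort_preset("crispant"); los <- cohort_preset("crispant_losartan")
ctrl <- cohort_preset("control")

## paired design: each animal is tracked before (untreated CRISPant
## kinematics) and after one hour of losartan (treated kinematics)
before <- cohort_locomotion(cri, cohort_seeds(master, 600, n_pairs))
after <- cohort_locomotion(los, cohort_seeds(master, 600, n_pairs) + 5000)
paired <- data.frame(animal = seq_len(n_pairs),
                     velocity_before = before$mean_velocity_mm_s,
                     velocity_after = after$mean_velocity_mm_s)
write.csv(paired, "results/losartan_paired_velocity.csv", row.names = FALSE)
wt <- wilcoxon_signed_rank(paired$velocity_before, paired$velocity_after)
cat(sprintf("velocity before %.3f +/- %.3f, after %.3f +/- %.3f mm/s\n",
            mean(paired$velocity_before), sd(paired$velocity_before) / sqrt(n_pairs),
            mean(paired$velocity_after), sd(paired$velocity_after) / sqrt(n_pairs)))
cat(sprintf("paired Wilcoxon: V = %g, p = %.4g; %d/%d animals decreased\n",
            wt$statistic, wt$p_value,
            sum(paired$velocity_after < paired$velocity_before), n_pairs))

## unpaired control vs CRISPant hyperactivity
ctl_loc <- cohort_locomotion(ctrl, cohort_seeds(master, 650, 12))
cri_loc <- cohort_locomotion(cri, cohort_seeds(master, 660, 13))
loc <- rbind(cbind(cohort = "control", ctl_loc), cbind(cohort = "crispant", cri_loc))
write.csv(loc, "results/locomotion_cohorts.csv", row.names = FALSE)
cat(sprintf("control %.3f mm/s (darting %.2f%%), crispant %.3f mm/s (darting %.2f%%), p = %.4g\n",
            mean(ctl_loc$mean_velocity_mm_s), mean(ctl_loc$darting_pct),
            mean(cri_loc$mean_velocity_mm_s), mean(cri_loc$darting_pct),
            compare_groups(ctl_loc$mean_velocity_mm_s,
                           cri_loc$mean_velocity_mm_s)$chosen$p_value))
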