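#!/usr/bin/env Rscript
# Stage 3: the full cohort experiment. Simulate control, tau-pattern and
# TDP-pattern groups with regional hypoperfusion, atrophy and a severity
# coupling; quantify, quality-gate, register with all three methods; then
# evaluate registration consistency (pairwise CC framework) and the ROI
# group statistics. All tables land under results/03_experiment/.

suppressMessages(library(aslregsim))

cfg <- experiment_config(
  spec = phantom_spec(structural_shape = c(48, 48, 48),
                      structural_spacing = 4, seed = 42),
  n_per_group = c(control = 8, tau_like = 5, tdp_like = 5),
  effects = list(
    group_effect_spec("control"),
    # frontal-type pattern: moderate reduction in a compact parcel set
    group_effect_spec("tau_like", affected_rois = 1:5,
                      cbf_reduction_fraction = 0.2,
                      atrophy_thinning_mm = 0.5,
                      severity_slope = -1, severity_noise_sd = 2),
    # temporal-type pattern: broader and deeper, inverse severity coupling
    group_effect_spec("tdp_like", affected_rois = 10:17,
                      cbf_reduction_fraction = 0.3,
                      atrophy_thinning_mm = 1,
                      severity_slope = -1.5, severity_noise_sd = 2)),
  out_dir = "results/03_experiment",
  seed = 42)

rep <- run_experiment(cfg)
print(rep)

cat("\nMean participant CC by method and group:\n")
for (key in names(rep$participant_cc))
  cat(sprintf("  %-24s %.4f\n", key, mean(rep$participant_cc[[key]]$mean_cc)))

cat("\nSignificant hypoperfusion ROIs (Bonferroni pFWE < 0.05):\n")
for (key in names(rep$roi_tests))
  cat(sprintf("  %-28s %d\n", key,
              sum(rep$roi_tests[[key]]$table$significant_fwe, na.rm = TRUE)))

cat("\nSignificant atrophy ROIs:\n")
for (key in names(rep$volume_tests))
  cat(sprintf("  %-28s %d\n", key,
              sum(rep$volume_tests[[key]]$table$significant_fwe, na.rm = TRUE)))

for (g in names(rep$severity_fits)) {
  f <- rep$severity_fits[[g]]
  cat(sprintf("\n%s: %d ROIs with p < 0.05 (uncorrected) severity association; ",
              g, sum(f$significant_uncorrected)))
  cat(sprintf("median slope in affected parcels %.2f\n",
              median(f$slope[f$parcel %in%
                               cfg$effects[[which(vapply(cfg$effects, `[[`, "",
                                                         "group") == g)]]$affected_rois])))
}
cat("\nAll tables under results/03_experiment/\n")
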