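#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort and example acquisition files.
#
# Generates 19/24/20 subjects (young 20-30, middle-aged 50-62, older 63-74)
# with vascular-risk indicators from a latent 3-factor model, ground-truth
# HRF parameters whose peak amplitude declines by 0.004 per year of age,
# and writes the cohort, the true HRF parameters, and one example
# checkerboard run (events TSV + 4D NIfTI + label volume) under results/.

library(shrf)
SEED <- 1
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(19, 24, 20, seed = SEED)
truth <- generate_true_hrf(cohort, hrf_effect_config(), seed = SEED + 1)
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
write.csv(truth, "results/true_hrf.csv", row.names = FALSE)

cat(sprintf("cohort: %d subjects; mean age by group: %s\n",
            nrow(cohort),
            paste(round(tapply(cohort$age, cohort$age_group, mean), 1),
                  collapse = " / ")))
cat(sprintf("hypertension prevalence by group: %s\n",
            paste(round(100 * tapply(cohort$hypertension, cohort$age_group,
                                     mean)), collapse = "% / ")))
cat(sprintf("memory accuracy by group: %s\n",
            paste(round(tapply(cohort$memory_accuracy, cohort$age_group,
                               mean), 2), collapse = " / ")))
cat(sprintf("true HRF peak amplitude: %.3f (young) vs %.3f (old)\n",
            mean(truth$peak_amplitude[cohort$age_group == "young"]),
            mean(truth$peak_amplitude[cohort$age_group == "old"])))

# one example run on disk, in the formats the readers consume
design <- generate_checkerboard_design(seed = SEED + 100 + 1)
run <- generate_bold(design, truth[1, ], seed = SEED + 200 + 1)
write_events(design, "results/example_checkerboard_events.tsv")
write_bold(run, "results/example_checkerboard_bold.nii",
           labels_path = "results/example_region_labels.nii")
cat(sprintf("example run: %d events, %d volumes at TR %.2f s, %d voxels\n",
            length(design$onsets), design$n_volumes, design$tr,
            nrow(run$data)))
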