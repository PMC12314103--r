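#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 14 surgeons (7 experienced,
# 7 novice by latent skill), 2 suturing trials each, with per-frame
# tip tracks for both hands, vessel-area series, phase annotations
# (A-D) and three-rater rubric scores. Files land in scratch/cohort/;
# a small per-surgeon summary goes to results/.

source("analysis/00_common.R")

ds <- generate_cohort(synthetic_config(seed = COHORT_SEED), dir = COHORT_DIR)

n_frames <- sum(vapply(ds$va, nrow, integer(1)))
cat(sprintf("cohort: %d surgeons x %d trials, %d vessel-area frames total\n",
            nrow(ds$truth), max(ds$trials$trial_index), n_frames))
cat(sprintf("latent skill: %d high-cluster, %d low-cluster surgeons\n",
            sum(ds$truth$label == "good"), sum(ds$truth$label == "poor")))

readr::write_csv(ds$truth, file.path(RESULTS_DIR, "cohort_truth.csv"))
cat("wrote", file.path(RESULTS_DIR, "cohort_truth.csv"),
    "and cohort CSVs under", COHORT_DIR, "\n")
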