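#!/usr/bin/env Rscript
# Extract the AI-style video parameters for every trial: CV-VA,
# Max-dVA and No. of TDE from the vessel-area series (threshold 1.13 on
# the relative area change per second), and PD / NJI per hand from the
# tip tracks - each over phases A-D and the whole trial - then average
# the first two trials into each surgeon's representative value.

source("analysis/00_common.R")

ds <- load_cohort()
params <- extract_cohort_parameters(ds)
cohort <- build_cohort_table(params)

write_parameter_table(params, file.path(RESULTS_DIR, "trial_parameters.csv"))
write_parameter_table(cohort, file.path(RESULTS_DIR, "cohort_table.csv"))

whole <- params[params$phase == "All", ]
cat(sprintf("extracted %d parameter cells (%d missing) over %d trials\n",
            nrow(params), sum(is.na(params$value)),
            dplyr::n_distinct(params$trial)))
cat(sprintf("whole-trial ranges: PD %.0f-%.0f px, NJI %.2g-%.2g, TDE %d-%d\n",
            min(whole$value[whole$metric == "pd"], na.rm = TRUE),
            max(whole$value[whole$metric == "pd"], na.rm = TRUE),
            min(whole$value[whole$metric == "nji"], na.rm = TRUE),
            max(whole$value[whole$metric == "nji"], na.rm = TRUE),
            as.integer(min(whole$value[whole$metric == "n_tde"], na.rm = TRUE)),
            as.integer(max(whole$value[whole$metric == "n_tde"], na.rm = TRUE))))
cat("wrote trial_parameters.csv and cohort_table.csv under results/\n")
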