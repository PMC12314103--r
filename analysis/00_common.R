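# Shared settings for the analysis scripts. Run the scripts from the
# repository root, in order; each regenerates what it needs, so any one
# can also be run standalone.

library(microskill)

COHORT_SEED <- 20269L
COHORT_DIR <- "scratch/cohort"
RESULTS_DIR <- "results"

dir.create(RESULTS_DIR, showWarnings = FALSE)

# The synthetic study cohort: 14 surgeons, 2 trials each, bimodal skill.
# Deterministic in COHORT_SEED, so reading the cached copy and
# regenerating are equivalent.
load_cohort <- function() {
  if (file.exists(file.path(COHORT_DIR, "trials.csv")))
    return(read_cohort(COHORT_DIR))
  generate_cohort(synthetic_config(seed = COHORT_SEED), dir = COHORT_DIR)
}
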