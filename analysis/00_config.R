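# Shared settings for the analysis drivers. Every stage reads its inputs
# from results/cohort/, which 01_simulate_cohort.R writes; rerunning 01
# with the same seed reproduces the files byte for byte.

library(oserve)

ANALYSIS_SEED <- 20150213L          # cohort seed used throughout
N_FAMILIES <- 400L                  # gene families in the simulated cohort

COHORT_DIR <- "results/cohort"
TABLE_DIR <- "results/tables"

analysis_config <- function() sim_config(seed = ANALYSIS_SEED, n_families = N_FAMILIES)

dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)
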