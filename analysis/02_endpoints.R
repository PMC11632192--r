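#!/usr/bin/env Rscript
# Compute the per-session endpoint table: SOL, microsleep rate/duration,
# sleepiness score average/slope/intercept, theta/alpha average/slope/
# intercept (through the full qEEG chain), inverse SOL, the isSiesta
# indicator and the SOL > 1 min slope-eligibility flag.
#
# The study is re-derived deterministically from the seed used in
# 01_simulate.R (simulation is idempotent), so this script does not depend
# on the session files being present.

suppressPackageStartupMessages(library(mwtbio))

STUDY_SEED <- 20240
dir.create("results", showWarnings = FALSE)

study <- simulate_study(default_study_design(n_per_cohort = 4, seed = STUDY_SEED),
                        with_eeg = TRUE)
endpoints <- compile_endpoints(study)
write.csv(endpoints, "results/endpoints.csv", row.names = FALSE)

cat(sprintf("endpoint table: %d sessions x %d columns\n",
            nrow(endpoints), ncol(endpoints)))
cat(sprintf("censored SOL: %d; slope-eligible (SOL > 1 min): %d\n",
            sum(endpoints$sol_censored), sum(endpoints$slope_analysis_eligible)))
agg <- aggregate(cbind(sol_min, microsleep_rate, sleepiness_slope,
                       theta_alpha_slope) ~ cohort + day, endpoints, mean)
cat("\ncohort x day means:\n")
print(agg, digits = 3)
cat("\nwrote results/endpoints.csv\n")
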