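#!/usr/bin/env Rscript
# Repeated-measures correlations between the slope endpoints and inverse
# SOL, restricted to sessions with SOL > 1 minute (the reliability filter
# for slope estimates). The slope-vs-inverse-SOL coupling is the
# threshold-crossing mechanism: with a shared starting sleepiness, the time
# to cross the sleep-onset threshold is inversely proportional to the
# log-sleepiness growth rate.

suppressPackageStartupMessages(library(mwtbio))

endpoints <- read.csv("results/endpoints.csv")
el <- endpoints[endpoints$slope_analysis_eligible, ]
cat(sprintf("%d of %d sessions eligible (SOL > 1 min)\n",
            nrow(el), nrow(endpoints)))

pairs <- rbind(
  c("sleepiness_slope", "inverse_sol"),
  c("theta_alpha_slope", "inverse_sol"),
  c("sleepiness_slope", "theta_alpha_slope"),
  c("sleepiness_avg", "inverse_sol"),
  c("microsleep_rate", "inverse_sol"))
rows <- apply(pairs, 1, function(pr) {
  res <- rmcorr(el, pr[1], pr[2])
  data.frame(x = pr[1], y = pr[2], r = res$r, df = res$df, p = res$p,
             n_obs = res$n_obs)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/rmcorr.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)
cat("\nwrote results/rmcorr.csv\n")
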