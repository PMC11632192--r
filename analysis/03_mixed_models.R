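#!/usr/bin/env Rscript
# Mixed-effects analysis of every endpoint: the study model
#   endpoint ~ day * treatment + isSiesta + (1 | participant),
# REML, with change-from-baseline contrasts per treatment arm and the joint
# Wald test of the day x treatment interaction.

suppressPackageStartupMessages(library(mwtbio))

endpoints <- read.csv("results/endpoints.csv")
outcomes <- c("sol_min", "inverse_sol", "microsleep_rate", "microsleep_duration",
              "sleepiness_avg", "sleepiness_slope", "sleepiness_intercept",
              "theta_alpha_avg", "theta_alpha_slope", "theta_alpha_intercept")

all_est <- list(); all_ct <- list()
for (y in outcomes) {
  fit <- tryCatch(fit_lmm(endpoints, model_design(y)), error = function(e) NULL)
  if (is.null(fit)) { cat(sprintf("%-22s skipped (fit error)\n", y)); next }
  w <- wald_test(fit)
  cat(sprintf("%-22s converged=%s  day:treatment Wald p = %.3g\n",
              y, fit$converged, w$p))
  est <- fit$estimates; est$endpoint <- y
  ct <- contrasts_change_from_baseline(fit); ct$endpoint <- y
  all_est[[y]] <- est; all_ct[[y]] <- ct
}
write.csv(do.call(rbind, all_est), "results/lmm_estimates.csv", row.names = FALSE)
write.csv(do.call(rbind, all_ct), "results/lmm_contrasts.csv", row.names = FALSE)

ct <- do.call(rbind, all_ct)
sig <- ct[ct$endpoint == "sleepiness_slope" & ct$treatment == "active", ]
cat("\ntreated-arm change-from-baseline, sleepiness slope:\n")
print(sig[, c("day", "estimate", "se", "z", "p")], digits = 3, row.names = FALSE)
cat("\nwrote results/lmm_estimates.csv and results/lmm_contrasts.csv\n")
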