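#!/usr/bin/env Rscript
# Stage 5: parameter-recovery checks behind the headline analysis.
#
# (a) Monthly air-temperature slope: 10 replicates of the 130-site x
#     10-month design, reporting mean bias and 95% Wald CI coverage.
# (b) Daily CAR(1) parameter: 5 replicates at 50 sites x 120 days with
#     phi = 0.8.
# These are smaller editions of the studies the test suite runs in full.

library(streamtemp)

seed <- 977

truth_m <- truth_params("month")
spec_m <- lmm_spec(env_covariates(), "month", "none", "REML")
est <- se <- numeric(10)
for (r in 1:10) {
  sim <- simulate_paired_obs(130, 10, truth_m, seed = seed + r)
  f <- fit_lmm(sim$paired, sim$sites, spec_m)
  est[r] <- f$beta[["air"]]
  se[r] <- sqrt(f$beta_cov["air", "air"])
}
cat(sprintf("monthly air slope: truth %.3f, mean estimate %.3f (bias %+.2f%%)\n",
            truth_m$beta_air, mean(est),
            100 * (mean(est) - truth_m$beta_air) / truth_m$beta_air))
cat(sprintf("95%% Wald CI coverage: %d/10\n",
            sum(abs(est - truth_m$beta_air) <= qnorm(0.975) * se)))

truth_d <- truth_params("day", phi = 0.8)
spec_d <- lmm_spec(env_covariates(), "day", "car1", "ML")
phis <- vapply(1:5, function(r) {
  sim <- simulate_paired_obs(50, 120, truth_d, seed = seed + 100 + r)
  fit_lmm(sim$paired, sim$sites, spec_d)$phi
}, numeric(1))
cat(sprintf("daily CAR(1): truth 0.800, estimates %s (mean %.3f)\n",
            paste(sprintf("%.3f", phis), collapse = " "), mean(phis)))
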