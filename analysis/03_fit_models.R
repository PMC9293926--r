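#!/usr/bin/env Rscript
# Stage 3: fit the air-water temperature mixed models at both timescales.
#
# Daily model: water ~ air + catchment + five environmental covariates,
# random intercept and air slope per site, continuous AR(1) within-site
# errors. Monthly model: same fixed/random structure, independent errors.
# Reports a coefficient table (between-within df), variance components,
# marginal/conditional R2, ICC, population RMSE, VIFs, and the ML
# likelihood-ratio comparison against the air + catchment baseline.

library(streamtemp)
library(jsonlite)

out_dir <- "results"
sites <- read.csv(file.path(out_dir, "sites.csv"))

for (unit in c("day", "month")) {
  paired <- read.csv(file.path(out_dir, sprintf("paired_%s.csv", unit)))
  spec_full <- lmm_spec(env_covariates(), timescale = unit, method = "REML")
  spec_base <- lmm_spec(character(0), timescale = unit, method = "REML")

  cat(sprintf("\n== %s model (%d paired observations, %d sites) ==\n",
              unit, nrow(paired), length(unique(paired$site_id))))
  fit <- fit_lmm(paired, sites, spec_full)
  print(fit)

  base <- fit_lmm(paired, sites, spec_base)
  lrt <- lrt_compare(base, fit)
  cat(sprintf("baseline R2m %.3f -> full R2m %.3f; ML LRT chi2=%.1f df=%d p=%.2g\n",
              r2_nakagawa(base)[["r2_marginal"]],
              r2_nakagawa(fit)[["r2_marginal"]], lrt$chi2, lrt$df, lrt$p))

  met <- metrics_report(fit)
  cat(sprintf("population RMSE %.2f degC; VIF max %.2f (flagged: %s)\n",
              met$rmse_population, max(met$vif$vif),
              if (length(met$flagged)) paste(met$flagged, collapse = ", ")
              else "none"))

  report <- list(
    unit = unit, n_obs = fit$n_obs, n_sites = fit$n_sites,
    fixed = fixed_inference(fit),
    random = list(sigma = fit$sigma, tau00 = fit$tau00, tau11 = fit$tau11,
                  phi = fit$phi, icc = met$icc_adjusted),
    r2 = list(marginal = met$r2_marginal,
              conditional = met$r2_conditional),
    rmse = met$rmse_population,
    baseline_r2_marginal = unname(r2_nakagawa(base)[["r2_marginal"]]),
    lrt = lrt[c("chi2", "df", "p")],
    vif = met$vif
  )
  write_json(report, file.path(out_dir, sprintf("model_%s.json", unit)),
             auto_unbox = TRUE, digits = NA, force = TRUE)
}
cat("\nwrote model_day.json and model_month.json\n")
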