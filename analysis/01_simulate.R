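#!/usr/bin/env Rscript
# Stage 1: simulate the monitoring network.
#
# Generates a 130-station, four-catchment paired air-water logger network:
# a site covariate table and two summer seasons (June-September 2018-2019)
# of hourly records per site, with ~1.8% burst missingness injected, the
# daily-scale truth driving the water channel. Writes sites.csv and the
# hourly series to results/hourly/.

library(streamtemp)

seed <- 20180601
out_dir <- "results"
dir.create(file.path(out_dir, "hourly"), recursive = TRUE,
           showWarnings = FALSE)

sites <- generate_sites(n_sites = 130, n_catchments = 4, seed = seed)
write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
cat(sprintf("sites: %d over %d catchments (%s)\n", nrow(sites),
            nlevels(sites$catchment),
            paste(levels(sites$catchment), collapse = ", ")))
print(summary(sites[, c("cultivated", "volc_quaternary", "elevation",
                        "riparian_forest")]))

truth <- truth_params("day")
cat(sprintf("\ndaily truth: alpha=%.3f beta_air=%.3f sigma=%.3f tau00=%.3f phi=%.3f\n",
            truth$alpha, truth$beta_air, truth$sigma, truth$tau00,
            truth$phi))

n_rows <- 0
for (j in seq_len(nrow(sites))) {
  site <- sites[j, ]
  per_year <- lapply(2018:2019, function(yr) {
    air <- generate_air_series(site, sprintf("%d-06-01", yr),
                               sprintf("%d-09-30", yr), seed = seed + yr)
    ser <- generate_hourly_water(site, air, truth, seed = seed)
    inject_missingness(ser, rate = 0.018, seed = seed + yr)
  })
  ser <- do.call(rbind, per_year)
  n_rows <- n_rows + nrow(ser)
  # explicit ISO-8601 so midnight rows keep their time part
  out <- data.frame(timestamp = format(ser$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    air = ser$air, water = ser$water)
  write.csv(out, file.path(out_dir, "hourly",
                           sprintf("series_%s.csv", site$site_id)),
            row.names = FALSE, na = "")
}
cat(sprintf("wrote %d hourly records for %d sites under %s/hourly\n",
            n_rows, nrow(sites), out_dir))
cat(sprintf("missing air fraction: %.3f\n", {
  f <- list.files(file.path(out_dir, "hourly"), full.names = TRUE)[1:10]
  mean(sapply(f, function(p) mean(is.na(read.csv(p)$air))))
}))
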