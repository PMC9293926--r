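#!/usr/bin/env Rscript
# Stage 2: aggregate the hourly series to mean daily and monthly paired
# observations under the 75% completeness rule.
#
# Reads results/sites.csv and results/hourly/series_*.csv (stage 1),
# aggregates each channel to calendar days and months (a unit's mean is
# kept only if at least 75% of its hours are present; monthly means come
# from the hourly data, never from daily means), pairs the channels, and
# writes paired_day.csv / paired_month.csv.

library(streamtemp)

out_dir <- "results"
files <- list.files(file.path(out_dir, "hourly"), pattern = "^series_",
                    full.names = TRUE)
stopifnot(length(files) > 0)

hourly <- do.call(rbind, lapply(files, function(f) {
  sid <- sub("^series_(.*)\\.csv$", "\\1", basename(f))
  d <- read.csv(f)
  data.frame(site_id = sid,
             timestamp = as.POSIXct(d$timestamp,
                                    format = "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"),
             air = d$air, water = d$water)
}))
cat(sprintf("read %d hourly records from %d sites\n", nrow(hourly),
            length(files)))

for (unit in c("day", "month")) {
  agg <- aggregate_hourly(hourly, unit, threshold = 0.75)
  paired <- pair_observations(agg)
  dropped <- sum(is.na(agg$mean_air) | is.na(agg$mean_water))
  cat(sprintf("%s: %d aggregated periods, %d below threshold or unpaired, %d valid pairs\n",
              unit, nrow(agg), dropped, nrow(paired)))
  write.csv(paired, file.path(out_dir, sprintf("paired_%s.csv", unit)),
            row.names = FALSE)
}
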