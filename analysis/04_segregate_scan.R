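#!/usr/bin/env Rscript
# Stage 4: pristine-marine segregation and the distance-threshold scan.
#
# On the 'mixed' campaign (terrestrial source near a meridional coast),
# computes the distance of every track point to the coastline, splits the
# record at 200 km, and scans candidate thresholds 25-500 km for the point
# where the correlation between hourly fluorescent concentration and wind
# speed stabilises -- the operational definition of "pristine marine".

library(pbapr)

dir.create("results", showWarnings = FALSE)
camp <- generate_campaign(scenario_preset("mixed"))
p <- camp$preset
th <- compute_ft_stats(camp$ft)
lab <- classify_particles(camp$particles, th, 3)
hh <- time_binned_series(camp$particles, lab, bin_width_s = 3600,
                         flow_lpm = p$flow_lpm * p$duty_cycle,
                         t_start = camp$track$timestamp[1])

seg <- segregate(camp$track, camp$coastline, threshold_km = 200)
utils::write.csv(
  data.frame(timestamp = as.numeric(seg$timestamp),
             distance_to_land_km = seg$distance_to_land_km,
             category = as.character(seg$category)),
  "results/segregation_mask_mixed.csv", row.names = FALSE)
message(sprintf("pristine-marine fraction of the track at 200 km: %.1f%%",
                100 * mean(seg$category == "pristine_marine")))

st <- as.numeric(seg$timestamp)
idx <- findInterval(as.numeric(hh$bin_start), st, all.inside = TRUE)
ok <- hh$n_total > 0
sc <- scan_distance_threshold(hh$conc_fluor[ok],
                              camp$track$u10n[idx][ok],
                              seg$distance_to_land_km[idx][ok],
                              thresholds = seq(25, 500, by = 25))
utils::write.csv(sc$curve, "results/threshold_scan_mixed.csv", row.names = FALSE)
message(sprintf(
  "correlation rises from R = %.2f at 25 km to %.2f at 500 km; plateau at %g km",
  sc$curve$r[1], sc$curve$r[nrow(sc$curve)], sc$plateau_km))

near <- seg$distance_to_land_km[idx][ok] <= 200
message(sprintf(
  "median fluorescent concentration: %.1f L^-1 terrestrially influenced vs %.1f L^-1 pristine",
  median(hh$conc_fluor[ok][near]), median(hh$conc_fluor[ok][!near])))
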