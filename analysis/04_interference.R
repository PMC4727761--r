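#!/usr/bin/env Rscript
# Step 4 — interference study: how an uncorrelated co-extracted component
# (a red-clover-like interferent sharing the analyte windows) degrades the
# total-isoflavone calibration as its level rises.
#
# For each interferent level, 10 independent small campaigns are simulated
# and calibrated; the mean LOO SEP% is reported. Rising SEP% with
# interferent amplitude is the mechanism by which foreign isoflavones can
# push a preparation's IR-predicted content away from its declaration.

library(ftirquant)

bs <- default_band_sets()
levels <- c(0, 0.025, 0.05, 0.1, 0.15)
seeds <- 1:10

rows <- lapply(levels, function(L) {
  seps <- vapply(seeds, function(s) {
    d <- sim_design(bs$analytes, bs$interferent, bs$matrix,
                    base_levels = c(daidzin = 0.025, genistin = 0.048,
                                    glycitin = 0.012),
                    spike_volumes = seq(50, 425, by = 75),
                    n_base = 4, interferent_level = L, seed = 1000 + s)
    dat <- generate_calibration_set(d)
    calibrate_analyte(dat$set, dat$reference, "total",
                      default_recipes()$total, max_lv = 8)$report$sep_percent
  }, numeric(1))
  data.frame(interferent_level = L, mean_sep_percent = mean(seps),
             sd_sep_percent = sd(seps))
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/interference_sep.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
message(sprintf("mean SEP%% rises from %.2f to %.2f across the level sweep",
                tab$mean_sep_percent[1], tab$mean_sep_percent[nrow(tab)]))
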