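#!/usr/bin/env Rscript
# Step 1 — build the study-scale simulated calibration campaign.
#
# The design emulates a standard-addition calibration for three isoflavone
# glycosides in a soy-extract matrix: 5 replicate series of 10 unspiked
# aliquots, 18 spike volumes (25-450 ul of 0.244 mg/mL standard stock) per
# analyte, and 3 two-analyte fractions: 5 x (10 + 3x18 + 3) = 335 samples.
# Writes the design, the reference-concentration table and a few example
# spectra under results/simulation/.

library(ftirquant)

out_dir <- "results/simulation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- default_paper_like_design(seed = 1)
print(design)
write_design_yaml(design, file.path(out_dir, "design.yaml"))

dat <- generate_calibration_set(design)
message("generated ", nrow(dat$set$matrix), " spectra on ",
        length(dat$set$grid), " wavenumbers (",
        max(dat$set$grid), "-", min(dat$set$grid), " cm-1)")

write.csv(dat$reference, file.path(out_dir, "reference.csv"),
          row.names = FALSE)
write.csv(dat$truth, file.path(out_dir, "ground_truth.csv"),
          row.names = FALSE)

# a handful of representative spectra in both exchange formats
examples <- c("base01_r1", "spike_genistin_0450ul_r1", "frac_no_daidzin_r1")
for (id in examples) {
  s <- spectrum(id, dat$set$grid, dat$set$matrix[id, ])
  write_spectrum_csv(s, file.path(out_dir, paste0(id, ".csv")))
  write_jcamp(s, file.path(out_dir, paste0(id, ".jdx")))
}
message("example spectra written: ", paste(examples, collapse = ", "))

rng <- range(dat$reference$total)
message(sprintf("total isoflavone range %.3f-%.3f mg per 500 ul (mean %.3f)",
                rng[1], rng[2], mean(dat$reference$total)))
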