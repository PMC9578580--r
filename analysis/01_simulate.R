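#!/usr/bin/env Rscript
# Stage 1: generate the synthetic strain panel.
#
# Emulates the study design: 12 strains in three dynamic classes (blue =
# inefficient growers / strong communicators; red = efficient but rapidly
# dying; green = efficient growers / poor communicators), 3-7 CFU replicates
# per strain on the coarse 9-point schedule, paired OD reads every 10 min,
# multiplicative count noise.

library(qsgrowth)

seed <- 1
dir.create("results", showWarnings = FALSE)

panel <- generate_archetype_panel(noise_cv = 0.15, with_od = TRUE, seed = seed)
write_growth_csv(rbind(panel$data, panel$od), "results/panel_data.csv")
write.csv(panel$truth, "results/panel_truth.csv", row.names = FALSE)

cat("Simulated", length(unique(panel$data$strain)), "strains;",
    nrow(panel$data), "CFU and", nrow(panel$od), "OD measurements.\n")
fc <- normalize_fold_change(panel$data)
peak <- tapply(fc$value, fc$strain, max)
cls <- panel$truth$class[match(names(peak), panel$truth$strain)]
cat("Median peak fold change by class:\n")
print(round(tapply(peak, cls, median)))
cat("Written: results/panel_data.csv, results/panel_truth.csv\n")
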