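#!/usr/bin/env Rscript
# Stage 2: maximal growth rates (from OD) and death rates (from the CFU
# decline) per strain and replicate — the first stage of the two-stage
# fitting protocol.

library(qsgrowth)

data <- read_growth_csv("results/panel_data.csv")
truth <- read.csv("results/panel_truth.csv")

rates <- rate_table(data)
write.csv(rates, "results/rates.csv", row.names = FALSE)

med <- function(w) tapply(rates$rate[rates$which == w], rates$strain[rates$which == w], median)
g <- med("growth"); d <- med("death")
cls <- truth$class[match(names(g), truth$strain)]
cat("Median maximal growth rate by class (1/h):\n")
print(round(tapply(g, cls, median), 3))
cat("Median death rate by class (1/h):\n")
print(round(tapply(d[names(g)], cls, median), 3))
cat("Growth rates vary far less across strains than death rates",
    sprintf("(CV %.2f vs %.2f).\n",
            dispersion_stats(g, names(g))$cv_pooled,
            dispersion_stats(d, names(d))$cv_pooled))
cat("Written: results/rates.csv\n")
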