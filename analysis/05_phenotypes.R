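#!/usr/bin/env Rscript
# Stage 5: phenotype analysis on the fitted kinetic parameters —
# time-series clustering of the median curves, PCA of the trait space,
# correlations, archetype distances, and dispersion statistics.

library(qsgrowth)

data <- read_growth_csv("results/panel_data.csv")
truth <- read.csv("results/panel_truth.csv")
fit_tab <- read.csv("results/fits.csv")
cfu <- data[data$modality == "CFU", ]

mt <- median_trajectories(cfu)
cl <- cluster_timeseries(mt, k = 3)
labels <- cl$labels
cls <- truth$class[match(names(labels), truth$strain)]
ari <- mclust::adjustedRandIndex(labels, cls)
write.csv(data.frame(strain = names(labels), cluster = labels, class = cls),
          "results/clusters.csv", row.names = FALSE)
cat(sprintf("Time-series clustering recovers the generating classes (ARI %.2f).\n", ari))

rq <- fit_tab[fit_tab$model == "RQ", ]
rep <- phenotype_report(rq)
write.csv(cbind(strain = rownames(rep$table$median), rep$table$median),
          "results/phenotype_medians.csv", row.names = FALSE)
vp3 <- rep$pca3$log_z$variance_pct
vp5 <- rep$pca5$log_z$variance_pct
cat(sprintf("3-variable PCA (max FC, K_qs, 1/B): PC1 explains %.1f%%.\n", vp3[1]))
cat(sprintf("5-parameter PCA: first two axes %.1f%%, first three %.1f%%.\n",
            sum(vp5[1:2]), sum(vp5[1:3])))
co <- rep$correlations$strain
cat(sprintf("Strain-level Pearson (log10 scale): maxFC-K_qs rho=%.2f (p=%.3f); K_qs-1/B rho=%.2f (p=%.3f).\n",
            co$maxfc_kqs$rho, co$maxfc_kqs$p_value,
            co$kqs_invB$rho, co$kqs_invB$p_value))
write.csv(data.frame(
  pair = c("maxfc_kqs", "maxfc_invB", "kqs_invB"),
  rho = sapply(co, `[[`, "rho"), p = sapply(co, `[[`, "p_value")),
  "results/correlations.csv", row.names = FALSE)

# archetype (class-median) trait distances in the z-scored 5D space
med <- rep$table$median
med$class <- truth$class[match(rownames(med), truth$strain)]
cm <- do.call(rbind, lapply(split(med[, c("d", "K_qs", "inv_B", "K_r", "lambda_max")],
                                  med$class), function(d) apply(d, 2, median)))
full <- rbind(med[, c("d", "K_qs", "inv_B", "K_r", "lambda_max")], as.data.frame(cm))
dist_rows <- lapply(list(c("blue", "red"), c("blue", "green"), c("red", "green")),
  function(pair) {
    pd <- phenotypic_distance(full, pair[1], pair[2])
    cat(sprintf("%s-%s archetypes separated by: %s (distance %.1f z-units).\n",
                pair[1], pair[2], paste(pd$separating, collapse = ", "), pd$scalar))
    data.frame(pair = paste(pair, collapse = "-"), scalar = pd$scalar,
               separating = paste(pd$separating, collapse = ";"))
  })
write.csv(do.call(rbind, dist_rows), "results/archetype_distances.csv", row.names = FALSE)

cat("Written: results/clusters.csv, results/phenotype_medians.csv,",
    "results/correlations.csv, results/archetype_distances.csv\n")
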