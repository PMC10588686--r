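#!/usr/bin/env Rscript
# Stage 5: trait-space PCAs and the specialization regressions.
#
# PCA of the hummingbird dominance/morphology space and of the floral
# trait space, then linear regressions of species-level d' on David's
# score, rank index, bill length and bill curvature.

suppressPackageStartupMessages(library(dominet))
hb <- read.csv("results/data/hummingbird_traits.csv")
pl <- read.csv("results/data/plant_traits.csv")
dom <- read.delim("results/dominance.tsv")
net <- read.delim("results/network_species.tsv")
hb$ds <- dom$ds[match(hb$species, dom$species)]

hb_pca <- pca(data.frame(ds = hb$ds, weight = hb$weight,
                         bill_length = hb$bill_length,
                         bill_curvature = hb$bill_curvature,
                         row.names = hb$species))
cat(sprintf("Hummingbird PCA: PC1 %.1f%%, PC1+2 %.1f%% of variance; top PC1 contributor: %s.\n",
            hb_pca$percent_variance[1], hb_pca$cumulative_percent[2],
            rownames(hb_pca$contributions)[
              which.max(hb_pca$contributions[, 1])]))

cal <- calories_per_flower(pl$nectar_volume,
                           concentration_brix = pl$nectar_concentration)
pl_pca <- pca(data.frame(nectar_volume = pl$nectar_volume,
                         nectar_concentration = pl$nectar_concentration,
                         calories = cal,
                         corolla_length = pl$corolla_length,
                         corolla_diameter = pl$corolla_diameter,
                         corolla_curvature = pl$corolla_curvature,
                         row.names = pl$species))
cat(sprintf("Floral PCA: PC1 %.1f%%, PC1+2 %.1f%% of variance.\n",
            pl_pca$percent_variance[1], pl_pca$cumulative_percent[2]))

write.table(cbind(variable = rownames(hb_pca$contributions),
                  as.data.frame(round(hb_pca$contributions, 2))),
            "results/pca_hummingbird_contributions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cbind(variable = rownames(pl_pca$contributions),
                  as.data.frame(round(pl_pca$contributions, 2))),
            "results/pca_floral_contributions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

d <- net$d_prime[match(hb$species, net$species)]
ridx <- dom$rank_index[match(hb$species, dom$species)]
regs <- list(ds = linreg(hb$ds, d),
             rank_index = linreg(ridx, d),
             bill_length = linreg(hb$bill_length, d),
             bill_curvature = linreg(hb$bill_curvature, d))
rtab <- do.call(rbind, lapply(names(regs), function(nm) {
  r <- regs[[nm]]
  data.frame(predictor = nm, slope = r$slope, r_squared = r$r_squared,
             F = r$F, df1 = r$df1, df2 = r$df2, p_value = r$p_value)
}))
write.table(rtab, "results/regressions.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
for (i in seq_len(nrow(rtab)))
  cat(sprintf("d' ~ %-12s R2 = %.2f, F(%d,%d) = %.2f, p = %.4g\n",
              rtab$predictor[i], rtab$r_squared[i], rtab$df1[i],
              rtab$df2[i], rtab$F[i], rtab$p_value[i]))
cat("Wrote PCA contribution tables and results/regressions.tsv.\n")
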