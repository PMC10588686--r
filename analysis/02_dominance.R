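#!/usr/bin/env Rscript
# Stage 2: dominance hierarchy from the agonistic win/loss matrix.
#
# David's score ranks the species; pathway-based dominance probabilities
# give each species a certainty (DC) for its position; species stuck at
# DC = 0.5 (too few contests) are flagged and the hierarchy recomputed
# without them.

suppressPackageStartupMessages(library(dominet))
W <- read_matrix_csv("results/data/agonistic_matrix.csv",
                     square_required = TRUE)

summ <- tournament_summary(W)
cat(sprintf("Tournament: %d interactions, %.1f per individual, %.1f per dyad, %.3f of dyads unknown.\n",
            summ$total_interactions, summ$per_individual, summ$per_dyad,
            summ$prop_unknown))

dom <- dominance_analysis(W, seed = 1)
tab <- data.frame(species = dom$labels, ds = dom$ds, rank = dom$ranks,
                  rank_index = dom$rank_index, dc_mean = dom$dc_mean,
                  dc_sd = dom$dc_sd)
tab <- tab[order(tab$rank), ]
write.table(tab, "results/dominance.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("Top three:", paste(head(tab$species, 3), collapse = ", "),
    "| bottom:", tail(tab$species, 1), "\n")
low <- tab$species[tab$dc_mean <= 0.5]
if (length(low)) {
  cat("Low-certainty species (DC <= 0.5):", paste(low, collapse = ", "),
      "-> re-ranking without them.\n")
  W2 <- filter_uncertain_species(W, dom, 0.5)
  dom2 <- dominance_analysis(W2, seed = 1)
  write.table(data.frame(species = dom2$labels, ds = dom2$ds,
                         rank = dom2$ranks, dc_mean = dom2$dc_mean),
              "results/dominance_filtered.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
} else {
  cat("All species ranked with DC > 0.5.\n")
}
cat("Wrote results/dominance.tsv.\n")
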