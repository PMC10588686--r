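#!/usr/bin/env Rscript
# Stage 1: generate the synthetic community standing in for the field data.
#
# Emulates the study's sampling conditions: 13 hummingbird and 10 plant
# species, 477 agonistic contests with ~55% of dyads never observed, and
# 2,272 flower visits driven mostly by abundance with secondary
# morphological-match and dominance components. Writes the matrices as
# labelled CSVs plus a JSON sidecar of the ground-truth parameters.

suppressPackageStartupMessages(library(dominet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

scen <- make_scenario(seed = seed)
W <- simulate_tournament(scen)
traits <- simulate_traits(scen)
V <- simulate_visitation(scen, traits)

write_matrix_csv(W, "results/data/agonistic_matrix.csv")
write_matrix_csv(V, "results/data/visitation_matrix.csv")
write.csv(traits$hummingbirds, "results/data/hummingbird_traits.csv",
          row.names = FALSE)
write.csv(traits$plants, "results/data/plant_traits.csv", row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, latent_dominance = scen$latent_dominance,
       weights = c(neutral = scen$weight_neutral,
                   match = scen$weight_match,
                   dominance = scen$weight_dominance),
       steepness = scen$steepness,
       dyad_observability = scen$dyad_observability),
  "results/data/ground_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated community (seed %d): %d contests over %d species, %d visits over a %dx%d network.\n",
            seed, sum(W), nrow(W), sum(V), nrow(V), ncol(V)))
cat(sprintf("Unobserved dyads: %.1f%%.\n",
            100 * tournament_summary(W)$prop_unknown))
cat("Wrote matrices, trait tables and ground truth under results/data/.\n")
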