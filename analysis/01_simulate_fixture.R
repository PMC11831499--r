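#!/usr/bin/env Rscript

# Generate the synthetic nodulation study fixture (2 genotypes x 3 tissues x
# 2 treatments x 3 replicates) with planted NR features, a genotype-driven
# lncRNA module, and planted ceRNA triplets. Writes results/fixture/.
#
# Usage: Rscript analysis/01_simulate_fixture.R [--seed <int>]

library(nodcerna)

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[which(args == "--seed") + 1])
} else 42L

config <- sim_config(seed = seed)
truth <- generate_truth(config)
sim <- simulate_counts(truth)
manifest <- write_fixture(truth, sim, file.path("results", "fixture"))

message("fixture written to results/fixture (seed ", seed, "):")
message(paste(sprintf("  %-24s %s", manifest$file, manifest$md5),
              collapse = "\n"))
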