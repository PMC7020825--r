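#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study population and survey data.
#
# Emulates the field design: a 8x8 grid of 9-ha territories held by breeder
# pairs (occasionally a lone non-breeding dominant), 0-7 helpers on breeder
# territories, playback points near territory-boundary intersections sampled
# twice a week for 12 weeks, stage-specific foray behaviour (helpers foray
# most, breeders not at all), plus opportunistic aggregations of forayers
# from non-adjacent territories. Writes the bundle consumed by the later
# stages.

library(foraynet)

seed <- 42
out <- "results/synthetic-study"

study <- simulate_study(synthetic_config(), seed = seed)
export_bundle(study, out)

cat("Simulated study (seed ", seed, "):\n", sep = "")
print(study$gbi)
cat("Stages:\n")
print(table(study$attrs$stage, study$attrs$sex))
cat("Sampling points:", nrow(study$points), "\n")
cat("Bundle written to ", out, "\n", sep = "")
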