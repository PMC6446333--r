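#!/usr/bin/env Rscript
# Simulate the study cohort: a 55K-style array (51,159 features) over the
# 21 wheat chromosomes, genotyped on two wheat parents, the alien donor,
# and three whole-chromosome substitution lines sharing 4B. Default rates:
# 57.7% of markers cross-hybridize with the donor, ~1.2% background
# missingness (7.9%/8.3% on the parent-divergent 2D/7B), and retention on
# the substituted chromosome tuned so ~60% of 4B markers go missing.

suppressPackageStartupMessages(library(chromsub))
out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20190402)
map <- simulate_marker_map(cfg)
sim <- simulate_genotypes(map, cfg)

write_marker_map(map, file.path(out_dir, "marker_map.tsv"))
write_genotypes(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
write_truth(sim$truth, file.path(out_dir, "truth.json"))

message(sprintf("simulated %d markers x %d samples (%d cross-hybridizing)",
                nrow(map), ncol(sim$genotypes),
                sum(sim$truth$markers$cross_hybridizing)))
message(sprintf("markers on 4B: %d", sum(map$chrom == "4B")))
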