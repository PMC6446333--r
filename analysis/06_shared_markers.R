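#!/usr/bin/env Rscript
# Markers on the substituted chromosome that also interrogate the alien
# homoeolog: called, homozygous, and allele-identical in all three
# substitution lines and the donor. These are candidates for markers
# usable on both the wheat chromosome and its alien replacement, and
# their spread across the chromosome corroborates a whole-chromosome
# (not segmental) substitution.

suppressPackageStartupMessages(library(chromsub))
G <- read_genotypes("results/cohort/genotypes.tsv")
map <- read_marker_map("results/cohort/marker_map.tsv")

set <- filter_shared_homozygous(G, map, "4B",
                                c("SubL1", "SubL2", "SubL3"), "Donor")
print(set)
write_shared_markers(set, "results/shared_4B.tsv")

rep <- coverage_report(set, wheat_chromosome_lengths()[["4B"]],
                       window_spec())
utils::write.table(rep, "results/shared_4B_windows.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("shared markers span %d of %d 10-Mb bins (%d empty)",
                sum(!rep$empty), nrow(rep), sum(rep$empty)))
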