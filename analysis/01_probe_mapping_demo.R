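#!/usr/bin/env Rscript
# Stage 0 of the pipeline: place array-marker flanking sequences on a
# reference assembly by best ungapped match (<= 1 mismatch, E <= 1e-10,
# unique best hit). Chip data ships with flanking sequences, not
# coordinates, so this is how the marker map used by every later stage is
# made. Demonstrated here on a synthetic two-chromosome reference with
# planted probes: 70 unique, 8 planted twice (must be rejected as
# ambiguous), 6 absent (must be no_hit).

suppressPackageStartupMessages(library(chromsub))
set.seed(20190402)
out_dir <- "results/probe_mapping"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

n_unique <- 70; n_dup <- 8; n_absent <- 6
probes <- vapply(seq_len(n_unique + n_dup + n_absent), function(i)
  random_dna(50), character(1))
names(probes) <- sprintf("AX%03d", seq_along(probes))

spacer <- function() random_dna(sample(200:400, 1))
chrA <- paste0(spacer(), paste(vapply(seq_len(n_unique), function(i)
  paste0(probes[i], spacer()), character(1)), collapse = ""))
dups <- probes[n_unique + seq_len(n_dup)]
chrB <- paste0(spacer(),
               paste(vapply(c(dups, dups), function(p)
                 paste0(p, spacer()), character(1)), collapse = ""))
reference <- c(chrA = chrA, chrB = chrB)

res <- build_marker_map(probes, reference, mapping_params())
write_marker_map(res$map, file.path(out_dir, "marker_map.tsv"))
utils::write.table(res$rejected, file.path(out_dir, "rejected.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("placed %d of %d probes; rejected: %s",
                nrow(res$map), length(probes),
                paste(sprintf("%s=%d", names(table(res$rejected$reason)),
                              table(res$rejected$reason)), collapse = ", ")))
stopifnot(nrow(res$map) == n_unique,
          sum(res$rejected$reason == "ambiguous") == n_dup,
          sum(res$rejected$reason == "no_hit") == n_absent)
message("placement agrees with the planted ground truth")
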