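# Small in-code fixtures shared across tests.

# compact cohort: a few equal-length chromosomes, default rates
small_config <- function(n_chrom = 3, chrom_len = 5e7, markers_per_chrom = 500,
                         substituted = "c2", seed = 1, ...) {
  chroms <- paste0("c", seq_len(n_chrom))
  lens <- stats::setNames(rep(chrom_len, n_chrom), chroms)
  samples <- data.frame(
    sample = c("WP1", "Donor", "SubL1"),
    role = c("wheat_parent", "alien_donor", "substitution_line"),
    substituted_chromosome = c(NA, NA, substituted),
    stringsAsFactors = FALSE
  )
  simulation_config(chromosome_lengths = lens,
                    n_markers = n_chrom * markers_per_chrom,
                    samples = samples, divergent_chromosomes = numeric(0),
                    seed = seed, ...)
}

# full 21-chromosome cohort at a reduced marker density, default rates
cohort_config <- function(markers_per_chrom = 1000, seed = 1,
                          null_cohort = FALSE) {
  lens <- stats::setNames(rep(1e8, 21), names(wheat_chromosome_lengths()))
  samples <- if (null_cohort) {
    data.frame(
      sample = c("WP1", "WP2", "D1", "D2", "D3"),
      role = c("wheat_parent", "wheat_parent",
               rep("no_alien_derivative", 3)),
      substituted_chromosome = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    default_cohort("4B")
  }
  simulation_config(chromosome_lengths = lens,
                    n_markers = 21 * markers_per_chrom,
                    samples = samples, seed = seed)
}

# hand-enumerable genotype fixture: markers at known positions, explicit
# calls per sample
toy_genotypes <- function(positions, calls_by_sample, chrom = "c1") {
  markers <- sprintf("t%03d", seq_along(positions))
  map <- data.frame(marker = markers, chrom = chrom, pos = positions,
                    stringsAsFactors = FALSE)
  G <- do.call(cbind, lapply(calls_by_sample, function(x) x))
  rownames(G) <- markers
  colnames(G) <- names(calls_by_sample)
  list(map = map, G = G)
}

table1_fixture <- function() {
  path <- system.file("extdata", "published_missingness_counts.tsv",
                      package = "chromsub")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
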