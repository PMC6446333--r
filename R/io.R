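# Readers and writers for the plain-text interchange formats: marker map
# TSV, genotype matrix TSV (markers x samples), truth JSON, config YAML.

#' Write a marker map as TSV
#'
#' @param map marker map data.frame (`marker`, `chrom`, `pos`, optionally
#'   `strand`, `mismatches`, `evalue`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map TSV
#'
#' @param path TSV with at least columns `marker`, `chrom`, `pos`.
#' @return data.frame.
#' @export
read_marker_map <- function(path) {
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(marker = "character",
                                          chrom = "character"))
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    input_error(sprintf("marker map must have columns %s",
                        paste(need, collapse = ", ")))
  map
}

#' Write a genotype matrix as TSV
#'
#' Rows are markers, columns samples; the first column (`marker`) holds
#' the marker id; calls are `AA`/`AB`/`BB`/`NC`.
#'
#' @param G genotype matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(marker = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix TSV
#'
#' Tolerant of the common missing-call spellings: any cell matching one of
#' `missing_spellings` (or an empty cell) is normalized to `NC`.
#'
#' @param path TSV written by [write_genotypes()] or an equivalent export.
#' @param missing_spellings values to treat as missing
#'   (default `c("NC", "NoCall", "--", "NA")`).
#' @return character matrix, markers x samples.
#' @export
read_genotypes <- function(path,
                           missing_spellings = c("NC", "NoCall", "--", "NA")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (names(df)[1] != "marker")
    input_error("first column of a genotype TSV must be 'marker'")
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$marker
  G[G %in% missing_spellings | G == ""] <- "NC"
  bad <- setdiff(unique(as.vector(G)), c("AA", "AB", "BB", "NC"))
  if (length(bad) > 0)
    input_error(sprintf("unrecognized genotype calls: %s",
                        paste(utils::head(bad, 5), collapse = ", ")))
  G
}

#' Write simulation truth as JSON
#'
#' @param truth truth list from [simulate_genotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Recognized keys mirror the arguments of [simulation_config()];
#' `chromosome_lengths` and `divergent_chromosomes` are given as named
#' maps, `samples` as a list of records with `sample`, `role` and
#' optional `substituted_chromosome`.
#'
#' @param path YAML path.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$chromosome_lengths))
    args$chromosome_lengths <- unlist(y$chromosome_lengths)
  if (!is.null(y$samples)) {
    args$samples <- do.call(rbind, lapply(y$samples, function(s) {
      data.frame(sample = s$sample, role = s$role,
                 substituted_chromosome =
                   if (is.null(s$substituted_chromosome)) NA_character_
                   else s$substituted_chromosome,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(y$divergent_chromosomes))
    args$divergent_chromosomes <- unlist(y$divergent_chromosomes)
  for (k in c("n_markers", "p_cross_hybridize", "p_background_missing",
              "p_retained_on_substituted", "p_heterozygous",
              "p_allele_match", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(simulation_config, args)
}

#' Read flanking sequences or a reference assembly from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
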