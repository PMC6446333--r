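# Independent brute-force oracles, deliberately implemented without the
# package's code paths (no Biostrings, no findInterval tricks).

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# position-by-position ungapped scan of one strand; a position matches
# only if both bases are equal and in {A,C,G,T}
.oracle_scan_strand <- function(query, subject, max_mismatch) {
  m <- nchar(query)
  n <- nchar(subject)
  if (m > n) return(integer(0))
  qv <- strsplit(query, "")[[1]]
  sv <- strsplit(subject, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  mism <- integer(n - m + 1)
  idx <- seq_len(n - m + 1)
  for (j in seq_len(m)) {
    sj <- sv[idx + j - 1]
    mism <- mism + as.integer(sj != qv[j] | !(qv[j] %in% acgt) |
                                !(sj %in% acgt))
  }
  which(mism <= max_mismatch)
}

.oracle_scan_mismatches <- function(query, subject, starts) {
  m <- nchar(query)
  vapply(starts, function(s) {
    qv <- strsplit(query, "")[[1]]
    sv <- strsplit(substr(subject, s, s + m - 1), "")[[1]]
    acgt <- c("A", "C", "G", "T")
    sum(qv != sv | !(qv %in% acgt) | !(sv %in% acgt))
  }, integer(1))
}

# full-hit-list oracle: every occurrence on either strand, with mismatch
# counts, sorted like find_hits()
oracle_find_hits <- function(query, reference, max_mismatch) {
  out <- list()
  for (chrom in names(reference)) {
    subj <- reference[[chrom]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else oracle_revcomp(query)
      starts <- .oracle_scan_strand(q, subj, max_mismatch)
      if (length(starts) == 0) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = starts, strand = strand,
        mismatches = .oracle_scan_mismatches(q, subj, starts),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$mismatches, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

# per-window recount by explicit subsetting (windows [start, end),
# marker at p inside iff start < p <= end)
oracle_window_counts <- function(positions, observed, starts, ends) {
  n_exp <- integer(length(starts))
  n_obs <- integer(length(starts))
  for (k in seq_along(starts)) {
    inw <- positions > starts[k] & positions <= ends[k]
    n_exp[k] <- sum(inw)
    n_obs[k] <- sum(inw & observed)
  }
  data.frame(n_expected = n_exp, n_observed = n_obs)
}

# four-way shared-homozygous intersection by explicit per-marker looping
oracle_shared_markers <- function(G, map, chromosome, samples) {
  mk <- map[map$chrom == chromosome, , drop = FALSE]
  keep <- character(0)
  for (m in mk$marker) {
    calls <- G[m, samples]
    if (any(calls == "NC")) next
    if (any(calls == "AB")) next
    if (length(unique(calls)) != 1) next
    keep <- c(keep, m)
  }
  keep
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(seq, at) {
  b <- substr(seq, at, at)
  repl <- setdiff(c("A", "C", "G", "T"), b)[sample.int(3, 1)]
  paste0(substr(seq, 1, at - 1), repl, substr(seq, at + 1, nchar(seq)))
}
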