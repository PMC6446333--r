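# Placement of marker flanking sequences on a reference assembly by best
# ungapped match. Candidate windows are enumerated with
# Biostrings::matchPattern; mismatches are then recounted under this
# package's rule (any non-ACGT base, N included, never matches), which can
# only add mismatches relative to Biostrings' literal matching, so no
# candidate is lost.

.dna_iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

#' Ungapped mapping parameters
#'
#' Controls hit enumeration and the acceptance gates for marker placement:
#' at most `max_mismatch` mismatches, an E-value at or below
#' `evalue_threshold`, and (by default) a unique best hit. `lambda` and `K`
#' are Karlin-Altschul parameters for the ungapped scoring scheme; the
#' defaults correspond to the standard +1/-2 nucleotide scheme.
#'
#' @param max_mismatch maximum mismatches per hit (default 1).
#' @param evalue_threshold E-value gate (default 1e-10).
#' @param lambda,K Karlin-Altschul parameters (defaults 1.28, 0.46).
#' @param match_score,mismatch_score per-base scores (defaults +1, -2).
#' @param require_unique_best drop markers whose best hit is tied
#'   (default TRUE).
#' @return an object of class `mapping_params`.
#' @export
mapping_params <- function(max_mismatch = 1, evalue_threshold = 1e-10,
                           lambda = 1.28, K = 0.46,
                           match_score = 1L, mismatch_score = -2L,
                           require_unique_best = TRUE) {
  if (max_mismatch < 0) config_error("max_mismatch", "must be >= 0")
  if (evalue_threshold <= 0) config_error("evalue_threshold", "must be > 0")
  if (lambda <= 0) config_error("lambda", "must be > 0")
  if (K <= 0) config_error("K", "must be > 0")
  structure(
    list(max_mismatch = as.integer(max_mismatch),
         evalue_threshold = evalue_threshold,
         lambda = lambda, K = K,
         match_score = as.integer(match_score),
         mismatch_score = as.integer(mismatch_score),
         require_unique_best = isTRUE(require_unique_best)),
    class = "mapping_params"
  )
}

#' Karlin-Altschul E-value for an ungapped hit
#'
#' `E = K * m * n * exp(-lambda * S)` for score `S`, query length `m` and
#' reference length `n`. Strictly decreasing in the score and linear in
#' both lengths.
#'
#' @param score alignment score.
#' @param query_len query length (>= 1).
#' @param reference_len total reference length (>= 1).
#' @param params a [mapping_params()].
#' @return numeric E-value.
#' @examples
#' evalue(50, 50, 1e6, mapping_params())
#' @export
evalue <- function(score, query_len, reference_len, params = mapping_params()) {
  if (any(!is.finite(score))) input_error("score must be finite")
  if (any(query_len < 1) || any(reference_len < 1))
    input_error("sequence lengths must be >= 1")
  params$K * query_len * reference_len * exp(-params$lambda * score)
}

.check_dna <- function(seq, what = "query") {
  chars <- unique(strsplit(toupper(seq), "")[[1]])
  bad <- setdiff(chars, .dna_iupac)
  if (length(bad) > 0)
    input_error(sprintf("%s contains non-IUPAC characters: %s",
                        what, paste(bad, collapse = ", ")))
  invisible(toupper(seq))
}

# mismatch count under the never-match rule for ambiguity codes:
# a position matches iff both bases are equal and in {A,C,G,T}
.count_mismatches <- function(q, s) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  sum(qv != sv | !(qv %in% c("A", "C", "G", "T")))
}

#' Find all ungapped occurrences of a query in a reference
#'
#' Exhaustively reports every full-length ungapped occurrence of the query
#' on either strand with at most `params$max_mismatch` mismatches —
#' equivalent to a position-by-position scan. `N` (or any ambiguity code)
#' in the query or reference never matches and counts as a mismatch. Each
#' hit carries its score (`matches * match_score + mismatches *
#' mismatch_score`) and Karlin-Altschul E-value computed against the total
#' reference length. The start is always the 1-based coordinate of the
#' hit's first reference base on the forward strand.
#'
#' @param query character DNA string (typically 35-71 nt), or a
#'   length-1 named character vector (name = marker id).
#' @param reference named character vector or `Biostrings::DNAStringSet`
#'   of reference sequences.
#' @param params a [mapping_params()].
#' @return data.frame with columns `chrom`, `start`, `strand`,
#'   `mismatches`, `score`, `evalue`, sorted by (mismatches, chrom,
#'   start, strand).
#' @export
find_hits <- function(query, reference, params = mapping_params()) {
  if (length(reference) == 0) input_error("reference is empty")
  q <- .check_dna(as.character(query)[1])
  if (nchar(q) == 0) input_error("query is empty")
  if (inherits(reference, "DNAStringSet")) {
    ref <- as.character(reference)
  } else {
    ref <- stats::setNames(toupper(unlist(reference, use.names = FALSE)),
                           names(reference))
  }
  if (is.null(names(ref)) || anyDuplicated(names(ref)))
    input_error("reference sequences must have unique names")
  total_len <- sum(nchar(ref))
  m <- nchar(q)

  qset <- c("+" = q,
            "-" = as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(q))))
  out <- list()
  for (chrom in names(ref)) {
    subj <- Biostrings::DNAString(ref[[chrom]])
    if (m > length(subj)) next
    for (strand in c("+", "-")) {
      pat <- Biostrings::DNAString(qset[[strand]])
      mt <- Biostrings::matchPattern(pat, subj,
                                     max.mismatch = params$max_mismatch,
                                     fixed = TRUE)
      starts <- Biostrings::start(mt)
      if (length(starts) == 0) next
      mism <- vapply(starts, function(s) {
        .count_mismatches(qset[[strand]], substr(ref[[chrom]], s, s + m - 1))
      }, integer(1))
      keep <- mism <= params$max_mismatch
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = starts[keep], strand = strand,
        mismatches = mism[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    hits <- data.frame(chrom = character(), start = integer(),
                       strand = character(), mismatches = integer(),
                       score = integer(), evalue = numeric(),
                       stringsAsFactors = FALSE)
    return(hits)
  }
  hits <- do.call(rbind, out)
  hits$score <- (m - hits$mismatches) * params$match_score +
    hits$mismatches * params$mismatch_score
  hits$evalue <- evalue(hits$score, m, total_len, params)
  hits <- hits[order(hits$mismatches, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Build a marker map by placing flanking sequences on a reference
#'
#' A marker is placed iff it has at least one hit with at most
#' `max_mismatch` mismatches passing the E-value gate AND (when
#' `require_unique_best`) a single best hit with strictly fewer mismatches
#' than every other passing hit; ties are rejected as ambiguous. Rejected
#' markers carry a reason in `{no_hit, evalue_fail, ambiguous}`.
#'
#' @param queries named character vector (names = marker ids) or
#'   `Biostrings::DNAStringSet` of flanking sequences.
#' @param reference named character vector or `DNAStringSet`.
#' @param params a [mapping_params()].
#' @return list with `map` (data.frame: `marker`, `chrom`, `pos`, `strand`,
#'   `mismatches`, `evalue`) and `rejected` (data.frame: `marker`,
#'   `reason`).
#' @export
build_marker_map <- function(queries, reference, params = mapping_params()) {
  if (inherits(queries, "DNAStringSet")) queries <- as.character(queries)
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    input_error("queries must have unique marker ids as names")
  placed <- list()
  rejected <- list()
  for (id in names(queries)) {
    hits <- find_hits(queries[[id]], reference, params)
    if (nrow(hits) == 0) {
      rejected[[id]] <- "no_hit"
      next
    }
    pass <- hits[hits$evalue <= params$evalue_threshold, , drop = FALSE]
    if (nrow(pass) == 0) {
      rejected[[id]] <- "evalue_fail"
      next
    }
    best_mm <- min(pass$mismatches)
    best <- pass[pass$mismatches == best_mm, , drop = FALSE]
    if (params$require_unique_best && nrow(best) > 1) {
      rejected[[id]] <- "ambiguous"
      next
    }
    placed[[id]] <- data.frame(
      marker = id, chrom = best$chrom[1], pos = best$start[1],
      strand = best$strand[1], mismatches = best$mismatches[1],
      evalue = best$evalue[1], stringsAsFactors = FALSE)
  }
  map <- if (length(placed) > 0) do.call(rbind, placed) else
    data.frame(marker = character(), chrom = character(), pos = numeric(),
               strand = character(), mismatches = integer(),
               evalue = numeric(), stringsAsFactors = FALSE)
  rownames(map) <- NULL
  rej <- data.frame(marker = as.character(names(rejected)),
                    reason = as.character(unlist(rejected, use.names = FALSE)),
                    stringsAsFactors = FALSE)
  list(map = map, rejected = rej)
}
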