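test_that("exact self-match and strand symmetry behave as expected", {
  ref <- c(chrA = "TTTTAAACCGTTTTTT")
  hits <- find_hits("AAACCGTT", ref, mapping_params(max_mismatch = 0))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  # a palindromic query legitimately hits both strands at the same spot
  pal <- find_hits("ACGTACGT", c(p = "TTACGTACGTTT"),
                   mapping_params(max_mismatch = 0))
  expect_equal(pal$strand, c("+", "-"))
  expect_equal(pal$start, c(3, 3))

  # query embedded as its reverse complement -> minus-strand hit there
  q <- "ACCGTTGCAA"
  rc <- oracle_revcomp(q)
  ref2 <- c(chrB = paste0("GGGGG", rc, "GGGGG"))
  hits2 <- find_hits(q, ref2, mapping_params(max_mismatch = 0))
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 6)
})

test_that("N never matches, in query or reference, even against N", {
  ref <- c(c1 = "TTTTTAACCGGATTTT")
  hits <- find_hits("AACCGNAT", ref, mapping_params(max_mismatch = 1))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 1)
  expect_equal(nrow(find_hits("AACCGNAT", ref, mapping_params(max_mismatch = 0))), 0)

  refN <- c(c1 = "TTTTTAACCGNATTTT")
  hitsNN <- find_hits("AACCGNAT", refN, mapping_params(max_mismatch = 1))
  expect_equal(nrow(hitsNN), 1)
  expect_equal(hitsNN$mismatches, 1)  # N-vs-N still a mismatch

  expect_error(find_hits("ACGT7", ref), class = "chromsub_input_error")
})

test_that("E-value follows the Karlin-Altschul closed form and its monotonicities", {
  p <- mapping_params(lambda = 1.28, K = 0.46)
  # closed-form cross-check computed in log space
  expect_equal(evalue(50, 50, 1e6, p),
               exp(log(0.46) + log(50) + log(1e6) - 1.28 * 50),
               tolerance = 1e-12)
  expect_lt(evalue(1000, 50, 1e6, p), 1e-300)           # E -> 0 as S grows
  expect_equal(evalue(30, 50, 2e6, p), 2 * evalue(30, 50, 1e6, p))
  expect_true(all(diff(evalue(10:20, 50, 1e6, p)) < 0)) # decreasing in S
  expect_error(evalue(10, 0, 1e6, p), class = "chromsub_input_error")
})

test_that("find_hits equals the brute-force scanner on random references", {
  set.seed(101)
  ref <- c(r1 = random_dna(20000), r2 = random_dna(15000))
  params <- mapping_params(max_mismatch = 1)
  for (i in 1:20) {
    m <- sample(35:60, 1)
    src <- if (i %% 2 == 0) "r1" else "r2"
    at <- sample.int(nchar(ref[[src]]) - m + 1, 1)
    q <- substr(ref[[src]], at, at + m - 1)
    if (i %% 3 == 0) q <- mutate_base(q, sample.int(m, 1))
    if (i %% 5 == 0) q <- oracle_revcomp(q)
    got <- find_hits(q, ref, params)
    want <- oracle_find_hits(q, ref, 1)
    expect_equal(got[, c("chrom", "start", "strand", "mismatches")], want,
                 label = sprintf("hit list for query %d", i))
    # scores/evalues consistent with the mismatch counts
    expect_equal(got$score, (m - got$mismatches) * 1 + got$mismatches * -2)
    expect_equal(got$evalue, evalue(got$score, m, sum(nchar(ref)), params))
  }
})

test_that("marker placement resolves unique, duplicated, and failing queries", {
  set.seed(7)
  n_unique <- 30
  n_dup <- 6
  seqs <- vapply(seq_len(n_unique + n_dup), function(i) random_dna(45),
                 character(1))
  # chromosome 1 carries every insert; chromosome 2 repeats the last n_dup
  chr1 <- paste0(random_dna(300),
                 paste0(seqs, collapse = random_dna(40)), random_dna(300))
  chr2 <- paste0(random_dna(500),
                 paste0(seqs[n_unique + seq_len(n_dup)],
                        collapse = random_dna(60)), random_dna(200))
  ref <- c(chr1 = chr1, chr2 = chr2)
  queries <- stats::setNames(seqs, sprintf("q%02d", seq_along(seqs)))
  res <- build_marker_map(queries, ref, mapping_params(max_mismatch = 1))
  expect_equal(nrow(res$map), n_unique)
  expect_equal(sum(res$rejected$reason == "ambiguous"), n_dup)
  # every placed marker sits where its sequence was planted
  for (i in seq_len(n_unique)) {
    id <- sprintf("q%02d", i)
    row <- res$map[res$map$marker == id, ]
    expect_equal(substr(chr1, row$pos, row$pos + 44), seqs[i])
  }
  # a query absent from the reference is a no_hit
  res2 <- build_marker_map(c(miss = random_dna(45)), ref)
  expect_equal(res2$rejected$reason, "no_hit")
})

test_that("the E-value gate is monotone and can reject outright", {
  set.seed(21)
  ref <- c(c1 = random_dna(5000))
  q <- substr(ref[[1]], 100, 147)
  queries <- c(m1 = q)
  # weak scoring makes even a perfect 48-mer fail a 1e-10 gate
  weak <- mapping_params(lambda = 0.1, K = 0.46)
  res_weak <- build_marker_map(queries, ref, weak)
  expect_equal(res_weak$rejected$reason, "evalue_fail")

  strict <- mapping_params(evalue_threshold = 1e-300)
  loose <- mapping_params(evalue_threshold = 1e-2)
  placed_strict <- build_marker_map(queries, ref, strict)$map$marker
  placed_loose <- build_marker_map(queries, ref, loose)$map$marker
  expect_true(all(placed_strict %in% placed_loose))
})

test_that("mapping the reverse complement flips strand but not position", {
  set.seed(33)
  ref <- c(c1 = random_dna(8000))
  ids <- sprintf("f%02d", 1:10)
  fwd <- stats::setNames(vapply(1:10, function(i) {
    at <- sample.int(8000 - 50, 1)
    substr(ref[[1]], at, at + 49)
  }, character(1)), ids)
  rev <- stats::setNames(vapply(fwd, oracle_revcomp, character(1)), ids)
  mf <- build_marker_map(fwd, ref)$map
  mr <- build_marker_map(rev, ref)$map
  shared <- intersect(mf$marker, mr$marker)
  expect_true(length(shared) > 0)
  mf <- mf[match(shared, mf$marker), ]
  mr <- mr[match(shared, mr$marker), ]
  expect_equal(mf$pos, mr$pos)
  expect_true(all(mf$strand != mr$strand))
})
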