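test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_markers = 0), "n_markers",
               class = "chromsub_config_error")
  expect_error(simulation_config(p_cross_hybridize = 1.2),
               "p_cross_hybridize", class = "chromsub_config_error")
  expect_error(simulation_config(chromosome_lengths = c(a = -5)),
               "chromosome_lengths", class = "chromsub_config_error")
  bad_samples <- data.frame(sample = "S", role = "substitution_line",
                            substituted_chromosome = "9Z",
                            stringsAsFactors = FALSE)
  expect_error(simulation_config(samples = bad_samples), "samples",
               class = "chromsub_config_error")
  expect_error(
    simulation_config(divergent_chromosomes = c(ZZ = 0.1)),
    "divergent_chromosomes", class = "chromsub_config_error")
})

test_that("marker maps respect chromosome bounds, unique ids, and the seed", {
  cfg <- simulation_config(chromosome_lengths = c(chr1 = 1e7),
                           n_markers = 100, seed = 1)
  map <- simulate_marker_map(cfg)
  expect_equal(nrow(map), 100)
  expect_true(all(map$pos >= 1 & map$pos <= 1e7))
  expect_false(anyDuplicated(map$marker) > 0)
  expect_identical(map, simulate_marker_map(cfg))

  cfg2 <- simulation_config(chromosome_lengths = c(chr1 = 1e7),
                            n_markers = 100, seed = 2)
  expect_false(identical(map$pos, simulate_marker_map(cfg2)$pos))
})

test_that("degenerate rates produce the exact limiting genotype patterns", {
  cfg <- small_config(p_background_missing = 0, p_cross_hybridize = 1,
                      p_retained_on_substituted = 1)
  map <- simulate_marker_map(cfg)
  sim <- simulate_genotypes(map, cfg)
  expect_false(any(sim$genotypes[, "SubL1"] == "NC"))

  cfg0 <- small_config(p_background_missing = 0,
                       p_retained_on_substituted = 0)
  map0 <- simulate_marker_map(cfg0)
  sim0 <- simulate_genotypes(map0, cfg0)
  s <- summarize_missingness(sim0$genotypes, map0, "SubL1")
  expect_equal(s$missing_ratio[s$chromosome == "c2"], 1.0)
  expect_equal(s$missing_ratio[s$chromosome != "c2"], c(0, 0))
})

test_that("substituted-chromosome missingness matches the binomial expectation", {
  # mean over 20 seeds of the missing ratio on a substituted chromosome
  # carrying ~2000 markers, against the closed form
  # 1 - p_cross * p_retained * (1 - p_background)
  ratios <- vapply(1:20, function(seed) {
    cfg <- small_config(n_chrom = 2, markers_per_chrom = 2000,
                        substituted = "c2", seed = seed)
    map <- simulate_marker_map(cfg)
    sim <- simulate_genotypes(map, cfg)
    s <- summarize_missingness(sim$genotypes, map, "SubL1")
    s$missing_ratio[s$chromosome == "c2"]
  }, numeric(1))
  cfg <- small_config()
  expected <- 1 - cfg$p_cross_hybridize * cfg$p_retained_on_substituted *
    (1 - cfg$p_background_missing)
  expect_equal(expected,
               expected_missing_rate(cfg, "substitution_line", "c2",
                                     substituted = TRUE))
  expect_lt(abs(mean(ratios) - expected), 0.01)
  expect_lt(abs(mean(ratios) - 0.60), 0.03)
})

test_that("empirical missing ratios converge to the configured rates (4 SE)", {
  cfg <- simulation_config(
    chromosome_lengths = c(cA = 5e7, cB = 5e7, cC = 5e7),
    n_markers = 6000,
    samples = data.frame(sample = c("WP", "Donor", "Sub"),
                         role = c("wheat_parent", "alien_donor",
                                  "substitution_line"),
                         substituted_chromosome = c(NA, NA, "cA"),
                         stringsAsFactors = FALSE),
    divergent_chromosomes = c(cB = 0.08),
    seed = 11)
  map <- simulate_marker_map(cfg)
  sim <- simulate_genotypes(map, cfg)
  for (smp_role in list(c("WP", "wheat_parent"), c("Sub", "substitution_line"),
                        c("Donor", "alien_donor"))) {
    s <- summarize_missingness(sim$genotypes, map, smp_role[1])
    for (i in seq_len(nrow(s))) {
      chrom <- s$chromosome[i]
      p <- expected_missing_rate(cfg, smp_role[2], chrom,
                                 substituted = chrom == "cA")
      se <- sqrt(p * (1 - p) / s$n_mapped[i])
      expect_lt(abs(s$missing_ratio[i] - p), 4 * se + 1e-12,
                label = sprintf("|ratio - p| for %s on %s", smp_role[1], chrom))
    }
  }
})

test_that("truth labels are complete and consistent with donor calls", {
  cfg <- small_config(seed = 5)
  map <- simulate_marker_map(cfg)
  sim <- simulate_genotypes(map, cfg)
  tr <- sim$truth
  expect_setequal(tr$markers$marker, map$marker)
  expect_setequal(tr$samples$sample, colnames(sim$genotypes))
  # cross_hybridizing <=> donor has a call
  donor_called <- sim$genotypes[tr$markers$marker, "Donor"] != "NC"
  expect_identical(unname(donor_called), tr$markers$cross_hybridizing)
})

test_that("identical config and seed give identical simulations", {
  cfg <- small_config(seed = 9)
  a <- simulate_genotypes(simulate_marker_map(cfg), cfg)
  b <- simulate_genotypes(simulate_marker_map(cfg), cfg)
  expect_identical(a, b)
})

test_that("map/config chromosome mismatch raises a consistency error", {
  cfg <- small_config()
  map <- simulate_marker_map(cfg)
  map$chrom[1] <- "elsewhere"
  expect_error(simulate_genotypes(map, cfg),
               class = "chromsub_consistency_error")
})
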