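#' Approximate bread wheat chromosome lengths
#'
#' Lengths (bp) of the 21 bread wheat chromosomes, rounded to the nearest
#' megabase from the IWGSC RefSeq v1.0 assembly. Used as the default
#' chromosome set for simulation.
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
wheat_chromosome_lengths <- function() {
  mb <- c(
    "1A" = 594, "1B" = 689, "1D" = 495,
    "2A" = 780, "2B" = 801, "2D" = 651,
    "3A" = 750, "3B" = 830, "3D" = 615,
    "4A" = 744, "4B" = 673, "4D" = 509,
    "5A" = 709, "5B" = 713, "5D" = 566,
    "6A" = 618, "6B" = 720, "6D" = 473,
    "7A" = 736, "7B" = 750, "7D" = 638
  )
  mb * 1e6
}

#' Default simulated cohort
#'
#' Two wheat parents, one alien donor, and three whole-chromosome
#' substitution lines sharing one substituted chromosome — the sample
#' structure of a typical wide-cross validation experiment.
#'
#' @param substituted_chromosome chromosome replaced in the substitution
#'   lines (default "4B").
#' @return data.frame with columns `sample`, `role`,
#'   `substituted_chromosome`.
#' @export
default_cohort <- function(substituted_chromosome = "4B") {
  data.frame(
    sample = c("WP1", "WP2", "Donor", "SubL1", "SubL2", "SubL3"),
    role = c("wheat_parent", "wheat_parent", "alien_donor",
             rep("substitution_line", 3)),
    substituted_chromosome = c(NA, NA, NA, rep(substituted_chromosome, 3)),
    stringsAsFactors = FALSE
  )
}

.sample_roles <- c("wheat_parent", "alien_donor", "substitution_line",
                   "addition_line", "no_alien_derivative")

#' Simulation configuration
#'
#' Parameters of the synthetic genotype model. Defaults emulate a 55K-style
#' wheat array (51,159 features) genotyped on a cohort carrying a single
#' whole-chromosome substitution:
#' * `p_cross_hybridize = 0.577`: fraction of array markers whose probe
#'   also detects a site in the alien donor genome;
#' * `p_background_missing = 0.012`: per-marker no-call rate in euploid
#'   wheat;
#' * `divergent_chromosomes`: chromosomes where the crossing parents
#'   diverge from the array design panel show elevated missingness
#'   (defaults 2D at 7.9% and 7B at 8.3%);
#' * `p_retained_on_substituted = 0.693`: probability that a
#'   cross-hybridizing marker on the substituted chromosome still yields a
#'   call in a substitution line, so the marginal call rate there is
#'   0.577 x 0.693 ~ 0.40 and the missing rate ~ 0.60;
#' * `p_heterozygous = 0.01`: probability a non-missing wheat call is AB;
#' * `p_allele_match = 0.5`: probability the alien donor's homozygous
#'   allele at a cross-hybridizing marker equals the wheat parents' allele.
#'
#' @param chromosome_lengths named vector of chromosome lengths in bp.
#' @param n_markers total number of array markers to place.
#' @param samples data.frame with columns `sample`, `role`,
#'   `substituted_chromosome` (NA unless role is `substitution_line`);
#'   defaults to [default_cohort()] on "4B" when present, else on the
#'   first chromosome.
#' @param p_cross_hybridize,p_background_missing,p_retained_on_substituted,p_heterozygous,p_allele_match
#'   model probabilities, each in \[0, 1\].
#' @param divergent_chromosomes named numeric vector mapping chromosome id
#'   to an elevated missing probability; defaults to 2D and 7B (where
#'   present) at their usual elevated rates. Pass `numeric(0)` for none.
#' @param seed integer seed; all simulation randomness derives from it.
#' @return an object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_markers = 1000, seed = 7)
#' cfg$p_cross_hybridize
#' @export
simulation_config <- function(chromosome_lengths = wheat_chromosome_lengths(),
                              n_markers = 51159,
                              samples = NULL,
                              p_cross_hybridize = 0.577,
                              p_background_missing = 0.012,
                              divergent_chromosomes = NULL,
                              p_retained_on_substituted = 0.693,
                              p_heterozygous = 0.01,
                              p_allele_match = 0.5,
                              seed = 1L) {
  if (length(chromosome_lengths) < 1 || is.null(names(chromosome_lengths)) ||
      anyDuplicated(names(chromosome_lengths)))
    config_error("chromosome_lengths", "must be a named vector with unique names")
  if (any(chromosome_lengths <= 0))
    config_error("chromosome_lengths", "must be > 0")
  if (is.null(divergent_chromosomes)) {
    dflt <- c("2D" = 0.079, "7B" = 0.083)
    divergent_chromosomes <- dflt[names(dflt) %in% names(chromosome_lengths)]
  }
  if (is.null(samples))
    samples <- default_cohort(
      if ("4B" %in% names(chromosome_lengths)) "4B"
      else names(chromosome_lengths)[1])
  if (length(n_markers) != 1 || is.na(n_markers) || n_markers < 1)
    config_error("n_markers", "must be >= 1")
  if (!is.data.frame(samples) ||
      !all(c("sample", "role", "substituted_chromosome") %in% names(samples)))
    config_error("samples",
                 "must be a data.frame with sample, role, substituted_chromosome")
  if (anyDuplicated(samples$sample))
    config_error("samples", "sample ids must be unique")
  if (!all(samples$role %in% .sample_roles))
    config_error("samples", sprintf("role must be one of %s",
                                    paste(.sample_roles, collapse = ", ")))
  is_sub <- samples$role == "substitution_line"
  if (any(is_sub & (is.na(samples$substituted_chromosome) |
                    !samples$substituted_chromosome %in% names(chromosome_lengths))))
    config_error("samples",
                 "every substitution_line must name a substituted_chromosome in the chromosome set")
  for (p in c("p_cross_hybridize", "p_background_missing",
              "p_retained_on_substituted", "p_heterozygous",
              "p_allele_match")) {
    v <- get(p)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      config_error(p, "must be a probability in [0, 1]")
  }
  if (length(divergent_chromosomes) > 0) {
    if (is.null(names(divergent_chromosomes)))
      config_error("divergent_chromosomes", "must be a named vector")
    if (!all(names(divergent_chromosomes) %in% names(chromosome_lengths)))
      config_error("divergent_chromosomes",
                   "names chromosomes outside the chromosome set")
    if (any(divergent_chromosomes < 0 | divergent_chromosomes > 1))
      config_error("divergent_chromosomes", "rates must be in [0, 1]")
  }
  if (length(seed) != 1 || is.na(seed))
    config_error("seed", "must be a single integer")

  structure(
    list(chromosome_lengths = chromosome_lengths,
         n_markers = as.integer(n_markers),
         samples = samples,
         p_cross_hybridize = p_cross_hybridize,
         p_background_missing = p_background_missing,
         divergent_chromosomes = divergent_chromosomes,
         p_retained_on_substituted = p_retained_on_substituted,
         p_heterozygous = p_heterozygous,
         p_allele_match = p_allele_match,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate an array marker map
#'
#' Places `n_markers` markers uniformly at random over the configured
#' genome: the chromosome is drawn with probability proportional to its
#' length and the position uniformly on `[1, length]`. Marker ids are
#' assigned in (chromosome, position) order and are unique. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `marker`, `chrom`, `pos` (1-based bp).
#' @examples
#' map <- simulate_marker_map(simulation_config(
#'   chromosome_lengths = c(chr1 = 1e7), n_markers = 100, seed = 1))
#' range(map$pos)
#' @export
simulate_marker_map <- function(config) {
  if (!inherits(config, "simulation_config"))
    config_error("config", "must be created by simulation_config()")
  lens <- config$chromosome_lengths
  n <- config$n_markers
  with_seed(config$seed, {
    chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
    pos <- 1 + floor(stats::runif(n) * lens[chrom])
  })
  ord <- order(match(chrom, names(lens)), pos)
  map <- data.frame(
    marker = sprintf("M%0*d", nchar(as.character(n)), seq_len(n)),
    chrom = chrom[ord],
    pos = as.numeric(pos[ord]),
    stringsAsFactors = FALSE
  )
  attr(map, "chromosome_lengths") <- lens
  map
}

#' Simulate a genotype call matrix with ground truth
#'
#' Draws calls in `{AA, AB, BB, NC}` for every (marker, sample) pair under
#' the missingness model:
#' * wheat-like samples (`wheat_parent`, `addition_line`,
#'   `no_alien_derivative`) are NC with the background (or
#'   divergent-chromosome) rate, AB with probability `p_heterozygous`
#'   otherwise, else the marker's fixed homozygous wheat allele;
#' * the `alien_donor` has a call iff the marker cross-hybridizes
#'   (per-marker Bernoulli with `p_cross_hybridize`); its call is the
#'   marker's homozygous donor allele;
#' * a `substitution_line` behaves as wheat everywhere except its
#'   substituted chromosome, where a call is present iff the marker
#'   cross-hybridizes AND an independent retention draw succeeds
#'   (`p_retained_on_substituted`); present calls take the donor allele,
#'   since the same alien sequence is interrogated as in the donor.
#'
#' Cross-hybridization is drawn once per marker and shared by the donor
#' and all substitution lines. Deterministic given `config$seed` (the map
#' uses the seed itself, the genotypes `seed + 1`).
#'
#' @param map marker map from [simulate_marker_map()].
#' @param config the same [simulation_config()].
#' @return list with elements `genotypes` (character matrix, markers x
#'   samples) and `truth` (list: `samples` data.frame, `markers`
#'   data.frame with per-marker `cross_hybridizing`, `wheat_allele`,
#'   `donor_allele`, true `chrom`/`pos`).
#' @export
simulate_genotypes <- function(map, config) {
  if (!inherits(config, "simulation_config"))
    config_error("config", "must be created by simulation_config()")
  if (!all(map$chrom %in% names(config$chromosome_lengths)))
    consistency_error("marker map names chromosomes absent from the config")
  n <- nrow(map)
  smp <- config$samples

  p_miss <- rep(config$p_background_missing, n)
  for (dc in names(config$divergent_chromosomes))
    p_miss[map$chrom == dc] <- config$divergent_chromosomes[[dc]]

  with_seed(config$seed + 1L, {
    cross <- stats::runif(n) < config$p_cross_hybridize
    wheat_allele <- ifelse(stats::runif(n) < 0.5, "AA", "BB")
    donor_allele <- ifelse(stats::runif(n) < config$p_allele_match,
                           wheat_allele,
                           ifelse(wheat_allele == "AA", "BB", "AA"))
    G <- matrix(NA_character_, nrow = n, ncol = nrow(smp),
                dimnames = list(map$marker, smp$sample))
    for (j in seq_len(nrow(smp))) {
      role <- smp$role[j]
      # wheat-like background for every role except the pure donor
      calls <- ifelse(stats::runif(n) < p_miss, "NC",
                      ifelse(stats::runif(n) < config$p_heterozygous,
                             "AB", wheat_allele))
      if (role == "alien_donor") {
        calls <- ifelse(cross, donor_allele, "NC")
      } else if (role == "substitution_line") {
        # retention composes with the background no-call layer already in
        # `calls`, so the substituted-chromosome missing rate is
        # 1 - p_cross * p_retained * (1 - p_background)
        on_sub <- map$chrom == smp$substituted_chromosome[j]
        retained <- stats::runif(n) < config$p_retained_on_substituted
        calls[on_sub] <- ifelse(cross[on_sub] & retained[on_sub] &
                                  calls[on_sub] != "NC",
                                donor_allele[on_sub], "NC")
      }
      G[, j] <- calls
    }
  })

  truth <- list(
    samples = smp,
    markers = data.frame(
      marker = map$marker, chrom = map$chrom, pos = map$pos,
      cross_hybridizing = cross,
      wheat_allele = wheat_allele,
      donor_allele = donor_allele,
      stringsAsFactors = FALSE
    )
  )
  list(genotypes = G, truth = truth)
}

#' Closed-form missing rate implied by a simulation config
#'
#' Expected per-marker missing probability for a given sample role and
#' chromosome under the model of [simulate_genotypes()]. For a
#' substitution line on its substituted chromosome this is
#' `1 - p_cross_hybridize * p_retained_on_substituted * (1 - background)`.
#'
#' @param config a [simulation_config()].
#' @param role sample role.
#' @param chrom chromosome id.
#' @param substituted is `chrom` the sample's substituted chromosome?
#' @return expected missing probability.
#' @export
expected_missing_rate <- function(config, role, chrom, substituted = FALSE) {
  bg <- config$p_background_missing
  if (chrom %in% names(config$divergent_chromosomes))
    bg <- config$divergent_chromosomes[[chrom]]
  switch(role,
    alien_donor = 1 - config$p_cross_hybridize,
    substitution_line = if (substituted)
      1 - config$p_cross_hybridize * config$p_retained_on_substituted * (1 - bg)
    else bg,
    bg)
}
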