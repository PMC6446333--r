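Package: chromsub
Title: Detection of Wheat/Alien Whole-Chromosome Substitutions from SNP
    Array Missingness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates candidate wheat/alien whole-chromosome substitution
    lines from SNP array genotype calls. Array markers designed on wheat
    fail to hybridize when their target chromosome is replaced by an alien
    homoeolog, so the substituted chromosome shows a strongly elevated
    missing-call rate. The package places marker flanking sequences on a
    reference assembly by best ungapped match under an E-value gate,
    summarises per-chromosome missing-call statistics, scans chromosomes
    with a sliding-window observed/expected marker ratio, calls the
    substituted chromosome, and filters cross-hybridizing markers shared
    as identical homozygous alleles between substitution lines and the
    alien donor. A seeded synthetic genotype simulator with ground-truth
    labels makes every stage testable without chip data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
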