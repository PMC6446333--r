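---
title: "Detecting whole-chromosome substitutions from SNP-array missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting whole-chromosome substitutions from SNP-array missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsub)
```

## The signal and its model

A wheat SNP array interrogates tens of thousands of loci by hybridizing
probes designed on wheat sequence. In a line where a wheat chromosome
pair has been replaced by an alien homoeologous pair, the wheat targets
of that chromosome's markers are simply absent. Two things follow:

1. markers mapped to the substituted chromosome return NoCall unless
   their probe *cross-hybridizes* with a site on the alien homoeolog, so
   the chromosome's missing-call ratio jumps from the ~1% background to
   the complement of the cross-hybridization-and-retention rate; and
2. because the whole chromosome is gone, the depression is uniform along
   it — distinguishing a substitution from a segmental introgression,
   which depresses only a window of the chromosome.

`chromsub` treats the genotype matrix (calls in {AA, AB, BB, NC}) and a
marker map (marker, chromosome, 1-based bp position) as the primitive
inputs and computes: per-chromosome missingness summaries, a sliding-
window observed/expected track, a three-gate substitution call, and the
set of "shared" markers usable on both homoeologues. "Missing" always
means call state NC alone; a heterozygous AB is a present call (the
shared-marker filter, separately, accepts only homozygous calls).

## Marker placement

Chip annotations ship flanking sequences rather than coordinates, so the
map is built by placing each flanking sequence on a reference assembly
(`build_marker_map()`). Matching is deliberately ungapped: the acceptance
rule of "at most one mismatched base" leaves no room for gaps, so a full
local aligner is unnecessary and exhaustive window scanning semantics are
the contract (`find_hits()` is tested for equality against a brute-force
position-by-position scanner). Hits are gated by the Karlin–Altschul
E-value `E = K·m·n·e^(−λS)` with defaults λ = 1.28, K = 0.46 (the
standard ungapped +1/−2 nucleotide scheme; the E-value is only a
pass/fail gate here, so the exact parameterization is exposed as
configuration rather than hard-coded). Policy decisions that the input
conventions do not settle, made once and centralized:

* **Ambiguous markers are dropped, not multiply placed.** A marker must
  contribute to exactly one chromosome's denominator; a tie on the best
  mismatch count rejects the marker with reason `ambiguous`.
* **N never matches** — in the query or the reference, even N-vs-N — and
  counts as a mismatch. Conservative placement costs a marker at worst;
  a wrong placement corrupts a denominator.
* **Coordinates**: marker positions are 1-based inclusive; windows are
  0-based half-open, and a marker at position p belongs to a window
  `[start, end)` iff `start < p ≤ end`. The conversion lives in one
  internal helper so boundary markers are counted identically everywhere.

## Windows and the coverage test

Windows default to 10 Mb width at a 1 Mb step. The track keeps the final
partial windows (signal runs to the chromosome end); windows with fewer
than `min_expected = 5` mapped markers are flagged undefined rather than
contributing an unstable ratio — marker-sparse windows otherwise flip
between 0 and 1 on a couple of calls. "Expected" is the count of all
mapped markers in the window, not the count conditioned on parental
calls; with ~1% parental missingness the two differ negligibly, and the
unconditioned form keeps the denominator sample-independent.

## The caller

The published argument — the substituted chromosome's missing ratio
"greatly exceeds" all others and the depression "covers the whole
chromosome" — is formalized as three explicit gates
(`caller_params()`):

* absolute: maximum missing ratio ≥ 0.40;
* relative: ≥ 5× the **median** ratio of the other chromosomes (the
  median, not the mean, because a couple of parent-divergent chromosomes
  legitimately sit at ~8% and would inflate a mean);
* coverage: ≥ 80% of defined windows at ratio ≤ 0.7.

Observed separations are comfortable: ~59–61% on the substituted
chromosome against ≤ 8.6% elsewhere is a fold of 7–45 even against the
*highest* background row, and ~50 against the median. The numeric
defaults are this package's policy, sit well inside that margin, and are
echoed in every JSON report. A line passing the ratio gates but failing
coverage is verdict `ambiguous` (segmental-introgression suspect), as is
a tied maximum or a second chromosome above the absolute gate — a double
substitution is biologically possible but is flagged for human review,
never auto-called. Everything below the ratio gates is
`no_substitution`; in particular the alien donor itself (≈42% missing on
*every* chromosome, fold ≈ 1) and euploid parents (≤ 8%, failing the
absolute gate despite a fold that can exceed 5) are rejected for
different reasons, which the report distinguishes.

## The shared-marker filter

Markers on the substituted chromosome that are called, homozygous, and
allele-identical across all substitution lines and the alien donor are
the probes interrogating both homoeologues. "Same homozygous alleles" is
read as the identical homozygous genotype in every queried sample, not
merely homozygosity in each. Exclusion reasons follow the fixed
precedence missing > heterozygous > discordant so the reason counts are
deterministic. AB and NC are the only unusable states — the chip's
internal signal-quality flags are not modeled.

## The simulator

`simulation_config()` / `simulate_genotypes()` generate cohorts with the
statistical structure the analysis assumes, with ground truth for
parameter-recovery tests. Defaults emulate the study conditions: 51,159
features over the 21 wheat chromosomes (IWGSC RefSeq v1.0 lengths to the
nearest Mb), donor cross-hybridization probability 0.577, background
missingness 0.012, parent-divergent chromosomes 2D/7B at 0.079/0.083,
heterozygosity 0.01. Cross-hybridization is drawn **once per marker** and
shared by the donor and all substitution lines — the same physical alien
sequence is interrogated in each — which is exactly what makes the
shared-homozygous filter meaningful; retained substituted-chromosome
calls take the donor's allele for the same reason. Retention given
cross-hybridization defaults to 0.693, chosen so the marginal call rate
on the substituted chromosome is 0.577 × 0.693 ≈ 0.40 and the missing
rate `1 − 0.577·0.693·(1 − 0.012) ≈ 0.605`, matching the ~60% missing /
~40% retained structure the method is built around. Background
missingness in euploid wheat is not directly knowable without raw chip
data; 0.012 reflects the typical 1–2% per-chromosome rates such tables
show.

Deliberate simplifications, hence what passing tests do and do not show:
markers are placed uniformly (chromosome drawn ∝ length), so simulated
per-chromosome marker counts track chromosome length rather than the
array's design density; raw intensities, cluster-calling artifacts and
ambiguous-signal states are not modeled beyond the scalar AB rate; and an
*addition* line is genotypically indistinguishable from euploid wheat
here — an added alien chromosome removes no wheat targets, which is why
addition lines are validated by protein/PCR evidence rather than by chip
missingness, and why the caller makes no attempt to detect them.
Segmental introgressions are likewise out of scope (the coverage gate
flags them as `ambiguous`, it does not call them). Consequently,
recovery rates measured here speak to the decision procedure under the
assumed noise model, not to chip chemistry.

## Numerical choices

* Percentage rendering is one decimal, round-half-even, computed in exact
  integer arithmetic from (missing, mapped) count pairs
  (`percent_from_counts()`), so every printed table cell round-trips from
  its counts.
* Window starts are generated by integer index (`(k−1)·step`), never by
  floating-point `seq()` against an endpoint, avoiding spurious boundary
  windows.
* All simulation randomness derives from the config seed (map at `seed`,
  genotypes at `seed + 1`), run under an internal RNG guard that restores
  the caller's stream; identical configs give byte-identical outputs.
* Degenerate inputs fail loudly with classed conditions
  (`chromsub_config_error`, `chromsub_lookup_error`, ...): empty marker
  sets, unknown samples, maps naming chromosomes outside the config,
  tracks with no defined windows.

## Problem sizes used in the checks

Unit tests run on compact cohorts (3 chromosomes × 500 markers, or 21 ×
250–1,000). The oracle-equivalence checks use a 200 kb reference with 60
planted 50-mers, a 10,000-marker chromosome for the window scan, and a
full simulated cohort for the shared filter; parameter recovery uses 100
substitution cohorts and 100 null cohorts at 1,000 markers per
chromosome, sizes at which the expected separations are many standard
errors wide while a full run stays comfortably interactive.

## Known limitations

The caller assumes a single substitution per line and whole-chromosome
events; telosomes, translocations and disomic additions need cytology or
other marker systems. The E-value gate reproduces gate *semantics*, not
NCBI BLASTN bit-for-bit (no seeding heuristics or composition
statistics). Real arrays exhibit marker-specific failure rates and
spatially correlated missingness that the i.i.d. noise model does not
capture; thresholds were chosen against the large observed separation,
not against those artifacts.
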