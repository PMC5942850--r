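---
title: "Models and methods behind mutcloud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutcloud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutcloud)
```

`mutcloud` packages the quantitative machinery of serial-transfer
experimental evolution with mutator strains: pooled-sequencing diversity
metrics, a replicate-convergence test for beneficial genes, effective
population size, fluctuation-assay mutation rates, phenotype scoring, and
a simulator of the whole design. This vignette explains the models, their
assumptions, the defaults and why they were chosen, and what the test
suite does and does not establish.

## The serial-transfer world

One "day" is a growth–dilution cycle: a culture grows from its bottleneck
size to carrying capacity `n_max`, is censused, and is diluted
`dilution`-fold into fresh medium. A `dilution`-fold dilution permits
`log2(dilution)` generations of regrowth; for the canonical 100,000-fold
dilution that is 16.61 generations — 16 complete doublings plus a
fractional generation that tops the culture up to `n_max`:

```{r}
generations_per_cycle(1e5)
complete_doublings(1e5)
generations_at_day(c(28, 175))
```

This one time structure is shared by the simulator and by the
effective-size calculation, deliberately: `nominal_ne()` computed from the
simulator's censuses equals the harmonic mean of the simulator's internal
per-generation sizes exactly, which the test suite asserts.

## The simulator

`simulate_replicate()` is a discrete-generation Wright–Fisher model on
*haplotypes* rather than sites. Each haplotype class carries a cell count,
a fitness multiplier, a per-genome mutation rate, and the set of its
derived mutations. Linkage is therefore exact — appropriate because the
populations modelled are fully asexual, so every mutation remains tied to
the genome on which it arose (hitchhiking and clonal interference emerge
naturally).

Per generation: the population doubles (multinomial resampling with
expected offspring proportional to `count × fitness`), and each genome
replication receives Poisson(U) new mutations placed uniformly on the
genome. Infinite-sites collisions within a haplotype are re-drawn; U is
orders of magnitude below the genome length so this is negligible but must
be defined. The cycle ends with a multinomial bottleneck of
`round(n_max / dilution)` cells. A fully non-viable population raises an
explicit extinction condition rather than returning empty output.

Assumptions worth naming: synchronous discrete doublings (no continuous
age structure), deterministic total sizes within a cycle (only the
*composition* is stochastic), selection acting each generation through
relative fitness multipliers, and no recombination, demography or explicit
repair biochemistry.

**Distribution of fitness effects.** The source experiments do not
estimate a DFE, so the generator's DFE is a stated convention, not a
measured quantity: by default a new mutation is beneficial with
probability 0.001 (s = +0.1), deleterious with probability 0.3
(s = −0.03), else neutral, as point masses (`dfe_spec()`); an exponential
variant is available. Point-mass effects keep parameter-recovery tests
sharp. The deleterious cost 0.03 follows the conventional value used for
linkage corrections in this literature; the beneficial fraction and effect
are of the order used in microbial evolution modelling. These defaults
were chosen once and are not tuned to test outcomes.

**Mutation-rate evolution.** An optional mutator locus (a position or
window plus a rate multiplier) lets lineages change their genomic rate
when mutated there, and an optional `beneficial_gene` plants a known
target of selection — used to test the power of the convergence scan.

**Sequencing sampler.** `sample_reads()` draws per-site depth
Poisson(mean depth) and derived reads Binomial(depth, frequency); sites
below the detection threshold (default 5% reported frequency, the
practical floor of pooled-sequencing variant callers) or with zero depth
are omitted, the latter tallied in a coverage report. Defaults (depth 200,
threshold 0.05) match a few-hundred-fold pooled sequencing design.

**Fluctuation sampler.** `simulate_fluctuation()` draws Poisson(m)
mutational events and gives each a clone of final size `floor(1/u)`,
`u ~ U(0,1)` — the classical single-clone size law
`P(size = j) = 1/(j(j+1))` under deterministic exponential growth — so the
sampled counts follow *exactly* the distribution that `ld_pmf()` computes.
This compound-Poisson identity is what makes the sampler a legitimate
independent check of the likelihood code (goodness-of-fit is asserted in
the tests at m = 0.5, 2 and 8).

**Scale.** The synthetic defaults (genome 50 kb, `n_max` 10⁵, dilution
10³, 50 cycles, 8 replicates) are a deliberate desk-scale reduction of the
wet-lab design (4.6 Mb, ~10⁹ cells, 10⁵-fold dilution, 175 days). Genomic
mutation rates are kept at the experimental values (U from 0.00034 to
0.036), so the *mutation supply per cycle* is reduced roughly in
proportion to `n_max`. Green end-to-end tests therefore establish
qualitative orderings (diversity increases with U; planted beneficial
genes are recovered), not the wet-lab effect sizes.

## Diversity metrics

At each site the majority allele is the one at frequency p > 0.5; the
consensus sequence is the per-site majority. `site_spread()` returns
`C_n = 1 − p`; `cloud_spread()` averages over *all* genome sites (variant
sites contribute their spread, invariant sites zero), while
`mean_diversity()` divides by the count of positions with non-zero
coverage — two different denominators, both caller-supplied, because the
spread is a genome-scale average while diversity is defined over covered
positions only.

Site diversity is computed as mismatching read pairs over all read pairs:

\[
\pi_n = \frac{m_p\,(m - m_p)}{m(m-1)/2}.
\]

One formulation in the source literature prints the numerator as a mixed
count-and-proportion product; the pairwise-counting definition used here
(count × count) is the only one consistent with "pairwise nucleotide
differences", equals the brute-force enumeration of read pairs (asserted
against an independent oracle in the tests), and is the standard
pooled-sequencing estimator. Sites with depth < 2 have no pairs; they are
excluded and reported.

Edge policies, chosen and logged rather than silent: a site whose top
allele frequency is exactly 0.5 (or tied) has no majority and is excluded
from C and D with a warning; multi-allelic sites take the most frequent
allele as majority; the high-frequency threshold is strict (> 0.5) and
configurable. Mutational spectra fold the twelve raw substitutions onto
six classes anchored at A or C via reverse complementation, with no
pseudo-counts.

## The replicate-convergence test

For gene g of length `l_g`, the null probability that a random
high-frequency mutation lands in it is `p_g = l_g / Σ l` over the gene set
in scope. Given `n_r` distinct mutant genes observed in replicate r
(a gene qualifying twice in one replicate counts once), the null point
probability that exactly the observed `n_g` replicates hit gene g is

\[
P_g = p_g^{\,n_g} \sum_{|S| = n_g} \Big[\prod_{r \in S} n_r\Big]
      (1-p_g)^{\,n_{tot} - \sum_{r \in S} n_r},
\]

summed over all size-`n_g` subsets of replicates. When every `n_r = 1`
this reduces exactly to the binomial pmf — asserted over a grid in the
tests. Enumeration is used while `choose(R, n_g)` is small; otherwise a
dynamic program over (replicates processed, subset size, chosen-sum)
computes the same quantity (equal to enumeration to 1e-12 relative error,
asserted). A Monte-Carlo oracle (`monte_carlo_null()`) simulates the null
directly and also reports the `≥ n_g` tail, since `P_g` itself is a point
probability, not a tail — users should know that the conventional
threshold `P_g < 5×10⁻⁵` (0.005%) is applied to the point statistic with
no further multiple-testing correction, mirroring standard practice for
this test.

Intergenic high-frequency alleles are excluded from the test (the null is
defined over genes) but reported. An optional ancestral mask removes
standing variants shared across replicates, because shared ancestral
mutations violate the test's independence assumption; it is off by
default so that both views are available.

## Effective population size

`nominal_ne()` is the harmonic mean of every size in every sampled day's
ladder — the bottleneck, each doubling, and the final stationary census
(18 values per day at 10⁵-fold dilution; the final fractional generation
is included as the census itself). Non-10⁵ dilutions generalise via
`floor(log2(dilution))` doublings plus the census. Days whose colony
counts fail plate QC (fewer than 20 or more than 700 colonies) are
dropped, with the day count adjusted. Linkage-corrected estimators
(background selection / interference) are *not* re-implemented — their
formulas belong to external published code — so `linkage_ne_hook()` is an
explicit pass-through that records parameters and accepts a user-supplied
estimator.

## Fluctuation-assay likelihood

The model class is Lea–Coulson/MSS: deterministic exponential growth,
full plating, no phenotypic lag, no differential mutant fitness. The pmf
recursion is

\[
p_0 = e^{-m},\qquad p_k = \frac{m}{k} \sum_{i=0}^{k-1} \frac{p_i}{k-i+1},
\]

maximised over m by golden-section search; the 95% CI is the profile
likelihood at a log-likelihood drop of `qchisq(0.95, 1)/2 = 1.92`. The
per-division rate is `mu = m̂ / mean(N_t)` (tube-level N_t are averaged
because a single per-strain rate is reported). Counts at or above
`count_cap` (default 512) are treated as right-censored through the tail
mass — jackpot cultures are plated but not countable, and censoring keeps
the quadratic recursion tractable without discarding them. All-zero
counts give the boundary MLE m̂ = 0 with the one-sided bound solving
`n·m = 1.92`. The published program this replaces is not described in
detail anywhere accessible, so this model class is documented as such
rather than claimed identical; `plating_fraction` is carried on the data
container as the designated extension point but values below 1 are
rejected rather than approximated.

Drake-style conversion divides by C = 71 — the number of distinct rpoB
single-nucleotide changes known to confer rifampicin resistance — and
multiplies by L = 4,641,652 bp for the genomic rate; both are arguments,
not constants, and the enumeration behind C = 71 is out of scope.

## Phenotype metrics

`fit_logistic()` fits `N(t) = K/(1 + ((K−n0)/n0)e^{−rt})` by bounded
nonlinear least squares with a grid of growth-rate starts, K started at
the maximum reading and n0 at the first positive reading. Wells whose
dynamic range is below a noise floor are flagged `non_growing` with
`r = NA` rather than given a spurious rate. Blank subtraction is an
explicit `blank` argument defaulting to zero: always subtracting the
first reading would change the model family (the first reading *is* n0
plus noise) and make exact parameter recovery impossible; the caller
knows whether a media blank exists. Relative fitness is `r_evo − r_anc`
with the reference averaged over same-plate replicates; `curve_auc()` is
the trapezoidal area above the initial reading, converging to the
analytic logistic integral as the grid refines.

Endpoint (Biolog-style) scoring: `B = A_24h − A_10m` per well;
`noise_threshold()` estimates the detection floor as the 99th percentile
of pairwise 10-minute differences within condition (the conventional
fixed value 0.097 can be passed wherever a threshold is accepted);
`select_concentration_well()` picks, per compound, the concentration with
the highest variance of the matched evolved-minus-ancestor difference
(ties to the lowest index, logged); gain/loss calls use strict
inequalities so a difference exactly at threshold is noise. The stress
fold change `G = (A_X,E/A_X,A)/(A_ctrl,E/A_ctrl,A)` cancels evolved
carrying-capacity changes; its natural-log transform is attached because
log fold changes are reported for some stressors (the log base is not
stated in the source convention; natural log is assumed and both values
are emitted). G is conventionally averaged over triplicate cultures
before comparison.

## Numerical and design choices

- RNG: every stochastic entry point takes a seed; replicate seeds derive
  deterministically from the root seed (`child_seed()`), kept below 2³¹.
  Identical config + seed gives byte-identical pipeline output (manifest
  checksums are compared in the tests).
- The enrichment DP guards the exponent `n_tot − Σ_{r∈S} n_r ≥ 0` by
  construction; `p_g = 0` with observed hits returns `P_g = 0`; `n_r = 0`
  replicates contribute factor zero to subsets containing them.
- pmf truncation: the likelihood evaluates the pmf to the largest
  uncensored count; censoring (above) bounds that at `count_cap`.
- Coordinates are 1-based inclusive everywhere (GFF3/breseq convention);
  readers reject position 0 with a coordinate-convention error.

## Limitations

- The simulator reduces scale (population size, genome, cycles); wet-lab
  effect sizes, absolute diversity levels, and anything driven by rare
  events at census 10⁹ are outside what a green test establishes.
- A reported "cube-root of diversity" convention in the source literature
  is inconsistent with C ≤ 0.5 for one strain and is treated as a
  transcription issue: no such transformed values are reproduced here.
- Downstream inferential statistics (mixed-effects models, rank tests,
  PCA) are deliberately out of scope: the package emits tidy tables for
  standard tools (`lme4`, base R).
- The fluctuation model omits phenotypic lag, differential mutant
  fitness, and partial plating; rates for indels or loci other than the
  reporter are not covered, so genomic rates may be underestimates.
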