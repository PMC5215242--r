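---
title: "Inferring meiotic recombination events from octad sequencing"
author: "octadRecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring meiotic recombination events from octad sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octadRecomb)
```

# The measurement

Meiotic recombination repairs programmed double-strand breaks (DSBs) using
the homologous chromosome, producing crossovers (COs, with reciprocal
exchange of flanking sequence) and noncrossovers (NCOs). Both pass through
heteroduplex DNA (hDNA) — a duplex whose two strands come from different
parents. In a polymorphic hybrid (e.g. S288C x SK1 budding yeast, with a SNP
roughly every 160 bp), hDNA is visible wherever it covers a marker, but only
if mismatch repair does not erase it. In an *msh2*-deficient hybrid most
hDNA survives, so virtually every interhomolog strand-transfer event leaves
a genotypic footprint.

Octad sequencing resolves that footprint to single strands: the four spores
of one meiosis are each allowed one mitotic division, and both daughter
cells are sequenced. The two daughters carry the two strands of the spore's
chromatid, so an hDNA tract appears as a disagreement between daughters
(5:3 segregation of the marker across the eight strands), a full conversion
as a 6:2, and a CO as a reciprocal 4:4 phase switch between two spores.

This package implements the full analysis from per-SNP read counts to:
called strand genotypes, segmented CO/NCO events with hDNA
sub-classification, gene-conversion tract lengths under three measurement
conventions, and crossover-interference estimates. A strand-resolved
simulator with exact ground truth makes each stage testable end to end.

# Genotype calling

A SNP genotype for one strand library is **valid** when

* only one parental allele has reads and its count lies in **[15, 150]**, or
* both alleles have reads, the more abundant count lies in **[40, 150]** and
  the less abundant is strictly **below 5**.

Anything else is missing. Both bounds are read inclusively and the minority
cutoff strictly, the plain reading of the rule; all five thresholds are
fields of `GenotypeCallConfig`, so the alternative readings are one
configuration edit away. Equal nonzero counts have no "most abundant"
allele and are missing by definition. The rule is deliberately conservative:
at 70X depth almost every marker is called, while chimeric or contaminated
libraries fail loudly as missingness.

# Event inference

`inferEvents()` composes five deterministic stages.

**Segregation profile.** Per marker, the P1:P2:missing counts over the eight
strands; 4:4 with no missing call is Mendelian.

**Phase background.** Per spore and chromosome, runs of concordant
homoduplex markers are collected. Runs spanning at least `minPhaseBlockBp`
(default 10 kb) anchor parental phase blocks; runs touching a chromosome end
anchor at the merge distance (1.5 kb), since a crossover close to a telomere
leaves only a short distal block. A short run that deviates from its
surroundings is normally a candidate conversion tract — but if its markers
still segregate 4:4 with no missing strand it *cannot* be a conversion
(full conversion is 6:2, retained hDNA 5:3) and is promoted to a phase
block. This promotion is what distinguishes a closely spaced double
crossover (4:4 throughout, two switches) from a conversion tract (one
island of perturbed segregation). Between adjacent anchors of opposite
phase, the switch point is placed by a changepoint that maximises phase
agreement of the intervening markers, and the crossover coordinate is the
midpoint of the final marker interval. Spores with no informative
homoduplex marker on a chromosome are flagged uncallable.

**Tract detection.** Per spore, maximal runs of markers whose duplex state
deviates from the background — heteroduplex (HET), opposite-phase
homoduplex, or a one-strand observation carrying the opposite parent. Runs
bridge up to `maxMissingRun` (default 2) uninformative markers, tolerating
the sparse missingness left by the read-count filter without fusing
distinct events. Each deviant marker is annotated with the daughter strand
carrying the donor allele, relative to one reference phase per run (the
background at the run's first deviant marker, so a tract that straddles a
crossover's background split keeps a coherent donor side).

**Merging.** Tracts and phase switches whose gap — measured between nearest
affected markers — is strictly less than `mergeGapBp` (default 1500) are
combined by single-linkage into one event, attributed to one DSB. A switch
contributes the interval between its flanking homoduplex markers.

**Classification.** An event is a **CO** iff its cluster contains a
reciprocal pair of phase switches on two spores; otherwise an **NCO**.
Tract patterns determine the category:

| category | pattern |
|---|---|
| `full_conversion` | both strands of one spore converted (6:2) |
| `SDSA_like_hDNA` | one contiguous one-strand HET tract on one spore |
| `trans_hDNA` | donor-carrying strand switches sides exactly once |
| `symmetric_hDNA` | complementary HET tracts on two opposite-phase spores |
| `complex` | anything else, including uncallable spores in the interval |
| `none` | a crossover with no detectable conversion tract |

`none` extends the category set: a CO whose hDNA tract fell between markers
has no measurable tract, and such events are excluded from tract-length
summaries.

## Tract-length conventions

The measurement convention behind published tract lengths is often
unstated, so all three are computed:

* **min** — `pos(last affected) - pos(first affected) + 1`;
* **mid** — between the midpoints of the two flanking marker intervals
  (the default headline statistic);
* **max** — just inside the nearest informative unaffected markers.

`min <= mid <= max` always, and the true tract length lies in
`[min, max]` whenever the event is correctly delimited. A side with no
informative flanking marker clamps to the chromosome end and is the reason
`max` can be conservative near telomeres. Resolution is about one marker
spacing (~160 bp at the default density): `min` loses and `max` gains
roughly one spacing, `mid` is close to unbiased. Summary medians computed
over *all* events additionally include merged multi-DSB clusters, which are
genuinely longer; at the default event densities (~190 events per 12 Mb
genome) this inflates the median by a few percent.

# Interference statistics

Inter-crossover distances are successive differences of CO midpoints per
chromosome (chromosomes with fewer than two COs contribute nothing), pooled
across chromosomes and meioses within a genotype. The field-standard model
is a gamma distribution for the gaps; its shape $\gamma$ is the
interference statistic ($\gamma = 1$ none, $\gamma > 1$ positive).

`fitGammaMle()` maximises the gamma likelihood directly: the shape solves
the score equation
$\log k - \psi(k) = \log \bar{x} - \overline{\log x}$
by Newton iteration safeguarded with bisection (the right side is positive
for any non-degenerate sample, and the left side is strictly decreasing, so
the root is unique); the scale MLE is $\bar{x}/k$. The fit is deterministic
and its log-likelihood is verified in the tests against a dense grid search
to $10^{-6}$ nats and against an independent general-purpose optimiser.
Degenerate inputs (fewer than two gaps, nonpositive values, zero variance)
fail with an explicit reason. Shapes are reported to one decimal in
summaries.

Two deliberate simplifications, both configurable by the caller upstream:
gaps are pooled per genotype rather than fitted per chromosome (per-
chromosome fits are available by splitting the gap table), and
chromosome-end censoring is ignored — the fit describes the observed
within-chromosome gaps, like a plain gamma fit to the measured distances.
On finite chromosomes the conditioning on "two or more COs" removes the
longest gaps, which biases the pooled shape slightly upward; at the scale
of a few meioses this is within the sampling spread of the estimator.

Distribution comparisons use a two-sample Kolmogorov-Smirnov test (gap
distributions) and a Wilcoxon rank-sum test with mid-ranks (tract lengths).
For small samples both compute *exact* p-values by enumerating all
assignments of the pooled values to the two groups, which remains correct
under ties — a case the textbook exact formulas do not cover; larger
samples use the asymptotic Kolmogorov tail and the tie-corrected normal
approximation (without continuity correction, so the large-sample p-value
approaches the enumerated null). Pairwise comparisons are reported raw,
with no multiple-testing correction, matching how such panels are usually
presented.

# The simulator

`simulateMeiosis()` generates strand-resolved octads with exact ground
truth. It emulates the study conditions; every generative choice is a field
of `SimParams`.

| parameter | default | rationale |
|---|---|---|
| `chromLengths` | 16 yeast chromosomes, 12.07 Mb | the hybrid's genome |
| `snpDensity` | 74911 / 12071326 per bp | the hybrid's SNP list scale |
| `gammaShape` | 2.3 | wild-type interference strength |
| `meanInterCo` | 130 kb | ~90 COs per meiosis genome-wide |
| `ncoRate` | 8e-6 per bp | ~95 NCOs per meiosis, the scale seen in MMR-deficient hybrid octads |
| `tractLenDist` | exponential, median 1 kb | geometric-like stand-in for the unreported tract-length family; median echoes wild-type |
| `pTransHdna` | 0.3 | trans tracts are a substantial minority of retained-hDNA NCOs |
| `pSymHdna` | 0.03 | symmetric hDNA is rare (a few events per meiosis at most) |
| `mmrActive` | `FALSE` | *msh2*-deficient: hDNA retained |
| depth | 70 | study sequencing depth |

Crossovers follow a **stationary gamma-renewal process**: the first point is
drawn from the equilibrium forward-recurrence distribution, whose CDF for
gamma(k, $\theta$) gaps is
$F_e(x) = [x(1 - F_k(x)) + k\theta F_{k+1}(x)]/(k\theta)$,
inverted numerically; subsequent gaps are i.i.d. gamma. Stationarity keeps
the observed gap statistics unbiased along the chromosome, which is the
model implicitly assumed when a plain gamma is fitted to observed gaps.
Each CO joins two chromatids of **opposite parental phase at the exchange
point** — a meiotic CO is an interhomolog exchange, and after earlier COs
the original "two per parent" grouping no longer determines local phase.
Exchange is applied from the point to the higher-coordinate chromosome end;
the mirrored orientation produces distribution-identical octads, so one
fixed orientation is used. Each CO deposits an hDNA tract abutting its
exchange point on one partner. NCOs are Poisson along the chromosome; a
tract is written as one-strand hDNA (SDSA-like), trans (donor strand
switches at a uniform split), or symmetric (complementary one-strand tracts
on two opposite-phase chromatids), at the configured probabilities. With
`mmrActive = TRUE` each tract instead becomes a full conversion with
probability `pConversion`, else an invisible restoration.

Events that would overlap an existing event on the same chromatid are
redrawn up to `maxRetries` and then dropped and counted (`collisions`),
because the inference stage assumes separable DSBs. One root seed yields
deterministic per-chromosome child seeds. Ground truth records every
exchange and per-strand transfer segment; replaying it
(`octadFromTruth()`) reproduces the emitted matrix bit for bit, which is a
standing test invariant. A truth event whose tract covers no marker writes
nothing into the matrix; such events are recorded with `nMarkers = 0` and
are excluded from recall on the marker-visible side (a CO remains visible
through its flank exchange).

**What the simulator does not emulate:** alignment and mapping artifacts,
indels and repeat-region marker exclusions, DSB hotspot structure and
chromatid interference, multi-chromatid complex events beyond the listed
categories, aneuploidy or incomplete octads (the pipeline requires all
eight strands and flags anything less). Passing round-trip tests therefore
demonstrates algorithmic correctness under the stated generative model, not
robustness to every artifact of real sequencing data.

## Evaluation conventions

Round-trip evaluation (`matchEventsToTruth()`) calls a truth event
recovered when an inferred interval overlaps it, and scores CO/NCO labels
only on **isolated** events: no other truth event within twice the merge
distance (switch intervals extend to flanking homoduplex markers, so events
between one and two merge distances apart can legitimately merge), and more
than 3 kb from chromosome ends, where no distal phase block remains to
anchor the CO/NCO distinction. Both margins are statements about what is
identifiable, not tuning knobs: closer events genuinely collapse into one
DSB under the stated merging rule, and a terminal exchange is genuinely
ambiguous against a terminal conversion.

## Problem sizes

The test suite simulates reduced genomes (single chromosomes of 0.2-1 Mb)
for unit checks and the full 16-chromosome genome for round-trip checks (20
octads at 70X), enumeration oracles up to a few thousand assignments, and
parameter-recovery sweeps of 50 genotypes at 300 gaps each — sizes chosen
so the whole suite runs in a couple of minutes while keeping every
statistical tolerance at three standard errors or better.

# Known limitations

* Events within the merge distance of each other are one event by
  definition; the per-DSB attribution cannot be recovered.
* Near telomeres the CO/NCO distinction rests on a short terminal block;
  below ~1.5 kb of distal homoduplex sequence it is not identifiable.
* The gamma fit ignores end censoring; a censored-likelihood variant would
  be needed for very short chromosomes or very weak CO density.
* Tract-length medians are resolution-limited by marker spacing and
  include merged clusters (see above); comparisons between genotypes
  measured the same way are unaffected.
* Incomplete octads (e.g. seven recovered cells) are rejected rather than
  imputed.
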