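---
title: "Calling meiotic crossovers from pedigree SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling meiotic crossovers from pedigree SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstrace)
```

## The problem

Each meiosis places a small number of crossovers along every chromosome —
roughly 24 genome-wide in human male meiosis and 40 in female meiosis, the
familiar ~1.7-fold sex asymmetry. Crossovers cannot be observed directly at
scale; they are inferred from the way SNP alleles travel through a pedigree.
`pstrace` implements two single-marker inference schemes over biallelic SNP
genotypes (`AA`/`AB`/`BB`/`NoCall`) and everything downstream of them:
recombination maps, arm-level regressions, and annotation correlations.

## Parent-sibling tracing (PST)

PST needs only a two-generation pedigree with at least two genotyped
siblings. A marker is *informative* for the paternal side when the father is
heterozygous and the mother homozygous: each child's genotype then reveals
which paternal allele it received. Over a sibling pair the informative
markers are coded

* `1` (IDENTICAL) when the two siblings have the same genotype — they
  received the same paternal allele, hence the same paternal haplotype;
* `0` (NOT_IDENTICAL) otherwise;
* uninformative everywhere else (wrong parental configuration, missing
  calls, or a Mendelian inconsistency in the family at that marker).

Along a chromosome the code is piecewise constant; a state switch marks a
crossover in *one of the pair's two* paternal meioses (more precisely, an
odd number of crossovers between the flanking informative markers — the
pair code sees the parity of the two meioses combined). The maternal side
is symmetric.

## The three-generation IBD comparator

With both paternal grandparents genotyped, each child can be coded directly:
the allele the father transmitted is resolved by subtracting the mother's
contribution, and is then assigned to the grandfather (GF) or grandmother
(GM) when exactly one carrier assignment is Mendelian-consistent. A GF↔GM
switch marks a crossover in the father's meiosis, now attributable to a
single child. All logic is single-marker by design — no multi-marker
phasing — so each marker is independently informative or not.

## Switch detection and uninformative regions

Both codings share one scan (`detect_switches()`). Runs of an informative
state shorter than `min_run` are recoded as uninformative noise — isolated
code flips are the signature of genotyping error, which at per-call error
rates of a few per mille would otherwise create hundreds of spurious events
per dataset. `min_run = 3` is the default for noisy array data; `min_run =
1` reproduces the idealized schema and is what all truth-recovery checks
use, since the simulator's error-free data contain no isolated flips.

Each accepted state change yields one event whose *uninformative region*
runs from the last informative marker of the old state to the first
accepted marker of the new state (`left_pos`, `right_pos`, both 1-based;
BED output converts to 0-based half-open). `n_uninformative` counts the
markers strictly between the flanks. A switch at a terminal informative
marker is still an event; nothing is extrapolated beyond the terminal
informative markers.

## Attribution and counting

For families with three or more siblings, pairwise events are clustered by
interval overlap and assigned by parity: a crossover in child *c* must show
up in every pair containing *c* and in no pair excluding it. Any other
support pattern (e.g. a cluster seen only in one pair of three) is reported
`UNATTRIBUTED` rather than guessed. For two-sibling families events stay at
pair level: the pair code aggregates the parent's two meioses, and a
pair-level event contributes 1 to the family's per-parent total. Per-meiosis
summaries therefore treat a pair as two meioses (`rate = count / 2`), which
recovers means correctly but understates the between-meiosis variance; the
unit table records `n_meioses` so downstream users can weight as they
prefer.

chrX is analyzed for maternal meioses only; there is no paternal
recombination to assay there, and the callers skip it for the paternal side.

## The simulator

`simulate_dataset()` generates the structure the callers assume, with known
truth:

* founder haplotypes drawn independently per marker with B-allele frequency
  ~ Uniform(`maf_range`), default (0.2, 0.5) — array panels are ascertained
  toward common variants;
* per meiosis, K ~ Poisson(sex-specific map length in Morgans) crossover
  positions uniform on the chromosome, no interference, gametes formed by
  alternating haplotype segments from a random starting phase;
* default sex maps distribute 23.8 (male) and 39.5 (female) Morgans over
  the chromosomes proportionally to physical length, so the headline sex
  asymmetry (39.5/23.8 ≈ 1.66) is recoverable;
* genotyping noise: a call is replaced by a uniformly chosen different call
  with probability `genotype_error_rate` (default 0.005) and dropped to
  NoCall with probability `nocall_rate` (default 0.02) — typical for array
  data passing a 90% call-rate QC;
* chrX is modelled as a diploid chromosome with male map length 0, so only
  maternal meioses recombine there. Male hemizygosity itself is not
  emulated; since the callers never use paternal chrX information, this
  simplification does not touch any analyzed code path.

What the simulator does **not** emulate: linkage disequilibrium between
markers, allele-frequency ascertainment structure, crossover interference,
gene conversion, batch- or sample-specific error profiles. Passing the
simulated checks therefore demonstrates correctness of the calling logic
and its statistics, not robustness to every artifact of real array data.

## Numerical and convention choices

* QC excludes samples with call rate strictly below 0.90 (boundary samples
  retained), then individuals left without pedigree links; the filter is
  idempotent.
* Marker positions are 1-based; all BED input/output is 0-based half-open.
* Events are anchored at the midpoint of their uninformative region for
  binning — deterministic and unbiased for symmetric intervals.
* Bins are 1 Mb by default, the last bin truncated at the chromosome end; a
  bin is "covered" when it contains at least one array SNP, and uncovered
  bins are masked from regressions and correlations.
* Centromere distance is measured from the nearest centromere boundary to
  the bin midpoint; arms with fewer than 3 covered bins return NA.
* Quartiles use the linear-interpolation convention (R type 7).
* Degenerate regressions are given explicit conventions: zero residual
  variance yields p = 1 for a zero slope and p = 0 for an exact nonzero
  linear relation; a paired t-test over constant zero differences yields
  t = 0, p = 1; a single pair leaves t undefined (NA).
* Tandem repeats are grouped by length as Q1 ≤ 4 bp, Q2 5–15, Q3 16–24,
  Q4 ≥ 25; the boundary value 25 goes to Q4. "Length" is the annotated
  interval's length attribute (the repeat array span), not the repeat unit
  period.
* Annotation correlations are Bonferroni-adjusted over the number of
  classes tested and capped at 1.

## Validation design and problem sizes

The acceptance-style checks run at desk scale, chosen so the whole suite
completes in minutes: truth recovery on 20 families × 3 siblings over 4
chromosomes (parity-exact agreement between truth and both callers);
union-equivalence of PST pair events and per-child IBD events on the same
simulated input; genome-wide mean recovery on 250 two-sibling families (500
meioses per sex) over 23 chromosomes at 6,000 markers per chromosome —
denser grids approximate the ~900K-marker arrays this pipeline targets, and
detection losses at chromosome ends and from even-parity cancellation
shrink inversely with marker density; statistical oracles on 30-element
vectors; and 100-replicate planted-signal recovery for the annotation
correlations.

## The PST-vs-IBD comparison: a caveat

On matched events our comparison op reports means, SDs, quartiles and a
paired t-test of the two methods' uninformative-region sizes. Under the
single-marker IBD schema implemented here — which uses the co-parent to
resolve the transmitted allele — the probability that a marker is
IBD-informative is h·(1 − h/2)², slightly *above* PST's h·(1 − h) for every
heterozygosity h, because IBD can exploit markers where both parents are
heterozygous. In simulation the IBD comparator consequently bounds
crossovers a little more tightly than PST, and with array-level noise the
gap widens (the pair code accumulates the genotyping errors of two
children). Published comparisons that favor PST rest on stricter
three-generation call tables than the reconstruction used here; users
comparing methods on real data should treat the direction of the difference
as schema-dependent, not as a fixed property of the two pedigree designs.

## Limitations

* Attribution in two-sibling families is fundamentally pair-level; an odd
  number of co-located crossovers in the two meioses is one event, an even
  number is invisible.
* All coding is single-marker; no use is made of surrounding-haplotype
  likelihoods, so the method trades power for robustness and transparency.
* Uninformative-region sizes are lower-bounded by marker spacing; sparse
  panels inflate them roughly in proportion.
* The Poisson, no-interference crossover model makes simulated double
  crossovers in short windows somewhat more common than in real meiosis;
  truth-recovery rates on real data should if anything be easier.
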