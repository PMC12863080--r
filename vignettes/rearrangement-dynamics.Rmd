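---
title: "Measuring genome rearrangement dynamics within bacterial species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome rearrangement dynamics within bacterial species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synbreak)
```

## The problem

Closely related bacterial strains usually share an almost identical gene
order. When that order is broken — by an inversion that reverses a stretch
of the chromosome, or a translocation that relocates it — the breaks leave a
signature in the order of shared single-copy genes. `synbreak` measures
that signature within a species: how many syntenic blocks each genome is cut
into relative to a reference strain, what kinds of events produced them,
where they sit relative to the replication origin, how fast they accumulate
relative to nucleotide substitutions, and what functions the rearranged
genes carry.

The package analyzes one species at a time: a set of complete, circular
genomes with gene annotations and ortholog family assignments, plus a
concatenated core-gene alignment. Ortholog inference itself is upstream:
`synbreak` consumes family labels, it does not compute them.

## Core genome and signed permutations

A family is *core* when present in at least a fraction `freq` (default
0.90, inclusive) of the genomes and single-copy in every genome where it
occurs. Families duplicated in any genome are excluded outright: a
duplicated family has no unique position in a gene-order permutation, and
within-species duplicates are more often paralogs than positional markers.
Each genome is then reduced to its *signed circular permutation*: core
families in chromosomal order, signed by strand. Accessory genes are
skipped but counted per inter-core interval so that block gene contents can
later include them.

When two genomes lack different core families (possible at `freq` below 1),
a pairwise comparison uses the intersection of their permutations:
breakpoints are only defined on shared markers.

## Blocks, breakpoints and event classification

For a reference--query pair, a *syntenic block* is a maximal run of shared
core families that is consecutive in both genomes, in identical or fully
reversed order. Equivalently, a *breakpoint* is a query adjacency whose
family pair is not adjacent on the reference circle; blocks are the arcs
between breakpoints. Both chromosomes are treated as circular — the first
and last permutation elements are adjacent — which is what makes one
inversion cut the circle into exactly 2 blocks and one translocation into
3. Single-gene runs are discarded (a lone out-of-place core gene is more
plausibly an orthology error than a one-gene rearrangement) but reported.

The largest block (most core genes; ties broken by total gene count, then
by smallest reference coordinate) is the *backbone*, the unrearranged
frame; the other n−1 blocks are the *rearranged* ones. A genome with a
single block shows no rearrangement at all. Non-backbone blocks whose gene
order is reversed relative to the reference are classified as inversions
(they normally also flip strand signs; an order-reversal without sign flips
is logged and still counted as an inversion, since order is the primary
signal and per-gene strand annotations are occasionally noisy), the rest as
translocations.

Two practical safeguards:

* *Orientation canonicalization*: if reversing the whole query permutation
  and flipping its signs strictly reduced the breakpoint count, the
  reversed representation would be used, so an assembly deposited on the
  opposite strand is not misread as one giant inversion. (With order-based
  adjacency the breakpoint count is actually reversal-invariant, so this is
  a guard rather than an active transformation; a full reverse-complement
  already yields a single reverted backbone and zero events.)
* *Reference selection*: the species reference is the genome minimizing the
  average block count against all others — the layout closest to everything
  else, in practice the most ancestral-like strain. Reference
  self-comparisons (one block by definition) are excluded from species
  means.

To avoid counting one historical event many times across genome pairs,
blocks are deduplicated by a canonical identity key (the lexicographically
smaller of the signed family tuple and its reversed, sign-flipped
counterpart); keys occurring more than twice in a species are dropped
entirely. Note the key is orientation-normalized, so the same segment
relocated in one strain and inverted in another maps to one key — by
design, since either way it is one segment's history.

```{r blocks-demo}
ref <- core_order(1:8)
qry <- plant_rearrangements(core_order(1:8), list(
  list(type = "inversion", start = 3, len = 2)))$order
find_blocks(ref, qry)$blocks[, c("families", "n_core", "orientation",
                                 "classification")]
```

## Ori, Ter and replichore-relative positions

The origin (Ori) and terminus (Ter) of replication are located from the
cumulative GC skew: per consecutive non-overlapping 1 kb window,
S = (G − C)/(G + C) (0 for windows without G or C); the cumulative sum
falls along one replichore and rises along the other, so its global minimum
marks Ori and its global maximum Ter. Non-overlapping windows are the
standard choice for cumulative skew; at 1 kb resolution a sliding stride
changes nothing material, and the stride is not exposed as a tuning knob. A
trailing partial window is dropped.

Profiles are flagged *ambiguous* — and excluded from positional analyses —
when a secondary local minimum (or maximum) has prominence of at least 20%
of the cumulative range and lies at least 5% of the genome away from the
global one, or when the curve carries no signal. The underlying published
criterion is visual ("multiple peaks and valleys"); this prominence rule is
our explicit stand-in, and both thresholds are exposed. A skew-free genome
produces a random-walk cumulative curve that this rule flags in the large
majority of cases (about 90% of simulated skew-free 1 Mb genomes), not in
every case — a walk can by chance look single-valleyed.

Each deduplicated rearranged block is mapped to its replichore-relative
midpoint position d ∈ [0, 1]: 0 at Ori, 1 at Ter, linear in arc distance
along whichever of the two Ori→Ter arcs contains it. Deviation from the
neutral expectation (mean 0.5) is tested with a two-sided one-sample
Wilcoxon signed-rank test against 0.5, reporting the direction ("Ori" if
the median is below 0.5, else "Ter"). The published analysis did not state
sidedness; two-sided with a reported direction is the conservative choice.
The neutral reference is the constant 0.5 rather than a genome-specific
null for unequal replichore lengths; the synthetic generator accordingly
plants equal replichores.

## From block counts to event counts and rates

Because one event produces 2 or 3 blocks and overlapping events produce
fewer blocks than the sum of their parts, block counts are converted to
event counts through a simulation calibration: k random events (inversion
with probability 0.5, else translocation; segment lengths uniform on
[2, C/10] by default, truncated to [2, C−2]) are applied to an identity
permutation of C core genes, the mean retained-block count is recorded per
k, and a quadratic `blocks = a + b·k + c·k²` is fitted by least squares.
The event mix and segment-length law are not pinned down by published
methods; both are explicit parameters, and the calibration is rerun per
species core size.

Inverting the quadratic for an observed block count B takes the smallest
non-negative real root — the fewest events explaining the blocks — with a
linear fallback when the quadratic term is negligible and a clamp at zero.
B = 1 maps to N = 0 identically: one block is the definition of "no
rearrangement". One numerical caveat, visible in the calibration
diagnostics: the true curve is piecewise (exactly 1 block at k = 0, then
about 2.5 blocks per event), so the fitted intercept `a` lands well below
1 — around 0.4 — rather than near 1. The fit is used only inside the
observed block range, where its round-trip error is small (parameter
recovery is within ±1 event for k ≤ 5 and within 25% for k ≤ 10 at
C = 500), and the B = 1 special case removes the one point where the
intercept would mislead.

The rearrangement rate of a genome pair is

B_cs = N / (C · S · L)

with N the predicted event count, C the core genome size in genes, S the
number of substitutions between the pair on the concatenated core alignment
(columns where both genomes carry an unambiguous A/C/G/T and differ; gapped
or ambiguous columns are excluded from both S and the comparable length),
and L the alignment length in nucleotides. The published formula's
typesetting is ambiguous ("Bcs=NC⋅S⋅L"); the accompanying prose — the rate
is the number of predicted rearrangements *divided by* the product of core
size, substitutions and alignment length — fixes the reading N/(C·S·L)
implemented here. Substitution counts stand in for maximum-likelihood
distances, which would require an external phylogenetics pipeline; a square
PHYLIP distance matrix can be supplied instead via `read_phylip_distances()`
and `estimate_rates(distances = )`, in which case S is distance × comparable
length.

## COG enrichment of rearranged blocks

For each COG (tested at the one-letter category or the COG-id level), a
2×2 table compares rearranged-block gene content against whole genomes:
genes with this COG in rearranged blocks, other genes in rearranged blocks,
genes with this COG across all genomes, other genes across all genomes.
Block gene content includes the accessory genes lying between a block's
core genes. Single-block genomes and backbone blocks are excluded from the
block side. The genome-wide side deliberately includes the block genes —
that is the published contingency layout, reproduced as described even
though it double-counts; a `disjoint = TRUE` flag subtracts the block
counts for users who prefer disjoint columns. Each table gets a Pearson
chi-square (df = 1, no continuity correction); p-values are
Benjamini–Hochberg corrected within each scope (translocations, inversions,
or all — the published text does not say whether its correction pooled
scopes, so correction is per scope); a COG is *enriched* when q < 0.05 and
its block frequency exceeds its genome-wide frequency. Tables with an
expected cell below 5 are flagged rather than rerouted to an exact test,
matching the published chi-square-only analysis. Unannotated genes count
toward the "other" totals but are not tested themselves.

## Statistical kernel

The signed-rank, rank-sum, Spearman, chi-square, BH and quadratic-fit
primitives are implemented in the package and cross-checked in the test
suite against independent oracles (full enumeration of sign patterns and
orderings on small samples, `stats::wilcox.test`, `chisq.test`, `p.adjust`,
`lm`). Conventions: zero differences are discarded (classic Wilcoxon, not
Pratt); signed-rank p-values are exact (subset-sum enumeration) for n ≤ 25
without ties, rank-sum p-values exact for a smaller group of ≤ 8 without
ties, both otherwise normal approximations with tie and continuity
corrections; Spearman p-values use the t approximation with n − 2 degrees
of freedom; BH is the step-up procedure with enforced monotonicity.

## The synthetic species generator

`make_species()` builds the statistical structure the analysis assumes,
with full ground truth: one ancestor (core families in identity order,
accessory genes attached to the core gene they follow, COG categories drawn
from realistic base frequencies with a 2% mobilome class and 10%
unannotated), and descendants along a star genealogy. A star — rather than
a sampled coalescent — keeps per-branch truth independent, which is what a
generator used for validation needs; within-species clonal structure is
nuisance for every question the package asks. Per branch: a Poisson number
of rearrangement events (default mean 1, the typical single event per
genome regime) applied through the same event model the calibration uses;
Poisson substitutions placed without replacement on a generated core
alignment, so pairwise truth counts are exact at desk scale; a GC-skewed
sequence with planted Ori at 25% and Ter at 75% of the genome (equal
replichores, matching the positional test's neutral reference); and
mobilome planting — genes inside the genome's rearranged spans (its
non-backbone blocks relative to the ancestor) are relabeled to the
transposase-carrying mobilome class at `transposase_boost` (default 5)
times the 2% base rate, leaving a recoverable enrichment signal.

Defaults are desk-scale study conditions: 10 genomes (the source study
required more than five per species), C = 100 core families, 0.5 accessory
genes per interval, 500 kb genomes, 900 bp genes, 0.002 substitutions per
site per branch. What the generator does *not* emulate: indels and
recombination on the alignment, gene gain/loss on the branches (the core is
exactly shared), multi-chromosome or linear genomes, and real annotation
noise beyond the strand-flip tolerance. Passing tests therefore validate
the machinery on data that satisfies the model's assumptions; they do not
certify behavior on assemblies that violate them (misassemblies,
contamination, wrong species assignments).

## Orchestration and reported sizes

`run_pipeline()` chains the stages (core calling → reference selection and
block partitioning → GC-skew and positional bias → calibration and rates →
enrichment) on a `species_set`, a `species_bundle`, or a YAML config
pointing at a gene table, FASTA and alignment, writing one TSV per stage
plus exclusion bookkeeping (singletons discarded, over-represented block
identities removed, ambiguous skew profiles, single-block genomes) —
first-class output, because these filters shape every downstream number.
The package is a library with this function surface as its interface; no
shell entry point is shipped.

Validation problem sizes were chosen to make each check sharp at desk
scale: oracle equivalence on thousands of random permutations at C ≤ 12
(where brute force is exhaustive), calibration and recovery at C = 500
with 100 replicates per k and 200 trials per planted k, positional
neutrality with 10,000 uniform midpoints and 1,000 replicate samples of 50,
Ori/Ter recovery on 1 Mb sequences over 20 seeds, and enrichment recovery
on a 10-genome, 150-family species. `scripts/acceptance.R` reruns all of
these from scratch under a caller-supplied seed.

## Known limitations

* Genes wrapping the circular origin (end < start) are rejected; rotate
  the annotation upstream.
* Multi-chromosome and linear replicons are out of scope for the
  replichore analysis; linear permutation comparison is supported only
  insofar as both genomes are flagged non-circular.
* The quadratic calibration saturates: beyond roughly C/10 events the
  block count ceases to identify k, and predictions there are lower bounds
  reported with a warning.
* The ambiguity rule is a threshold stand-in for a visual judgment; its
  two parameters matter and are exposed.
* B_cs is undefined for identical genomes (S = 0); such pairs are reported
  as NA rather than silently dropped.
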