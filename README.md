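# synbreak

Intra-species genome rearrangement analysis for bacteria and archaea:
syntenic core-gene blocks, inversion/translocation classification,
replichore-relative positioning from GC skew, simulation-calibrated
rearrangement-rate estimation, and COG functional enrichment — with a
synthetic-species generator that plants ground truth for every stage.

## Who this is for

Microbial comparative genomicists asking how often, where, and why gene
order breaks within a species: given complete genomes of one species with
ortholog family assignments and a concatenated core-gene alignment, the
package quantifies rearrangement per strain and per pair, localizes events
relative to the replication origin, and tests which gene functions travel
with them.

## The method in brief

- **Blocks.** Each genome is reduced to its signed circular permutation of
  single-copy core families (present in ≥ 90% of genomes by default). For a
  reference–query pair, syntenic blocks are maximal runs of shared families
  consecutive in both genomes (same or fully reversed order), with circular
  adjacency; single-gene runs are discarded as likely orthology errors. One
  inversion cuts the circle into 2 blocks, one translocation into 3. The
  largest block is the backbone; the other n−1 blocks are the rearranged
  ones. Reversed-order blocks are inversions, the rest translocations. The
  species reference is the genome minimizing the average block count.
- **Replichores.** Ori and Ter are the global minimum and maximum of the
  cumulative GC skew S = (G−C)/(G+C) over 1 kb windows; ambiguous profiles
  (competing extrema) are excluded. Block midpoints map to d ∈ [0,1] along
  their Ori→Ter arc and are tested against the neutral mean 0.5 with a
  Wilcoxon signed-rank test.
- **Rates.** Simulated event histories calibrate a quadratic map from event
  count k to expected block count; inverting it converts an observed block
  count B into a predicted event count N (B = 1 → N = 0). The pair rate is
  **B_cs = N / (C · S · L)** — events per substitution, normalized by core
  genome size C (genes) and core alignment length L (nt), with S the
  pairwise substitution count on the alignment.
- **Enrichment.** Per COG, a 2×2 chi-square compares rearranged-block gene
  content (core + accessory genes inside block spans; backbone blocks and
  single-block genomes excluded) against all genes of all genomes, with
  Benjamini–Hochberg correction at 0.05.

All statistical primitives (signed-rank, rank-sum, Spearman, chi-square,
BH, quadratic least squares) are implemented in the package and verified
against enumeration oracles and base R in the test suite.

## Worked example

Generate a synthetic species with known ground truth and run the full
pipeline:

```r
library(synbreak)

bundle <- make_species(synth_params(n_genomes = 6, C = 60,
                                    genome_length_bp = 2e5,
                                    gene_length_bp = 500, seed = 42))
bundle
#> <species_bundle> 6 genomes, C = 60, planted events per genome: 0 0 0 3 0 1

res <- run_pipeline(bundle, seed = 2,
                    calibration = sim_params(60, k_grid = 0:10,
                                             replicates = 30, seed = 2))
res$reference_id
#> [1] "g01"
res$summary$per_genome
#>     genome_id n_blocks n_inversions n_translocations
#> g02       g02        1            0                0
#> g03       g03        1            0                0
#> g04       g04        8            0                7
#> g05       g05        1            0                0
#> g06       g06        3            0                2
res$rates[, c("query_id", "B", "N", "S", "B_cs")]
#>     query_id B        N   S         B_cs
#> g02      g02 1 0.000000 123 0.000000e+00
#> g03      g03 1 0.000000 112 0.000000e+00
#> g04      g04 8 3.949570 101 2.172481e-08
#> g05      g05 1 0.000000 107 0.000000e+00
#> g06      g06 3 1.071409 112 5.314529e-09
```

Reading the output: the three event-free genomes are single blocks with
N = 0; the genome with one planted translocation shows the canonical 3
blocks and N ≈ 1; the genome with three planted events is cut into 8
blocks, converted back to N ≈ 3.9 events; B_cs scales those events by the
pair's 101–123 substitutions over the 30 kb core alignment. The skew stage
recovers the planted replication origin within half a window
(`res$skew[["g01"]]$ori_bp` = 49500 vs 50000 planted), and
`res$positional` carries the replichore-distance test (here n = 9 block
midpoints — far too few for a meaningful positional verdict, which is why
the acceptance script tests positional calibration on 10,000 simulated
midpoints instead).

`run_pipeline(out_dir = "...")` additionally writes one TSV per stage
(blocks per genome, Ori/Ter table, distances, rates, enrichment,
exclusion bookkeeping).

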