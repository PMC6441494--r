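# circpipe

Characterization of circular RNAs (circRNAs) across sorted cell
populations: annotation of backsplice junctions against a gene model,
exon/intron feature decomposition, RPKM-based expression calling with a
data-derived threshold, fold-change trajectory classification, miRNA seed
scanning, ORF/codon-adaptation statistics with a Markov-null expected CAI,
conservation scoring against location-matched shuffled backgrounds, and
circular-versus-linear host-gene comparison.

## The problem

Backsplice junction callers (find_circ and kin) emit genomic spans with
read support but say nothing about what the circle contains, whether it is
expressed above noise, how it behaves across a lineage, or whether it could
sponge miRNAs, encode a peptide, or sit under purifying selection.
`circpipe` turns junction calls plus standard references (GTF annotation,
genome FASTA, read intervals, a phyloP-like per-base conservation track,
mature miRNA FASTA, a codon-usage table, linear-transcript RPKM tables)
into a fully annotated, quantified and functionally profiled circRNA
catalog. It is aimed at transcriptomics researchers analysing multi-stage
designs — the motivating case is three FACS-sorted cortical populations
(proliferative progenitors, differentiative progenitors, newborn neurons)
with three biological replicates each.

The statistical core, in the field's standard notation:

* **Expression**: `RPKM = count / (R * L)`, `R = library size x 1e-6`,
  `L = length x 1e-3`, averaged over replicates per population. The
  expression threshold is the highest RPKM among predicted-but-undetected
  introns of sequencing-validated circRNAs (published realization:
  `RPKM > 3.5`, the default).
* **Trajectories**: median-of-ratios normalization, then per-transition
  fold changes labelled `U` (`FC >= 1.5`), `D` (`FC <= 0.67`) or `F`,
  giving nine two-transition classes (no FDR; raw FC classes by design).
* **Seeds**: Bartel categories (8mer, 7mer-m8, 7mer-A1, 6mer) from
  Watson-Crick complementarity to miRNA positions 2-8, scanned circularly
  across the backsplice junction, gated by alignment score (>= 150) and
  nearest-neighbor duplex energy (dG <= -19 kcal/mol).
* **Coding potential**: ATG-only non-nested ORFs >= 150 nt;
  `CAI = (prod w_i)^(1/n)` with `w` the within-family relative
  adaptiveness; significance threshold `eCAI` = 95% quantile of CAI over
  500 Markov-model null sequences, averaged over repeated runs; real vs
  shuffled genomic/transcriptomic ORF sets compared by 2x2 chi-squared
  (1 df).
* **Conservation**: masked-aware mean of per-base scores over exon-only
  bodies and 200-bp flanks, against one same-length shuffle per region
  drawn from a class-matched reference (exonic / gene-body / intronic /
  whole genome); Welch t test.

Every stage is exercised end to end on a bundled synthetic-data generator
that plants ground truth (classes, expression, trajectories, seed sites,
ORFs, conservation elevations, correlated linear expression) and writes a
machine-readable truth manifest.

## Worked example

```r
library(circpipe)

bundle <- generate_dataset(synthetic_config(), seed = 1)
res <- run_pipeline(bundle, seed = 1)

res$manifest$funnel
#> putative expressed
#>      150       128

res$manifest$classes
#>    antisense genic_exonic  genic_other   intergenic
#>            1          145            2            2

res$diffexp$pattern
#> UU DU FU UD DD FD UF DF FF
#> 14  8  6 14  9  7  7 11 52
```

Of 150 junction calls, 128 pass the expression threshold (the funnel is
recorded in the run manifest so every filter is auditable). The class table
shows the planted 97% genic-exonic mix realized exactly. The trajectory
table counts the nine fold-change classes; `UD` and `DU` are the
transiently up-/down-regulated classes specific to the middle population.

```r
res$orfcai$ecai
#> [1] 0.5070482
res$orfcai$above_expected$circ
#> [1] 12 33
```

The eCAI threshold (0.507 here) is the 95% quantile of CAI over Markov-null
sequences; 12 of 45 circRNA ORFs exceed it — exactly the planted
codon-biased ORFs.

```r
sapply(res$conserve$tests, function(t)
  c(real = t$mean_real, shuffled = t$mean_shuffled, p = t$p_value))
#>               body         flank
#> real      4.998e-01     3.034e-01
#> shuffled  1.027e-01     3.648e-02
#> p         1.824e-57    3.572e-144

res$compare_linear$pearson_overall$r
#> [1] 0.8051815
```

Bodies and flanks are both far more conserved than their location-matched
shuffles (planted elevations 0.5 and 0.3 over a noisy background), and the
circular-linear log2-RPKM correlation recovers the planted r = 0.8.

With the default score/energy gates the seed-count table keeps only sites
with extended complementarity; planted bare seed matches are counted with
the gates disabled:

```r
filter_and_count(res$seeds$matches, min_score = -Inf, max_dg = Inf)$counts[1:3, ]
#>       circ_id  mirna_id n_sites
#> 1 circ_000018 syn-miR-2       3
#> 2 circ_000045 syn-miR-2       3
#> 3 circ_000111 syn-miR-5       3
```

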