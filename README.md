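# satkit

Satellite DNA (satDNA) — long tandem arrays of a repeated monomer — can make
up several percent of an insect genome yet is nearly invisible to standard
assembly-based annotation: arrays collapse in assemblies, and their true
abundance must be estimated from unassembled reads. `satkit` characterizes a
genome's **satellitome** (its full complement of satDNA families) from
low-coverage paired-end reads, the way read-clustering pipelines
(RepeatExplorer/TAREAN) plus RepeatMasker-style masking are used in
satellitome papers, but as a single tested, scriptable R package with a
synthetic-data module that knows the ground truth.

It is written for genome/repeat biologists who want a reproducible desk-scale
satellitome analysis, and for methodologists who want every stage validated
by parameter recovery on simulated data.

## What it computes

* **Discovery** — reads are sampled at low coverage, connected by shared
  canonical k-mers, and clustered (weighted Louvain communities by default);
  tandem clusters are called from a polished cluster representative by
  self-shift periodicity: a sequence with monomer length *P* matches itself
  shifted by *P*, so the smallest shift *s* with match fraction
  *f(s) ≥ 0.7* is the repeat period.
* **Consensus** — representatives are cut into monomers, rotation-normalized
  (tandem monomers are circular), and combined by column majority; cluster
  consensuses are grouped into families/subfamilies by rotation-aware local
  alignment (≥ 80% identity over ≥ 50% of the shorter), then named
  `<prefix>Sat<rank>-<length>` by decreasing genome proportion.
* **Quantification** — a read sample is aligned (seeded, gapped, both
  strands) against ~200-bp tandem references built from each consensus;
  per-hit transition (*P*) and transversion (*Q*) proportions give the
  Kimura 2-parameter distance

  *K* = −½ ln((1 − 2*P* − *Q*)·√(1 − 2*Q*)),

  genome proportion = masked bp / sampled bp, and masked bp binned by *K*
  yields the repeat landscape.
* **Relations** — all-vs-all consensus similarity screening against a
  shuffled-sequence null (expectation ≤ 0.001), and ε = 0 minimum spanning
  networks (the union of all minimum spanning trees) of subfamily
  consensuses weighted by abundance.
* **Assembly scan** — blastn hits of each consensus in an assembly accepted
  under the 90/90 rule (≥ 90% single-HSP query coverage, ≥ 90% identity),
  per-scaffold monomer counts, and Jaccard co-occurrence of subfamilies
  across scaffolds.
* **Transcription** — RNA-seq reads counted per family (best alignment),
  CPM-normalized, filtered (> 50 CPM in ≥ 2 samples), classified into four
  tissue patterns (ubiquitous, antenna-biased, gonad-biased, single-gonad)
  and correlated with genomic abundance (Spearman).
* **Simulation** — genomes with planted satellite arrays (per-copy
  divergence with transition bias, subfamilies in separate arrays), PE150
  reads, assembly pseudo-reads and RNA-seq libraries, all with
  machine-readable truth tables for parameter-recovery testing.

## Worked example

```r
library(satkit)

# simulate a 1-Mb genome with three satellite families and 1X PE150 reads
specs <- dplyr::bind_rows(
  sat_family_spec("fam1", make_consensus(165, 0.70, seed = 11), 0.030, 0.05),
  sat_family_spec("fam2", make_consensus(80,  0.60, seed = 12), 0.010, 0.15),
  sat_family_spec("fam3", make_consensus(60,  0.65, seed = 13), 0.004, 0.02))
sim   <- build_genome(specs, genome_length = 1e6, seed = 3)
reads <- sim_reads(sim, coverage = 1, error_rate = 0.001, seed = 4)

# discover, build consensuses, quantify, name
res <- characterize_satellitome(
  reads, satkit_config(seed = 9, cluster_sample = 2600,
                       quant_sample = nrow(reads)))
dplyr::select(res$families, name:divergence_pct)
#> # A tibble: 3 × 6
#>   name          n_clusters proportion_pct length_bp at_pct divergence_pct
#>   <chr>              <int>          <dbl>     <int>  <dbl>          <dbl>
#> 1 RproSat01-165          1          3.02        165   80.6           5.43
#> 2 RproSat02-80           1          1.01         80   61.3          15.9
#> 3 RproSat03-60           1          0.398        60   70             1.97
```

The three planted families (3.0%, 1.0%, 0.40% of the genome at 5%, 15% and
2% per-copy divergence) are recovered with their exact monomer lengths;
`res$landscape` holds the divergence landscape (`plot_landscape(res$landscape)`),
and `tidy()` / `glance()` methods summarize every result object.

Published satellitome tables load and summarize directly:

```r
summarize_table(load_family_table("fixture"))
#> # A tibble: 4 × 5
#>   statistic length_bp at_pct divergence_pct proportion_pct
#> 1 Mean           235.   65.7           10.6          NA
#> 2 SD             223.    9.1            6.91         NA
#> 3 Median         165    65.5           10.0          NA
#> 4 Total           NA    NA             NA             8.05
```

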