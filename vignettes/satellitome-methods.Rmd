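---
title: "Satellitome characterization from low-coverage reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome characterization from low-coverage reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Satellite DNA families live in long tandem arrays that assemblies collapse,
so their abundance and age structure are estimated from unassembled,
low-coverage reads. This vignette is the package's own account of how each
stage works, which assumptions it makes, which parameters matter, and what
the synthetic-data validation does and does not demonstrate.

## The read-clustering model of discovery

At sampled coverages well below 1X, two reads drawn from the same satellite
family share sequence because monomer copies resemble the family consensus,
not because the reads overlap in the genome. Discovery therefore builds a
graph whose nodes are sampled reads and whose edges join reads sharing at
least `min_shared = 3` canonical k-mers (a k-mer and its reverse complement
count once, making the graph strand-insensitive).

Two failure modes bound the k-mer size `k`:

* **Too large:** for copies at per-site divergence *d* from the consensus,
  two reads agree at a site with probability ≈ (1−d)² + d²/3, so a shared
  21-mer between copies at *d* = 0.20 survives with probability ≈ 0.65²¹ ≈
  10⁻⁴ — such families simply never connect.
* **Too small:** chance collisions between background reads arrive in runs
  (a shared 15-bp stretch yields three shared 13-mers at once), so
  `min_shared` cannot compensate; at a background A+T of 0.65 the per-pair
  collision probability at `k = 11` is large enough to percolate a
  several-thousand-read sample into one giant component.

The default `k = 13` sits between the two regimes: 20%-diverged families
still connect (expected shared k-mers per read pair ≈ 1 with heavy tails,
enough for a connected cluster at tens of members) while background
collisions stay subcritical at the sampled densities the pipeline uses.
`k` is capped at 25 because k-mers are encoded as base-4 integers held
exactly in doubles.

**Communities, not components.** Junction reads (half satellite, half
flanking sequence) and chance collisions create thin bridges between
otherwise unrelated clusters; at sampling densities above roughly 0.2X these
bridges percolate connected components into chimeric giants. The default
clustering is therefore weighted Louvain community detection (edge weight =
shared k-mer count): within-family edges carry tens of shared k-mers while
bridges carry close to `min_shared`, so modularity optimization cuts them.
Plain connected components remain available (`method = "components"`) and
behave identically at very low sampling density. Clusters are ranked CL1,
CL2, … by member bp, and clusters below 0.001% of the sampled bp are
discarded with their bp accounted in an attribute, so bp is conserved.

## Representatives, tandem calling and its geometry

A cluster's representative starts from the mate-joined insert of a
high-degree member (mate 1 plus the reverse complement of mate 2 is a
contiguous genomic window of about the insert size). Up to five high-degree
members are tried as seeds, because in a community that mixes a small tandem
family with background chains the single top-degree read can be background.
Members are strand-oriented against the seed, locally aligned, and a
majority base is taken per representative column; the representative is then
extended by overhanging member tails, but only tails that align to at least
one other member at ≥ 50% of their length in score are accepted — junction
reads otherwise graft flanking sequence onto the representative.

Tandemness is called by **self-shift identity**: for shifts `s` in
`[min_period, L/2]`, `f(s)` is the fraction of positions where the sequence
matches itself shifted by `s`; the sequence is tandem when `max f(s) ≥ 0.7`
and the period is the smallest local maximum reaching the threshold (so
multiples of the true period are not reported). Two consequences of this
definition are worth knowing:

* Periods below `min_period = 4` surface as multiples (a 3-bp motif reports
  6); lowering `min_period` resolves them.
* Confirming a period *P* needs `L ≥ 2P`. With 150-bp reads and 300-bp
  inserts, representatives can reach about insert + *P* (a fully-contained
  placement can hang off the end by at most *P* − (*L* − unit length)), so
  monomers up to ≈ 225 bp are detectable at this read geometry; longer
  monomers need longer inserts or deeper coverage. The 0.7 threshold is
  far above the ≈ 0.25–0.33 self-match fraction of random sequence and
  below the ≈ (1−d)² + d²/3 copy-to-copy identity of families up to
  d ≈ 0.15; more diverged families pass after majority polishing.

## Consensus building on a circle

Monomers cut from a tandem representative are circular permutations of one
another, so every comparison is rotation-normalized first: `rotate_align`
scans all rotations for the minimum Levenshtein distance (ties to the
smallest offset). The consensus is a column majority over `{A, C, G, T, -}`
against the longest monomer as anchor; gap-majority columns are removed and
base ties break alphabetically, a deliberate choice that keeps consensuses
concrete DNA (no IUPAC ambiguity codes) at the cost of a deterministic bias
toward A in exactly-tied columns.

A consensus built from the handful of monomers in a small cluster carries a
few percent residual error, and a consensus error of *e*% inflates the
family's divergence estimate by about *e* percentage points. The pipeline
therefore majority-polishes every consensus against a read subsample mapped
to the draft references before final quantification (`polish_consensus`):
reads align to a tandem reference of the consensus, and reference columns
fold back onto consensus positions modulo the monomer length, so read phase
is irrelevant. This step is substitution-only; indel polishing is left to
the monomer-based `refine_consensus`, which also discards monomer windows
more than 35% distant from the current consensus so that unrelated reads in
a mixed cluster cannot poison the majority.

Cluster consensuses join one family when a rotation-aware local alignment
covers ≥ 50% of the shorter at ≥ 80% identity (single linkage). The
threshold pair is configurable; 80/50 keeps the subfamily structure of
highly variable families inside one family while unrelated families (which
share no detectable similarity) stay apart. Families are named
`<prefix>Sat<rank>-<length>` with rank by decreasing genome proportion, ties
by decreasing length then lexicographic consensus.

## Quantification: masking and the Kimura-2P distance

References are tandem concatenations of each consensus,
`max(2, ceiling(200/L))` copies, so every reference holds at least two
monomers and about 200 bp — a read from anywhere in an array aligns without
end effects. Declared short motifs (telomeric TTAGG, GATA microsatellites)
receive references by the same rule; graph discovery cannot see such
low-complexity repeats and they are inputs, not discoveries.

Reads are aligned (11-mer seeded, +1/−1 with affine gaps 5/2, both strands)
and hits below `min_score = 30` — roughly 30 matched bp — are dropped.
Overlaps on a read are resolved greedily by score with trimming, so each
read base is masked at most once. Per hit, transitions *P* and transversions
*Q* are counted over gap-free aligned columns (indels do not enter
divergence), and

$$K = -\tfrac12 \ln\left((1 - 2P - Q)\sqrt{1 - 2Q}\right),$$

undefined (flagged, excluded from divergence means but kept in abundance)
when `1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0`. Genome proportion is masked bp over
sampled bp; the landscape bins masked bp by `floor(100K)` into 1-point bins
capped at 49. Family divergence is the matched-column-weighted mean of
per-hit *K*. Two scale subtleties are deliberate:

* *K* is computed from each hit's pooled *P*, *Q*, not per-column.
* The simulator's truth tables record realized divergence **on the Kimura
  scale**, computed from the generator's actual transition/transversion
  counts. The mutation model is single-hit Bernoulli (each site substituted
  at most once), and above ≈ 15% divergence the multiple-hit correction in
  *K* exceeds the raw substituted-site fraction by more than 2 percentage
  points — comparisons of estimate to truth are only meaningful on the
  estimator's own scale. The raw substituted fraction is kept alongside as
  `p_distance`.

Summary statistics over a family table use the sample standard deviation
(n−1) and include declared short-motif rows.

## Similarity screening and minimum spanning networks

Family-to-family similarity is screened by local alignment of the doubled
shorter sequence (junction-spanning similarity between circular monomers is
visible only on the doubled sequence) on both strands. Significance comes
from an empirical null: 200 column-shuffled versions of the shorter
sequence are aligned to the longer, a Gumbel distribution is fitted to the
null scores by moments (local alignment maxima are extreme values), and the
observed score's upper-tail probability is compared with 0.001. The Gumbel
fit extrapolates below the 1/200 resolution of the raw null; this mirrors a
BLAST expectation threshold without re-implementing its analytic theory.

Subfamily networks use rotation-minimized edit distances and the ε = 0
minimum spanning network: distances are visited in ascending order and
every edge whose endpoints are not yet connected by strictly smaller
distances is added — by construction the union of all minimum spanning
trees, so tied distances retain alternative paths (reticulation). The
implementation is verified against exhaustive enumeration of labeled trees
for n ≤ 6.

## Assembly scan and co-occurrence

Monomer consensuses are searched in an assembly with NCBI blastn (the
standard tool for all-HSP scans of short queries against scaffolds), and
hits are accepted under the 90/90 rule: ≥ 90% single-HSP query coverage and
≥ 90% identity. Co-occurrence of two subfamilies is the Jaccard fraction
|S∩S'|/|S∪S'| of scaffolds holding accepted hits of each — symmetric, which
is why it was chosen over the asymmetric |S∩S'|/|S| (still available by
flag). Note the sharp edge this rule creates: subfamilies ≈ 90% identical
to each other cross-match sporadically, so co-occurrence between
near-identical variants is an artefact-prone measurement — the package
leaves any merging of > 97%-identical subfamilies to the user.

## Transcription patterns

RNA-seq reads are counted against the same tandem references as genomic
quantification; each read increments exactly one family (best score, ties
to the lexicographically first name) and unmapped reads fill a background
bucket standing in for the rest of the transcriptome. CPM uses total counted
reads (families + background) as denominator, so CPM columns sum to one
million; no between-sample normalization (such as TMM) is applied. Note the
study-design caveat this inherits: if some libraries are poly-A enriched and
others are not, cross-library comparisons of non-coding satellite
transcription are only qualitative.

A family is expressed when CPM exceeds 50 (strictly) in at least two
samples. The four qualitative tissue patterns are quantified by a dominance
threshold on tissue-group means (antenna *a* = mean of the antenna samples;
ovary *o* and testis *t* single samples; *T* = *a*+*o*+*t*): antenna-biased
when *a*/*T* ≥ 0.7; single-gonad when *o*/*T* or *t*/*T* ≥ 0.7;
gonad-biased when (*o*+*t*)/*T* ≥ 0.7 with neither gonad alone dominant;
ubiquitous otherwise. The 0.7 threshold is the package's quantification of
the published qualitative patterns and is configurable; classification is
scale-invariant by construction. Transcription–abundance correlation is
Spearman's rank correlation with average ranks for ties, exact permutation
p for n ≤ 9 without ties, t-approximation otherwise; the per-family
transcription summary is the mean CPM over all samples — a documented
assumption, since sums and means differ only by a constant when every
family is observed in every sample.

## The simulator: what it emulates, and what it does not

`build_genome` plants, for each family, tandem arrays of independently
mutated monomer copies (substitutions with a transitions:transversions bias
of κ:1, κ = 2 by default; optional single-base indels, insertion/deletion
equiprobable) at random non-overlapping loci in i.i.d. background at A+T
0.65. Subfamily variants always occupy their own arrays, emulating the
array-level homogenization that makes subfamilies real. Truth tables (BED
intervals, per-family realized proportions and divergences) are exact by
construction, and interval lengths sum to the realized satellite fraction.

`sim_reads` places inserts by jittered stratified sampling by default:
positions are marginally uniform but locally even, so the coverage of a
2.5-kb array at 1X is near its expectation instead of Poisson. This is a
variance-reduction choice made at design time so that recovery tests of
0.05%-proportion families measure the method, not binomial sampling noise;
i.i.d. placement is available (`mode = "uniform"`) and is what
`assembly_pseudo_reads` uses. Base qualities are constant; no instrument
error profile, PCR duplicates, heterozygosity or transposable elements are
simulated. Consequently, passing recovery tests demonstrates correctness of
the clustering/consensus/masking machinery under the stated statistical
model — not robustness to real-library artefacts, diverged TE families that
cluster alongside satellites, or nested/higher-order repeat structure.

## The standing recovery study

`run_recovery_study` is the package's validation experiment: a 5-Mb genome
with eight families at proportions 3–0.05% (geometrically spaced, so that
±20% estimation noise cannot permute the rank order), Kimura divergences
2–20%, monomer lengths 50–165 bp (within the detectable range of the read
geometry; more diverged families get shorter monomers, matching the
tendency of old families to be short-monomer ones), 1X PE150 reads at 0.1%
error, and a 12,000-read clustering sample (≈ 0.36X). Estimates are matched
to planted families by rotation- and strand-aware consensus distance
(≤ 0.25 normalized). Under these conditions all eight families are
recovered with abundances within a few percent relative, divergences within
one percentage point, and the exact planted rank order; the acceptance
script reports the measured errors for any seed.

## Numerical choices and degenerate inputs

* Alignment scoring is +1/−1 with affine gaps (open 5, extend 2)
  throughout, so scores read as matched-bp equivalents.
* Ties: consensus columns break alphabetically; equal-score overlap hits
  keep the earlier interval then the lexicographically first family;
  equal-score RNA assignments go to the lexicographically first family;
  rotation ties to the smallest offset. All documented, all deterministic.
* Reverse-complement invariance of masking statistics holds to within
  alignment-endpoint tie-breaking (a base or two per hit), not bitwise;
  rotation invariance of consensus building is exact.
* Every generator and every pipeline stage is a pure function of its
  arguments and a seed; child streams are derived per stage so stage order
  cannot leak randomness across stages. Reruns are byte-identical.
* Degenerate inputs error early and name the problem: empty reference sets,
  empty assemblies or samples, constant vectors in the correlation,
  malformed family tables (with the offending line), cluster sampling
  beyond the available reads (with the shortfall), and stage inputs missing
  because an upstream stage was toggled off (with the artifact path).

## Known limitations

* Monomers longer than ≈ 1.5× the insert size are not confirmable as tandem
  at the default read geometry.
* Abundance is mildly underestimated (a few percent relative) for highly
  diverged families because local alignments shed low-identity hit ends.
* The family-joining threshold (80/50) cannot distinguish genuinely related
  families that share only a short segment — such pairs surface in the
  similarity screen instead.
* The shuffle-null similarity test assumes composition is the only nuisance
  structure; repetitive low-complexity consensuses can still inflate
  significance.
* Louvain clustering is resolution-limited: a very small family embedded in
  a large mixed community is found only through the multi-seed tandem
  check, which requires at least one of the five highest-degree members to
  be a family read.
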