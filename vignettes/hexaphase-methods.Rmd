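---
title: "Resolving a three-subgenome genome from joint k-mer spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a three-subgenome genome from joint k-mer spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Some animal genomes are hidden polyploids: a recent whole-genome
duplication followed by chromosome fusion leaves a karyotype that looks
diploid while the sequence content is three-fold redundant. The system this
package models has one small-chromosome subgenome **S**, present as a
homozygous diploid pair, and two diverged haplovariants **L1** and **L2**
of a single large fused chromosome. A haploid assembly of such a genome
interleaves all three complements, and standard read mapping smears
evidence across homologous loci.

The package implements an analysis strategy that resolves this organization
from three independent directions:

1. **Assembly self-homology** — slice the assembly into *paralogous
   blocks* (PBs) using chained pairwise self-alignments, so copy number
   is defined per fragment, then validate it with read coverage.
2. **Reference-free k-mer spectra** — count canonical 35-mers in two
   sequencing libraries from sublines that differ in the copy number of
   the fused chromosome (disomic, configuration S S L1 L2, versus
   tetrasomic, S S L1 L1 L2 L2), and model the joint 2D frequency
   spectrum with a shared-parameter tetraploid/hexaploid mixture.
3. **Window classification + microdissection evidence** — assign 5-kb
   windows and scaffolds to S or L from coverage log-ratios and
   subgenome-specific k-mers, and corroborate the L class with the
   coverage breadth of a whole-genome-amplified (WGA) library derived
   from the microdissected large chromosome.

Everything runs end to end on synthetic data whose generator is a
first-class, tested module.

# The synthetic generator

`simulate_subgenomes()` draws an ancestral sequence s uniformly over
A/C/G/T and derives L1 and L2 under a star phylogeny: a *shared* branch
(s to the L ancestor) and two *private* branches. With target pairwise
SNP divergences $d_{SL}$ (s vs either L) and $d_{12}$ (L1 vs L2), the
branch rates are

$$a = d_{SL} - d_{12}/2, \qquad b = d_{12}/2,$$

so both targets are met simultaneously in expectation; the configuration
is infeasible when $d_{12} > 2\,d_{SL}$, and `sim_params()` refuses it.
Indel events (geometric lengths, mean $1/p$ with $p = 0.4$ by default)
are placed with a minimum mutual separation so that the truth alignments
— gapless blocks split exactly at injected indels — are unambiguous.
Every event is recorded; truth chains serialize losslessly to PSL.

Defaults are the study conditions: 500-kb ancestral sequence, three small
S chromosomes, $d_{SL} = 1.6\%$, $d_{12} = 1.4\%$, indel rate $10^{-4}$
events/site/pair, 100-bp paired reads with 350 ± 50 bp inserts and 0.1%
substitution error. The insert-size and error values are conventional
short-read figures; nothing downstream is sensitive to the insert
geometry.

**Sequencing depth.** The per-copy depth default is 50-fold (both mates).
Since k-mer counting uses first mates only and a 100-bp read carries 66
distinct 35-mer windows, this puts the per-copy depth of the *counted*
data at $\lambda \approx 16.5$. This value is deliberate: the multiplicity
clouds of the joint spectrum sit at integer multiples of $\lambda$ with
near-Poisson widths, so adjacent peaks at multiplicity $m$ and $m+1$ are
separated by $\lambda/\sqrt{(m+1)\lambda} = \sqrt{\lambda}/\sqrt{m+1}$
standard deviations. Resolving the lattice up to the 4- and 6-copy
homozygous peak needs $\lambda \gtrsim 16$; at $\lambda \approx 4$ the
high-multiplicity clouds provably merge and only the lowest peaks are
detectable. The default therefore reproduces the per-copy depths implied
by the original study's frequency rectangles (about 16.5 and 10 per copy).

A consequence worth stating: at this depth, sequencing-error k-mers that
recur (the same error at the same position in two reads) pass the
min-count-2 filter often enough to make up roughly 3% of the union of the
two libraries' key sets. The shared fraction of distinct filtered 35-mers
is therefore ~97%, not >99%; the two figures — full five-peak resolution
and a >99% distinct-k-mer sharing — are not simultaneously achievable at a
0.1% error rate. We keep the depth (the five-peak structure is the
scientific core) and report the shared fraction as computed.

**What the generator does not emulate:** platform-specific error profiles
and quality scores, GC-amplification bias, repeat families (a seeding knob
exists but no repeat analysis is performed), and meiotic recombination.
Passing tests therefore demonstrate correctness of the algorithms under
the stated statistical structure, not robustness to every artifact of real
libraries.

**Known-origin placement.** Synthetic "mapping" is done by
`place_fragments()`: each fragment goes to the reference locus of its true
origin, and fragments whose span contains no variant distinguishing two or
three haplovariants are distributed among the corresponding homologous
loci — uniformly sampled by default (mass-conserving), or enumerated for
multi-mapping analyses. This reproduces the essential statistics of a real
multi-mapper (the 1/3 placement probability of fully shared reads, the
compressed S : L coverage contrast) without reimplementing an aligner.
Fragments spanning scaffold-piece boundaries are dropped, as a real
mapper's pairs would be near contig edges. For real data, externally
produced alignment and count tables are accepted at the same interfaces.

# Paralogous blocks

`slice_into_blocks()` iterates endpoint projection to a fixed point:
every alignment-span endpoint is projected through every overlapping
chain (cut positions inside alignment gaps snap deterministically to the
next block edge) until no new cut appears. After cutting, any two
alignment spans on a scaffold coincide or are disjoint, each chain
decomposes into (target segment, query segment) pairs, and homologous
segments are grouped by transitive closure of full-length alignment
(union-find). Unaligned sequence becomes 1-copy blocks; the member
intervals of all blocks partition the genome exactly. A strict-clique
grouping mode exists for users who do not want closure to bridge aligner
dropout. Fragments shorter than `min_segment` (default 100 bp) are
absorbed into their left neighbour (first fragment: right neighbour) — a
deterministic tie-break that keeps rank statistics meaningful.

Interval semantics deliberately cannot represent tandem-style
self-alignments of a region onto itself at a small shift (per-position
copy number would then vary inside a segment); such chains are the
province of repeat annotation, which is out of scope.

Divergence statistics per block average over member pairs:

* `snp_rate` — mismatches per aligned column;
* `indel_event_rate` — gap openings per kb of aligned columns;
* `edit_rate` — (mismatches + indel events) / longest member length,
  counting an indel of any length as one edit;
* `length_weighted_divergence` — (mismatches + indel bases) / gapped
  alignment span.

The three scales are reported because they answer different questions
(point divergence, event divergence, sequence-content divergence); the
denominators above reproduce their expected ordering. Note that "an indel
of any length is one edit" does not define a useful global optimum — for
any two long sequences, deleting one and inserting the other costs 2 — so
the quantity is defined via the chained alignment, and the dynamic-
programming cross-check in the tests runs only on short windows where the
genuine count (at most 2 edits) is provably optimal.

Coverage validation (`block_coverage()`): block FPK is the sum of member
fragment counts per kilobase; the haploid FPK is, unless supplied, the
length-weighted mode of the per-block FPK/copy-number distribution — the
consistent majority of the assembly defines the per-copy depth, so the
estimate survives a minority of collapsed or expanded blocks. A block's
coverage multiplicity is FPK over haploid FPK rounded; disagreement with
the member count flags suspected collapse (multiplicity above copy
number) or expansion.

# The joint spectrum model

Canonical 35-mers (lexicographic minimum of a k-mer and its reverse
complement) are counted from first mates only, which avoids double
counting overlapping pairs. K-mers seen at least twice in both libraries
enter the joint table; the 2D histogram of (disomic frequency, tetrasomic
frequency) is the object of study. Its peaks are local maxima of a
Gaussian-smoothed histogram (separable kernel, sd 1.5 bins) passing an
8-neighbour test with height at least 5% of the global maximum. "Major
peak" is a visual judgement in the original analysis; the bandwidth and
prominence floor are its documented, tunable operationalization. Peak
multiplicities are modes divided by the smallest detected mode on the
disomic axis; for a subset $U$ of haplovariants present in configurations
A and B, the expected pair is (copies of $U$ in A, copies of $U$ in B) —
`expected_peak_multiplicities()` enumerates them, giving
(1,2), (2,2), (2,4), (3,4), (4,6) for the two-subline design.

Each marginal spectrum is a negative-binomial mixture with components at
means $j \cdot \mathrm{kmercov}$, $j = 1..p$, and size
$j \cdot \mathrm{kmercov} / \mathrm{bias}$ (Poisson as bias tends to 0).
Heterozygosity enters through per-site rates $r_t$ of allele-class
topologies — partitions of the $p$ homologous copies, e.g. for $p = 6$:
aaaaab, aaaabb, aaabbb, aaaabc, aaabbc, aabbcc, aaabcd, aabbcd, bound to
$r_1..r_8$ in that order (the two topologies with five or more distinct
alleles are omitted: at most four allelic states can coexist here). At
k-mer scale $\rho_t = 1 - (1 - r_t)^k$ under the standard
at-most-one-heterozygous-site approximation; a topology with class sizes
$(c_1..c_m)$ contributes weight $\rho_t$ to each component $c_j$, and the
homozygous remainder sits at component $p$.

The two spectra share one parameter vector. The tetraploid
(disomic-line) rates are fixed combinations of the hexaploid ones,

$$(r_1 + \varepsilon_1 r_2 + \varepsilon_2 r_3,\;
   (1-\varepsilon_1) r_2 + (1-\varepsilon_2) r_3,\;
   r_4 + r_5 + r_6,\; r_7 + r_8),$$

where the proportions $\varepsilon_1, \varepsilon_2$ say which fraction
of the one-subgenome-differs (and 3+3) classes collapses to a single-copy
difference in the disomic configuration. (These proportions are the
"partial correspondence" parameters; the package treats the two published
symbol pairs as the same quantities.) The disomic library's per-copy
depth and overdispersion are `kmercov * N` and `bias * N`; `N` absorbs
the sequencing-depth and genome-size difference and is initialized from
the ratio of total k-mer counts times 3/2 (4 versus 6 genome copies).

`joint_fit()` minimizes stacked least squares on frequency-weighted
counts ($x \cdot y$), which tempers the error-dominated low-frequency
tail; the exact transform behind the published two-column response is not
stated, and this weighting is our documented interpretation. Fitting uses
bounded Levenberg-Marquardt with a multi-start over per-copy-depth
candidates derived from the lowest tetrasomic-axis mode — both under the
"lowest mode = 2 copies" hypothesis and the "single homozygous peak = 6
copies" hypothesis, so a divergence-free genome does not trap the
optimizer in a depth-divisor local optimum. Duplication parameters d and
d1 exist, default to 0, and are fitted only on request.

Under the structural constraint of the design (S pair identical, each L
pair identical in the tetrasomic line), the only admissible heterozygous
topologies are aaaabb ($r_2$) and aabbcc ($r_6$), and

$$d_{12} = \varepsilon_1 r_2 + \varepsilon_2 r_3 + r_6, \qquad
  d_{SL} = (1 - \varepsilon_1/2)\, r_2 + (1 - \varepsilon_2/2)\, r_3 + r_6,$$

with the remaining rates reported as within-copy/unconstrained signal and
their sum as the total SNP variation. On read-derived spectra the
recovered divergences run some 10–25% below the generator's inputs: at
2–3% total divergence about a fifth of all 35-mers span two or more
variant sites, which the one-site-per-k-mer approximation redistributes
into higher topologies. This downward bias is a property of the k-mer
method itself (the original study's k-mer estimates sit similarly below
its alignment-based SNP rates) and is left visible rather than corrected.

# Window and scaffold classification

Windows are non-overlapping 5-kb bins; scaffold tails shorter than half a
window are excluded from rank statistics. Two metrics are computed:

* **log2(RRC)** — the log-ratio of normalized disomic to tetrasomic
  fragment counts. Counts are normalized by median-of-ratios size factors
  computed over the windows of the upper (S) coverage mode, and the
  log-ratio is centred at the midpoint between its two kernel-density
  mode summits, so the sign separates the classes. A unimodal
  distribution triggers a warning and median centring.
* **log2(RKC)** — the log-ratio of S-specific to L-specific k-mer
  matches, each normalized by its subset's total. Subgenome-specific
  subsets come from frequency rectangles placed around fitted peak
  positions: S around the (2,2) peak, L around (2,4) and (1,2), each mode
  ± 30% with inward rounding so rectangles of different labels stay
  disjoint. Rectangles are derived from the data rather than hard-coded
  because literal frequency ranges only apply at one sequencing depth.
  Matching against the reference is exact (canonical k-mer identity).
  Windows with one zero count get signed infinity and participate through
  their sign; windows with both counts zero stay unclassified.

The decision rule is a conjunction: S-class windows must be in the top
1/3 of windows ranked by S-specific k-mer count, have log2(RKC) >= 1 and
positive log2(RRC); L-class windows in the top 2/3 by L-specific count,
log2(RKC) <= -1 and negative log2(RRC). Raising the |RKC| threshold can
only shrink both classes (tested as a monotonicity property).

Scaffolds: with at least `min_chimera` (default 2) classified windows of
each class a scaffold is chimeric; otherwise it takes a class when that
class holds at least `min_frac` (default 0.9) of its classified windows;
otherwise it is unclassified. No scaffold-level rule is published; this
conservative operationalization is configurable. Divergence comparison
over PB triplets keeps 3-copy blocks whose members lie in nonchimeric
classified scaffolds with exactly one S and two L members, and reports
mean SNP and length-weighted rates for S–L versus L–L pairs with seeded
bootstrap intervals (1,000 resamples). In synthetic mode the L members
carry truth labels (L1/L2); on real data the pair stays "L-L".

# WGA scoring

Scaffold-specific mappability: position $i$ is 1 when the 100-mer
starting there occurs only within its own scaffold (any number of times,
both strands). Exact matching (E = 0) is the default; E > 0 uses
pigeonhole seeds with Hamming verification, is flagged approximate, and
is intended for desk-scale genomes only — the published setting (E = 2 at
K = 100 genome-wide) requires a dedicated external tool. Alignments of
the WGA library are filtered by the uniqueness rule: after dropping
placements with more than one edit, a read is retained when it has 1–10
placements, all on one scaffold. The window score is
$\sqrt{\text{covered mappable bases} / \text{mappable bases}}$ — breadth,
not depth, because isothermal amplification makes depth meaningless — and
the square root spreads near-zero values. Concordance reporting gives
per-class means, the fraction of positive-score windows per class and a
rank-based effect size; no hypothesis tests are involved anywhere in the
scheme, so no multiple-testing machinery exists.

# Numerical and engineering choices

* Coordinates are 1-based closed intervals throughout the R code
  (Bioconductor convention); PSL and BED files use their native 0-based
  half-open convention at the file boundary.
* K-mers are 2-bit packed (k <= 63) into 128-bit integers with
  sorted-array counting and merge joins in C++; tables cross into R as
  42-bit words in doubles. The count table, not the structure, is the
  contract.
* All randomness flows from a single integer seed; every generator is a
  pure function of (parameters, seed), and C++ code draws from R's RNG.
* Degenerate inputs: zero divergence yields identical haplotypes, a
  perfect reference and gapless truth chains; zero depth yields empty
  (not invalid) read sets; empty alignment sets yield all-unique blocks.
* Problem sizes: unit tests run on 10–250 kb genomes; the acceptance
  analyses use the full 500-kb study conditions. The pipeline's tiny
  smoke configuration is 60 kb with 1.5-kb windows (the median-of-ratios
  step needs at least 100 windows with counts in both libraries).

# Limitations

Real-data mode consumes externally produced alignments and counts; the
package does not run aligners or disk-based k-mer counters, and full-size
(hundreds of Mb, 100x) datasets are outside its in-memory design. L1
versus L2 cannot be distinguished at scaffold level on real data — only
the truth tables of the simulator make that split observable. The k-mer
divergence estimates inherit the one-site-per-k-mer bias discussed above,
and the chained-alignment edit metric is alignment-defined, not a global
optimum.
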