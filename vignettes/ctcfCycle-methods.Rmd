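---
title: "Methods: models, null distributions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, null distributions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why. It
states no empirical result that the test suite or the acceptance script does
not itself compute.

## The problem

Some chromatin proteins stay bound through mitosis ("mitotic bookmarking"),
and which binding sites they retain is informative about how chromatin
organization is re-established after division. Starting from two ChIP-seq
peak lists for one factor — one from interphase cells, one from mitotic
cells — the package partitions sites into interphase–mitosis-common (IM),
interphase-only (IO) and mitosis-only (MO) classes and asks how the classes
differ in genomic position, conservation, sequence content, binding
intensity and spatial arrangement relative to each other and to chromatin
domain boundaries.

## Coordinates, anchors and classification

All user-facing coordinates are 0-based half-open (BED convention); GFF
input is converted on read. The *anchor* of a site is its summit when one
is recorded, otherwise the interval midpoint `floor((start + end) / 2)`.
Distances, categories, GC windows and meta-profiles all act on anchors.
The original analysis never states whether distances were summit-to-summit
or midpoint-to-midpoint; both are available (`use_summit` in
`anchor_positions()`), summit-when-available is the default because
intensity profiles are summit-centered.

Classification calls an interphase peak IM when it overlaps any mitosis
peak by at least `min_overlap` bp. The source analysis states no overlap
criterion, so the default is the weakest one (1 bp); it is a parameter
everywhere. Two decisions the source leaves open:

* **IM coordinates** come from the interphase record, so IM ∪ IO tiles the
  interphase set exactly and `|IM| + |IO|` equals the interphase count — a
  partition invariant the tests enforce.
* **Many-to-one overlaps** are allowed: two interphase peaks overlapping one
  mitosis peak both become IM.

## Genomic categories

Each anchor gets exactly one category by precedence
`TSS_region > Promoter > Downstream > UTR5 > CodingExon > Intron >
Intergenic`, evaluated across all genes. The promoter-proximal categories
outrank gene-body categories because the TSS-region fraction is the headline
statistic being compared between classes. Definitions, with the defaults
`tss_window = 200` bp and `flank = 2000` bp:

* TSS region: within 200 bp of a TSS, either side (symmetric window).
* Promoter: the 2 kb strand-aware upstream extension of the TSS region.
* Downstream: within 2 kb past the TTS, strand-aware.
* UTR5: exonic and 5′ (in transcription direction) of the first CDS base.
* CodingExon: any other exonic anchor. This bucket deliberately absorbs two
  ambiguous cases: 3′-untranslated exonic sequence (there is no UTR3
  category in the scheme) and exons of genes without CDS. Calling exonic
  sequence "Intron" would be worse; the alternative reading (count only CDS
  bases) can be recovered from the gene models if needed.
* Intron: inside the gene span, not exonic.

Category fractions are compared between classes with a two-sided Fisher's
exact test computed as an exact hypergeometric sum: all tables with the
observed margins whose probability is at most that of the observed table
(relative tolerance 1e-7 to absorb floating-point ties, the conventional
choice). The implementation is checked against an independent
log-binomial-coefficient enumeration on every 2×2 table with total ≤ 40.

## Conservation through chain lift-over

Peaks of other species are mapped into the reference genome through UCSC
chain files: each base is mapped through the aligned blocks of the
best-scoring chain overlapping the interval (ties broken by lowest chain
id), and the mapped interval is the minimal span of mapped bases, accepted
when the mapped-base fraction is ≥ `min_match` (0.5, matching the remap
threshold the original analysis used). Minus-strand chains yield
forward-strand coordinates. The vectorized mapper is validated against a
per-base brute-force mapper on random chains of both strands.

A reference site is conserved in a species when a mapped peak overlaps it by
≥ 1 bp. "Conserved in at least N species" counts the reference species
itself, so N ∈ {2, 3, 4} means ≥ 1, 2, 3 supporting species — matching the
bar-triplet presentation of the source figure and monotone non-increasing in
N by construction.

The observed/expected ratio needs an expectation the source never defines;
this package uses class-size-proportional allocation: expected(class) =
total conserved × |class| / total sites. Under this definition the
expected-weighted mean of the per-class ratios is identically 1 (a test
asserts it to 1e-9). A Fisher test of class-versus-rest accompanies each
ratio. MO-site conservation is computed when data exist, but with real data
there is usually no mitotic ChIP in the other species, so the pipeline
report carries a standing caveat on MO rows.

## Motifs

De novo discovery is out of scope; PWMs are inputs (JASPAR or MEME-minimal
readers). Scanning is plain log2-odds with pseudocount smoothing
(`(p + 0.001) / (1 + 0.004)` per cell) over both strands; there is no
p-value calibration — thresholds are in bits. A site is two-part-positive
when a module A hit and a module B hit lie on the same strand, A 5′ of B,
with a gap in `[min_gap, max_gap]` (defaults 0–15 bp, covering the
33/34-mer spacing of the known bipartite motif). The source states no FIMO
threshold; per-module defaults are 60% of each module's maximum attainable
score, documented and configurable. The packaged default module PWMs are
*synthetic stand-ins* built from consensus strings (a CTCF-core-like 20-mer
and a 10-mer), not database matrices; they exist so the generator and
scanner share a planted truth.

## Signal meta-profiles

For each site the window `[anchor − flank, anchor + flank)` is cut into
fixed bins; a bin's value is the length-weighted mean of the bedGraph step
function over the bin (absent data = 0), and the profile is the unweighted
mean over sites, so classes of different sizes are comparable. Windows
clipped at chromosome ends contribute only fully covered bins, and each
bin's denominator counts only the sites covering it. No statistical test is
attached to profiles; they are descriptive, as in the source.

## Spatial statistics and their nulls

**Nearest-neighbor test.** The statistic is each bait's distance to the
nearest target anchor on the same chromosome (a bait in its own target set
is excluded by identity; chromosomes without a partner contribute nothing).
The null shuffles every target uniformly along its own chromosome, keeping
length and chromosome and allowing overlaps — the simplest reading of
"shuffling along chromosomes". The source's "computed 1,000 times followed
by normalization" is interpreted as equal-weight pooling of the
per-permutation distance distributions into one null sample; per-permutation
medians are also stored so users can inspect alternatives. Significance is a
two-sided Wilcoxon rank-sum test of observed versus pooled null, direction
reported via medians. When baits and targets are the same set, each
permutation shuffles the one set and compares it against itself, so bait and
target move together.

*Known limitation:* with two distinct sets and target-only shuffling, the
observed distances share a single target configuration and are positively
dependent; the rank-sum test then rejects a true null at roughly twice the
nominal rate in simulation. The same-set form does not show this (type-I
0.05 at 200 replicates of 500 uniform sites in the acceptance suite). The
within-class tests — the analyses that motivated the method — are same-set;
treat cross-set p-values as approximate.

**Boundary analyses.** Domain boundaries are the domain edges (a position
shared by two adjacent domains is one boundary), indexed per chromosome in
coordinate order. Enrichment profiles bin site anchors by signed distance to
each edge, negative on the domain-interior side, both edges of each domain
used with flipped orientation; counts are divided by the number of edges. A
boundary is labeled IM/IO/MO when a site of that class overlaps the boundary
interval by ≥ 1 bp; point boundaries use a ±500 bp containment window
(configurable), since a zero-width interval can never be overlapped.

**Minimum domain numbers.** The spacing between two boundaries is the
number of domains lying entirely within their closed span, so the two edges
of one domain are 1 apart (the source's convention) and two facing edges
across an inter-domain gap are 0 apart. The statistic per labeled boundary
is the minimum over same-label boundaries on the same chromosome; because
the count is monotone in the span, only adjacent labeled boundaries need
checking, and an exhaustive-pairwise oracle confirms the equivalence.
Cross-chromosome pairs never contribute. The null permutes the label
positions uniformly over all boundaries of each chromosome, preserving the
per-chromosome label count (asserted for every permutation), pooled as
above. Cross-class spacing (e.g. IM boundaries to IO boundaries) is
implemented but not run by default, mirroring the source's figures which
only show within-class comparisons.

## The synthetic world

The generator's defaults are a scaled-down statement of the analyzed
system, fixed once:

* Six chromosome arms named 2L, 2R, 3L, 3R, 4, X totalling ~21 Mb (the real
  arms total ~120 Mb; scaling keeps the suite fast without changing any
  per-site statistic), i.i.d. sequence at GC 0.42 (fly-like).
* 4,145 sites split 870/2031/1244 (= 21%/49%/30%), peak widths 200–400 bp,
  IM pairs jittered by at most 50 bp — strictly less than the minimum
  width, so the pair always overlaps and classification recovers the truth
  exactly, making the generator usable as an oracle.
* 1,800 genes (fly-like density of ~90 genes/Mb at this scale; also needed
  so that TSS-placed sites of different classes can avoid cross-set
  collisions), lengths 1.5–8 kb, 1–5 exons, 10% non-coding.
* TSS-proximal fractions 0.33/0.25/0.10 per class (the first two published;
  the MO value chosen low because MO sites are depleted at TSSs), boundary
  fractions 0.15/0.10/0.10, clustering off by default.
* Two-part motif planted in 60%/51%/29% of IM/IO/MO sites; MO intervals
  rewritten at GC 0.55.
* TADs 50–200 kb with 5–20 kb gaps; syntenic blocks 200–500 kb.
* Three species, chains mapping 70% of bases, 30% minus-strand chromosomes;
  per-class conservation probabilities 0.8/0.4/0.05 (IM most conserved; MO
  essentially absent elsewhere, mirroring the data situation).
* Signal plateaus of height 10 (IM) and 6 (IO/MO) over ±100 bp of summits.

Placement collisions that would corrupt the planted classification (an IO
site overlapping a mitosis record, or an MO site overlapping an interphase
record) are re-drawn *with the same placement rule* until none remain;
planted fractions are therefore preserved exactly up to rounding.

What the generator does **not** emulate: read-level noise and peak-calling
artifacts (peaks are exact), realistic sequence composition beyond GC and
planted motifs, correlated domain/gene architecture, inter-species
rearrangements beyond strand flips and gaps, and replicate variability. A
green test therefore establishes that the *computations* are correct on
data with known structure — not that the biological conclusions would
survive real-data noise.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds (`withr::with_seed`); the
  pipeline derives stage seeds from one master seed, and identical
  configuration + seed gives byte-identical outputs, including JSON reports.
* Nearest-distance ties keep the distance value only; the identity of the
  neighbor is never part of a statistic.
* Chain score ties break by lowest chain id; an interval overlapping no
  chain, or mapping below `min_match`, is "absent", not an error.
* Empty peak sets propagate as empty (fractions reported `NA`); an empty
  classification is an error only where a proportion is requested.
* An interval longer than its chromosome cannot be shuffled and raises an
  error naming the interval; an interval exactly as long as its chromosome
  shuffles to start 0.
* GC windows and sequence windows clip at chromosome ends; all-N windows
  give `NA`.
* Wilcoxon tests use the normal approximation with continuity correction
  (`exact = FALSE`), appropriate at the pooled-null sizes involved.

## Known limitations

* The pooled-null Wilcoxon p-value treats pooled null values as one sample;
  its calibration for distinct bait/target sets is approximate (see above).
* Boundary enrichment double-counts sites near a boundary shared by two
  adjacent domains (once per orientation); with gapped domain calls, the
  default in the generator, this does not arise.
* The O/E expectation is class-size-proportional by definition; a
  shuffle-based expectation would differ when conservation covaries with
  chromosome-scale position.
* `conserved_in_at_least_4` requires three other species; with fewer
  species configured it is identically FALSE rather than an error.
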