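---
title: "Computing and applying genome mappability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and applying genome mappability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mappable)
```

## The model

Short-read experiments cannot distinguish reads that originate from
repeated sequence. For a read length $k$ and a mismatch tolerance $m$,
the *frequency* $F[i]$ of a genome position $i$ is the number of times
the $k$-mer starting at $i$ occurs in the genome and in its reverse
complement, counting as equivalent all $k$-mers within $m$
substitutions (no indels). The *mappability* is $M[i] = 1/F[i]$, a
value in $(0, 1]$ where $M[i] = 1$ marks positions whose reads map back
uniquely; positions whose window contains an N, or that are within
$k-1$ of a contig end, are undefined and reported as 0. Occurrence
counts carry strand multiplicity — a window matched on both strands
(e.g. by a reverse-complement palindrome at $m=0$) counts twice — while
the match-position set $P$ holds each forward-strand start once. This
distinction matters only in corner cases but is fixed here as a
documented convention so that tracks are reproducible bit for bit.

Matching treats N as unmatchable on either side: an assembly gap must
not manufacture spurious uniqueness or multiplicity.

## The fast approximation

Computing $F$ exactly requires matching every position against the
whole genome, which is dominated by high-frequency repeat classes:
thousands of equivalent $k$-mers are re-matched once per member.
`compute_frequency_track()` therefore visits positions in ascending
order and, whenever a query's match-position set $P$ reaches a
threshold $t$, assigns the occurrence count to *every* member of $P$
and skips those positions from then on. A skipped position hit again by
a later propagation keeps the maximum of the propagated values, which
avoids underestimation as far as possible without recomputing.

The guarantees, each enforced by tests:

* exact everywhere when $m = 0$ (equivalence classes at $m=0$ coincide,
  so the propagated value is the true count);
* exact at every unique position for any $t$: a unique position can
  never be a member of another position's match set;
* exact wherever the reported value is below $t$ (propagated values are
  at least $t$ by construction);
* exact everywhere when the approximation is disabled (`t = Inf`).

Elsewhere the value is approximate; the error is typically a small
fraction of the true (large) value and barely moves the mappability,
since $1/F$ is flat for large $F$. `compare_bins()` quantifies this as
a bin-migration matrix over the encoded frequency bins.

The default threshold grows slowly with genome length,
`default_t(n) = max(8, ceiling(log2 n))` (about 27 for 100 Mb, 32 for
3 Gb): small frequency classes stay exact while large repeat families
are collapsed. The formula is this package's own calibration — exposed
as an ordinary argument — chosen so that $t$ tracks the scale at which
chance $k$-mer collisions stop mattering.

Traversal order is ascending global position and the only skip test is
$F[i] \neq 0$; the output is a pure function of (genome, $k$, $m$,
$t$). The engine is single-threaded by design so that this determinism
is unconditional.

## Engine design and numerical choices

The matcher is compiled code with two interchangeable strategies: an
exhaustive window scan (`count_matches()`, `brute_frequency_track()`),
kept deliberately simple so it can serve as the reference
implementation, and a pigeonhole seed index (`build_index()`,
`indexed_count_matches()`, and internally the track computation): a
query within $m$ mismatches of a window must agree exactly with it on
at least one of $m+1$ query chunks, so hashed chunk lookups enumerate a
candidate superset that is verified by Hamming distance. The two paths
are required to agree bit for bit; the test suite checks this on over a
thousand randomized (genome, query, $m$) instances.

Coordinates are 0-based half-open throughout, matching BED/BedGraph;
1-based coordinates appear only in GTF output. Soft-masked lowercase
bases are folded to uppercase — repeats are exactly what mappability is
about — and IUPAC ambiguity codes other than A/C/G/T collapse to N.
$k$-mers never span contig boundaries. `t = 1` is rejected rather than
accepted-and-misbehaving, since it would propagate over unique classes.

## The track format

Tracks are written as pseudo-multi-FASTA: a `~`-prefixed preamble
(parameters, codec constants, contig table), then per contig a `>name`
header and 60-character lines with one printable ASCII character per
base. The codec uses the 94 printable codes: code 0 is "undefined",
codes 1–60 store those frequencies exactly, and the remaining codes
split $(60, 2^{32}]$ into geometric bins with a final overflow
catch-all. A range code decodes to the rounded geometric midpoint of
its bin, which minimizes multiplicative error; since mappability is the
reciprocal, the absolute error this induces on $M$ is negligible
precisely where binning applies. All constants live in the preamble, so
files are self-describing; the byte-offset retrieval index
(`build_track_index()`, `query_region()`) is a sidecar rebuilt on
demand. Because encoded body lines may begin with any printable
character (including `>` and `~`), readers parse records structurally
from the preamble's contig table, never by line prefix.

## Derived scores

*Pileup mappability* (`pileup_mappability()`): a pileup column at $p$
can receive reads starting anywhere in $[p-l+1, p]$, so its mappability
is the mean of $M$ over the valid covering window starts (the track
must have been computed with $k = l$). Near contig starts the mean runs
over the reduced valid set.

*Paired-end mappability* (`paired_end_mappability()`): with fragment
size variance taken as zero, the mate windows of a read at $p$ start at
$p \pm d$ (start-to-start insert size $d$ on the same contig — the
simplest reading of the mate geometry; mates falling off-contig or on
undefined positions are unavailable). Three cases: the position is
already at least as mappable as every available mate (keep it); smaller
than exactly one (average with that mate); smaller than both (average
the two mates). Ties count as case 1 via strict comparison. Pairing
never lowers the single-end value.

*Rescue fraction* (`rescue_fraction()`, `rescue_sweep()`): among
positions with $F > 1$, the fraction whose both mates at distance $d$
have $F = 1$ — those reads are rescued completely, because either end
pins the fragment. One valid unique mate is not enough: "completely"
requires both. Repeats shorter than the insert size with unique flanks
rescue fully, so the fraction rises with $d$ until it saturates at the
scale of the longest repeats. Rescue by unique insert-size
configurations among non-unique mates is deliberately not modeled.

*Proper length* (`proper_length(n, s)`): the smallest $\ell$ with
$s^\ell \ge n$ — the read length above which a random genome would be
essentially all unique. Real genomes deviate from this because they are
not random.

## Expression correction

`project_exons()` collapses each gene's transcripts into an exon-union
interval set (via `IRanges::reduce()`), so shared exon fragments count
once. `unique_exonic_length()` counts union positions with $F = 1$;
window starts near an exon's 3' boundary use the genomic $k$-mer, which
may run into the intron — splice-junction $k$-mers are out of scope, and
the convention is isolated here. With unique-read count $c$, exonic
length $L$, unique length $U$ and $N$ total mapped reads:

$$\mathrm{RPKM} = \frac{10^9\,c}{L\,N}, \qquad
  \mathrm{RPKUM} = \frac{10^9\,c}{U\,N} \;(\mathrm{NA\ if\ } U = 0).$$

When multi-mapping reads are discarded, only the $U$ uniquely mappable
positions can collect reads, so RPKM underestimates repetitive genes by
the factor $L/U$ that RPKUM removes; a half-unique gene recovers its
full expression estimate. Strand is recorded but ignored for the
mappability intersection (mappability is strand-symmetric), and genes
sharing positions count them independently.

## The synthetic genome generator

`generate_genome()` emulates the one feature of real genomes that
drives mappability — repeat families of known copy number and
divergence — on an i.i.d. uniform background, with optional N-gaps.
Divergence is modeled as up to `max_divergence` biallelic segregating
sites shared by a family, each copy carrying a random subset of the
alternate alleles. This bounds the *pairwise* Hamming distance between
copies by `max_divergence`, so a family with divergence $\le m$ is
provably one equivalence class and every copy start must reach
$F \ge$ copy number — the property the recovery tests assert. (Mutating
each copy independently would allow two copies to drift up to twice
the per-copy divergence apart and would void that guarantee.) What the
generator does *not* emulate: indels, nested or truncated repeats,
GC-content structure, and the fractal repeat hierarchy of real genomes;
green tests on these fixtures validate the algorithmic contracts, not
biological realism. One integer seed drives a named stream per
component (background, units, placement, mutation, gaps), so fixtures
are byte-stable when unrelated features are added.

`generate_annotation()` lays 1–5-exon genes over unique background or
directly on planted copies per class recipe, mimicking e.g. a clustered
multi-copy RNA family next to largely unique protein-coding genes.

## Problem sizes used by the test suite

The validation suite runs 100 random genomes with sizes drawn
log-uniformly between 1 and 50 kb with mixed repeat content. Exactness
with `t = Inf` is checked against the exhaustive scanner over the full
track on genomes up to 6 kb and at 300 sampled positions (plus all
planted copy starts) on larger ones — the exhaustive oracle is
quadratic in the genome size, and sampling keeps it honest without
making it the bottleneck; the $m=0$ checks use an independent
enumeration oracle (sorted $k$-mer counting) at full length on every
genome. Engine equivalence runs on over 1000 randomized instances with
$m \in \{0,1,2\}$. These scales were chosen so that the whole suite
completes in minutes on a single core while still visiting every
guarantee.

## A worked example

```{r example}
g <- generate_genome(6000, list(repeat_spec(40, 12, 2)), seed = 13)
track <- compute_frequency_track(g$ref, k = 40, m = 2, t = 4)
table(track$values[g$truth$start + 1])   # copy starts see the whole family
mt <- frequency_to_mappability(track)
round(pileup_mappability(mt, g$truth$start[1]), 3)
rescue_fraction(track, library_spec(40, 500))
```

## Known limitations

* Edit distance (indels) is not supported; the equivalence relation is
  substitutions-only by construction.
* The track dialect is self-describing but intentionally not
  byte-compatible with other tools' mappability files, whose bin
  boundaries are unpublished.
* Whole-mammalian-genome runs are methodologically supported but not
  exercised by the test fixtures; memory use of the seed index is
  linear in genome size with a substantial constant.
* Splice-junction mappability and isoform-level deconvolution are out
  of scope.
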