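# mappable

Genome mappability computation and its downstream applications, for
people analysing short-read sequencing data (ChIP-seq, RNA-seq, DNA-seq)
who need to know, *before* looking at any reads, which parts of a
reference can be mapped unambiguously.

## What it computes

For a read length *k* and a mismatch tolerance *m*, the **frequency**
F[i] of a genome position is the number of occurrences of the k-mer
starting at i in the genome and its reverse complement, counting as
equivalent all k-mers within m substitutions; the **mappability** is
M[i] = 1/F[i] ∈ (0, 1], with M = 1 at uniquely mappable positions and 0
where no valid k-mer exists (N gaps, contig tails).

Exact computation re-matches large repeat classes once per member, so
`compute_frequency_track()` uses a propagation approximation: positions
are visited in ascending order, and whenever a query's match-position
set P has |P| ≥ t, its occurrence count is written to every member of P
(max rule on collisions) and those positions are skipped. The result is
exact for m = 0, exact at every unique position, exact wherever the
reported value is below t, and fully exact with `t = Inf`.

On top of the tracks the package provides:

* a compact self-describing **track format** (one printable ASCII
  character per base, exact codes 1–60 then geometric bins), with a
  byte-offset index for `query_region()` and BedGraph export;
* **pileup mappability** (mean over the l covering window starts),
  **paired-end mappability** (three-case mate-averaging rule) and
  **rescue fractions** over insert-size sweeps;
* **RPKUM** — reads per kilobase of *unique* exon per million mapped
  reads, `1e9·c/(U·N)` — alongside RPKM, over exon-union projected gene
  models (`project_exons()`), plus per-class mappability profiles;
* a **synthetic-genome generator** with planted repeat families of
  known copy number and bounded pairwise divergence, used as ground
  truth by the test suite.

## Worked example

```r
library(mappable)
g <- generate_genome(6000, list(repeat_spec(40, 12, 2)), seed = 13)
track <- compute_frequency_track(g$ref, k = 40, m = 2, t = 4)
table(track$values[g$truth$start + 1])
#> 12
#> 12
```

All 12 planted copy starts report frequency 12: the family is one
equivalence class at m = 2 because copy divergence is bounded pairwise.

```r
mt <- frequency_to_mappability(track)
round(pileup_mappability(mt, g$truth$start[1]), 3)
#> [1] 0.932
```

A pileup column at the first copy start still gets most of its reads
from the unique flank upstream, hence a mean mappability near 1 rather
than the 1/12 of the copy-interior windows.

```r
rescue_fraction(track, library_spec(40, 500))
#> [1] 0.7435897
```

74% of the non-unique positions have both mate windows (insert size
500) on unique sequence, so their reads are rescued completely by
pairing.

```r
print(track)
#> frequency_track: n=6000, k=40, m=2, t=4
#>   defined positions: 5961  unique: 5844
```

See `vignettes/genome-mappability.Rmd` for the model, the approximation
guarantees, the track dialect and the design decisions.

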