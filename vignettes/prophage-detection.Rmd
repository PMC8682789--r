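---
title: "Detecting excisable prophages from overlapping split-read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting excisable prophages from overlapping split-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attrace)
```

## The model

An integrated prophage is flanked by two attachment sites, attL and attR,
sharing a common core (a direct repeat of 2 to ~150 bp). Site-specific
recombination between them excises the element, leaving one core copy on the
chromosome (attB) and one on the circular phage genome (attP). In a
sequencing library from a culture where some cells carry the excised state,
reads spanning an attB or attP junction exist at a rate proportional to the
abundance of the excised/circular molecules and to the junction "visibility
window" on a read.

The discriminative signal is the *overlapping split-read alignment*. A
junction read aligns locally to the two attachment loci with query intervals
R1–R2 and R3–R4 satisfying R1 < R3 ≤ R2 < R4; the overlap `ov = R2 − R3 + 1`
is the att core carried by the read, because both local alignments extend
through the shared core. Generic structural-variant breakpoints produce
*disjoint* query intervals; requiring an overlap therefore suppresses the
large background of other improperly aligned reads. Classification is
geometric: if the query prefix maps upstream of the suffix, the read jumps
forward across a deletion — an excision (attB) junction; if it maps
downstream, the read wraps across the circular junction (attP). Both
evidence types imply the same four att endpoints, which is also the internal
consistency check that makes boundary calls base-pair precise.

Discordant read pairs (pairs aligned end-to-end but with incompatible
orientation or spacing) are secondary evidence: a pair flanking the element
from outside in deletion orientation supports attB; an everted pair just
inside the element supports attP. They cannot pinpoint boundaries and are
only merged into clusters built from split-read evidence.

## Pipeline stages and the parameters that matter

1. **Preliminary extraction** (`detect_split_candidates()`,
   `detect_discordant_candidates()`). Mapped primary records with one-sided
   clip patterns `aSbM`/`aMbS` are admitted when the FLAG value matches the
   clip side: a clip facing away from the mate implies a long apparent insert
   (proper-pair bit off — FLAGs 145/81 left, 97/161 right and their
   first/second-in-pair mirrors), a clip facing the mate a normal insert
   (99/163 left, 147/83 right). Both the clipped and aligned lengths must lie
   in `clip_bounds` (default [10, 150] for 2 × 150 bp libraries; the lower
   bound is the minimum anchor that makes a 10 bp alignment non-random, the
   upper bound the read length). Discordant candidates are single `M`-runs
   longer than `min_aligned` (130 bp, i.e. near-full-length) with the
   non-proper FLAG set. Contig-level references additionally admit the
   inverted-orientation FLAGs (113/117, 65/129 splits; 177/113/129/65 pairs).
   A `lenient_flags` switch matches FLAGs ignoring the proper-pair bit, for
   aligners with different 0x2 conventions; the default is the strict integer
   match. Records whose FLAG marks them unmapped carry no usable CIGAR and
   are excluded from re-alignment.

2. **Verification** (`verify_split_reads()`). Each candidate is re-aligned
   from scratch: a Smith–Waterman local alignment (match +1, mismatch −2,
   gap open 3, gap extend 1) around its mapped position gives the anchor
   segment, and the second locus is found by exact/1-mismatch matching of a
   14 bp seed taken from the outer end of the clipped part, refined by local
   alignment in a window around each seed hit. Seeding the whole reference
   costs little and avoids restricting the search to a distance window;
   random 14-mers are effectively unique in genomes ≪ 4^14 ≈ 270 Mb. Each
   segment must be ≥ `min_segment` (10 bp, matching the clip bound) at
   identity ≥ `min_identity` (0.95 — loose enough for 1–2 bp core mismatches
   and ~0.1% sequencing error, tight enough to reject random 10 bp hits
   combined with the seed requirement). When several alignment pairs satisfy
   the overlap criterion the pair with the largest total aligned query
   length wins, then highest summed identity, then smallest reference
   coordinates — a deterministic tie-break. Reads splitting into more than
   two admissible segments keep only the best pair. Segments on different
   contigs yield `jtype = "cross"` for the contig-level path.

3. **Clustering and filtering** (`cluster_evidence()`, `merge_discordant()`,
   `filter_candidates()`). Evidence quads are single-linked at
   `cluster_tol = 2` bp per endpoint (exact junction reads agree exactly;
   2 bp absorbs end-trimming jitter at degenerate core edges), and the
   consensus takes the per-endpoint mode with ties to the smaller
   coordinate. Discordant pairs are assigned within `drp_window = 1000` bp
   (covers short-insert libraries) to the cluster they bracket most tightly,
   once per pair. Default report filters: att length > 2 bp (shorter cores
   are indistinguishable from blunt breakpoints), 5 kb < size < 150 kb
   (the plausible prophage size range), and at least one attB *and* one attP
   event. Read-level counting is used (both split mates of one fragment
   count twice); the evidence rendering per candidate supports manual review
   of genes disrupted at the integration site.

4. **Contig mode** (`detect_cross_contig_candidates()`). Cross-contig
   evidence is clustered per contig pair and orientation. The att core sits
   at the end of the query-prefix segment (its contig joins rightward, noted
   `"contig = "`) and at the start of the query-suffix segment (joins
   leftward, `" = contig"`). The approximate size sums each att site's
   distance to the junction-side end of its contig; it equals the true size
   when the contigs abut and underestimates it when a third contig
   intervenes, so only the upper size bound is applied. Excision versus
   circularization identity cannot be read off reference order across
   contigs, so cross-contig candidates carry an undifferentiated read count.
   A prophage split across two contigs typically yields two junction
   records — the excision join and the circular join — whose att intervals
   agree.

## The simulator

`simulate_prophage_genome()` builds a random host genome at a requested GC
content with one prophage at a uniform random position:
`H1 | attL | interior | attR | H2`, the att copies identical except for 1–2
substitutions when the core exceeds 2 bp. The excised chromosome
(`H1 | attB | H2`, attB = the attL copy) and the circular phage genome
(linearized as `interior | attP`, attP = the attR copy) are derived from the
same sequence, so `len(wt) = len(excised) + size` and
`len(circular) = size` hold by construction.

`simulate_read_mixture()` draws fragments from the three molecules with
probability proportional to `copy-number ratio × molecule length` until the
library reaches `depth` × coverage of the wild-type genome (2 × 150 bp
reads; Gaussian insert 350 ± 50 truncated to [300, 1000]; uniform per-base
substitution error, default 0.001, with flat qualities — an error model
whose details are not load-bearing for junction geometry). Instead of
running an aligner, the truth alignment of every read against the wild-type
reference is computed from its provenance: junction-crossing reads get the
primary alignment on their longer split segment with the remainder
soft-clipped, and the proper-pair bit follows the mapped FR geometry — which
reproduces exactly the FLAG/CIGAR patterns the extraction stage admits.
Sequences are materialized for soft-clipped records (others may carry SAM
`SEQ *`), keeping multi-replicate protocols fast; `seq_policy = "all"`
materializes everything for FASTQ export.

One subtlety determines what "exact boundary recovery" means. The att core
the *data* supports is the maximal-scoring shared context of the two
attachment loci, not the constructed core: a chance match of the flanking
bases extends the realized direct repeat (probability 1/4 per flank per
base), and a mismatch placed at a core edge is trimmed by any score-maximal
local aligner. The simulator therefore reports as truth the realized quad,
computed from the genome with the same +1/−2 scoring the verifier uses.
Evaluation (`evaluate_calls()`) scores a call as a hit when all four
endpoints lie within `tol` (default 2 bp, 0 for strict exactness) of this
realized truth.

What the simulator does *not* emulate: real aligner heuristics (mapping
quality, ambiguous placement of reads inside long att cores), non-uniform
error profiles, chimeric library artifacts, repeat-rich host genomes, and
Mu-like prophages that package with variable ends (which the method cannot
detect even in principle). Passing simulated tests therefore demonstrates
the geometry and statistics of the method, not robustness to every real
library artifact.

## Study protocols, problem sizes and statistical expectations

The packaged protocols scale the study design down to desk size; the
vignette states these as the package's chosen problem sizes. Genomes of
160–400 kb with 6–60 kb prophages behave identically to multi-Mb genomes
for junction statistics, because junction-read counts depend only on the
coverage of the excised/circular molecules and the att length, not on
genome size.

The expected number of *verifiable* junction reads per library is
`λ = (cov_attB + cov_attP) × (131 − att_len)/150` — the junction is visible
from `read_len − att_len − 2 × min_segment + 1` start positions. Two
consequences follow. First, the recovery ceiling: with 150 bp reads and
10 bp anchors no junction read exists for att cores above 130 bp, and the
sweep protocol (att 2→160, ratios 97:2:1, 100×) measures a ceiling at or
just below that structural limit — at those ratios the minor molecules sit
near 2–3× coverage, so λ(130) ≈ 0.02 per library and the measured ceiling
fluctuates between ~110 and 130. Second, low-excision detection: at
molecule ratios 1000:1:1 the first depth in {10, 20, 50, 100} with evidence
in ≥ 1 of 20 replicates is typically 20–50×, and tenfold circular-phage
replication (1000:1:10) brings it down to 10× — weak-signal threshold
events with the corresponding Poisson tails. Boundary exactness, by
contrast, is deterministic once evidence exists; every simulated recovery
in the test suite that produced evidence hit the realized truth quad
exactly. Draws combining a very short core (≤ 4 bp) with the full 2 bp
divergence can lose the query overlap to alignment trimming; that is the
method's honest behavior on degenerate repeats, not an implementation
artifact.

## Excision-activity fold-change

For a single prophage observed under two conditions, evidence counts
normalized by library size estimate the *relative change* in excision
activity: `fc = (count_t / total_t) / (count_c / total_c)` per evidence
class (attB — the excision proxy, attP, combined). Absolute excision rates
are *not* estimable this way, because the junction-read yield depends
strongly on att length. A zero count entering either rate is replaced by one
and flagged, making the result a bound rather than an estimate. The choice
of total reads (mapped + unmapped) as the normalizer is configurable by
passing any consistent library-size measure. `primer_windows()` exports
150 bp windows flanking both junctions for qPCR confirmation with 200–300 bp
products.

## Numerical choices, degenerate inputs, limitations

* Coordinates are 1-based closed throughout, as in SAM.
* Abutting (non-overlapping) splits are rejected unless `min_overlap = 0` is
  requested; the default filter requires att length > 2 bp anyway.
* Two-side-clipped reads are rejected in preliminary extraction; at
  `a, b ≥ 10` true junction reads are one-sided.
* Reads whose clipped part is too short for the 14 bp seed fall back to an
  exact-match seed of the clipped length.
* A candidate quad with `attL_end ≥ attR_start` (inconsistent geometry) is
  discarded.
* Verification of hard-clipped records is impossible without the full read
  sequence; they count in extraction but are dropped at verification.
* Detection requires the excision state to exist in the culture at sampling
  time and at least one junction-spanning read; prophages that never excise,
  excise with variable ends, or whose att cores exceed ~130 bp (for 150 bp
  reads) are out of reach of split-read evidence — the latter can still be
  approached through discordant pairs, which this package reports but does
  not use for boundary inference.
* Real-data validation against public short-read accessions is possible by
  aligning reads upstream (any SAM-producing aligner) and running
  `run_trace()`; it requires downloads and is not part of the test suite.

## Reproducibility

All randomness is seed-controlled (`simulate_prophage_genome(seed = )`,
`simulate_read_mixture(seed = )`); identical seeds give byte-identical
genomes, libraries and reports. `scripts/acceptance.R --seed N` derives
every simulation seed from `N` and recomputes the headline quantities by
running the installed package end to end.
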