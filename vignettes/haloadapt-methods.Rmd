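---
title: "haloadapt: models and methods for CRISPR acquisition-assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haloadapt: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloadapt)
```

## The biological setting

Type I-B CRISPR-Cas systems acquire new spacers at the leader end of their
CRISPR arrays. When a crRNA directs interference against the host's own
genome (self-targeting), the Cas3 nuclease-helicase degrades DNA around
the protospacer and the resulting fragments feed the adaptation machinery
(Cas1-Cas2-Cas4). Acquisition assays read this process out by
PCR-amplifying the leader-proximal end of an array and sequencing the
amplicons: an expanded array shows up as an extra repeat-spacer unit
(occasionally two) between the leader and the first endogenous spacer.

Three signatures of such assays drive the design of this package:

1. **Genome-wide origins with hotspots.** Newly acquired spacers map back
   to all replicons, concentrated near features with frequent free DNA
   ends — transposase genes, an integrated provirus, highly transcribed
   rRNA operons — and, under targeting, around the target site itself.
2. **Strand-asymmetric, distance-decaying acquisition around the cut.**
   Upstream of the cut site spacers derive predominantly from the coding
   strand, downstream from the template strand, and counts decay with
   distance — a footprint of Cas3's 3′→5′ processivity.
3. **A sharp adaptation PAM.** The trinucleotide immediately 5′ of the
   protospacer is strongly biased toward a single motif (TAC in the
   system this package is calibrated to, at roughly three quarters of
   events), much stricter than the interference PAM repertoire.

`haloadapt` implements the full analysis path (parse → map → PAM →
hotspots → target profile) together with a generative model of the assay,
so that every analysis stage can be validated against planted truth.

## The synthetic-data generator

`simulation_config()` fixes all parameters; a single seed determines every
random draw (the reference, prespacer and read stages use `seed`,
`seed + 1` and `seed + 2`, so stages can be re-run independently and still
reproduce byte-identically).

**Reference genome.** One "chromosome" (default 200 kb) plus one or more
plasmids (default 20 kb), i.i.d. bases at a configurable GC fraction
(default 0.65, a GC-rich haloarchaeal genome). Hotspot features
(transposases, an rRNA operon, a provirus), a `target_site` and optionally
a `hen_site` are placed uniformly without overlap, with a 100-nt margin.
The feature's `strand` field declares the coding strand of the targeted
gene; the **cut site** is a single coordinate, the 5′ boundary of the
target feature on that strand. Real genomes are of course not i.i.d.
sequence: the generator does not emulate local composition bias, repeated
elements or mobile-element copies, so multimapping is rare in simulation
(and is exercised by dedicated constructed tests instead).

**Prespacer origins.** Each of `n_prespacers` events draws its component
from the mixture (`w_target`, `w_hotspot`, `w_background`):

* *target*: a side (upstream/downstream, equiprobable) and a geometric
  offset with scale `target_decay_scale` (default 500 nt) from the cut
  site; the strand follows the configured rule — by default upstream →
  coding strand, downstream → template strand, the asymmetry observed
  under self-targeting. The decay is modelled geometrically because the
  observed pattern is a monotone decline suggestive of a processive
  nuclease dissociating at a constant per-base rate; the published data
  constrain the shape only qualitatively, so the scale is a free,
  configurable parameter.
* *hotspot*: uniform within a uniformly chosen hotspot feature, either
  strand.
* *background*: uniform over the genome (replicons weighted by length),
  either strand.

**PAM planting.** With probability `pam_modal_fraction` (default 0.76) a
draw is constrained so the 3 nt immediately 5′ of the protospacer — on the
protospacer strand — equal `pam_modal_motif` (default TAC). This is done
by rejection sampling over candidate positions indexed by their upstream
trinucleotide, never by rewriting reference bases, so the reference stays
internally consistent. Unconstrained draws may still carry the modal
motif by chance (≈ 1/64 of them), so the realised modal fraction sits
marginally above the planted probability; at the depths used here the
excess (< 0.4 percentage points) is well inside binomial noise. For
target-component draws the offset is redrawn until the constraint holds,
which conditions the geometric law on motif availability; decay-recovery
tests therefore plant with the PAM constraint disabled.

**Reads.** Each event receives reads by a uniform multinomial over
`n_reads` (PCR jackpotting is deliberately not modelled; the per-read
vs per-spacer distinction downstream exists precisely because real
libraries conflate amplification with acquisition). A read is

```
adapter + k random bases + leader anchor + (repeat + spacer) x m
        + repeat + endogenous-spacer anchor
```

with `k` uniform on 0-3 (the random bases real primers carry to add
cluster diversity), `m = 2` with probability `double_insertion_fraction`
(the second, array-distal unit carries another planted spacer), a
configurable reverse-complemented fraction (default 0.5), and i.i.d.
substitution errors at `error_rate`. Indels are not modelled by default:
substitutions dominate short-read error profiles, and Hamming-only
matching keeps an exact brute-force oracle cheap. Reads span the full
amplicon (the sequencing layout of the assay is not constrained by the
published description; full-length single reads are the simplest faithful
choice). Supplying a `read_length` shorter than a construct is a
configuration error rather than silent truncation.

The `TruthTable` records, per event: sequence, replicon, interval
(0-based half-open), strand, mixture component, upstream PAM and planted
read count. Tests assert that coordinates reproduce sequences exactly and
that planted read support is conserved through parsing.

## Parsing

`orient_and_trim()` anchors the adapter at the read start (Hamming ≤
`anchor_max_mismatches`, default 2), tries each random-prefix length, then
requires the leader anchor, in the read and its reverse complement;
rejections carry reason codes (`no_adapter`, `no_anchor`) and are data,
not errors. `detect_expansion()` then scans greedily: match the repeat
(≤ `repeat_max_mismatches`, default 3), take the segment up to the next
repeat occurrence as a spacer, and stop at the endogenous next-spacer
anchor or the read end. Segments equal to an endogenous spacer are
discarded; a read whose array contains no novel segment is `unexpanded`,
mirroring the gel-level distinction between expanded and unexpanded
products. Mismatch tolerances are configuration, not reconstructions —
the published analysis does not state its thresholds.

`aggregate_calls()` deduplicates by exact sequence (the published
analysis gives no clustering rule; an error-tolerant collapse would trade
precision for recall and is left out), sums distinct-read support,
records the modal insertion index, and orders by support with
lexicographic tie-breaks so output is deterministic.

## Mapping

`map_spacer()` performs an exhaustive Hamming scan (compiled) of both
strands of every replicon, returning *all* positions within `max_mm`
(default 2, matching the parser's tolerance scale). Circular replicons
are scanned on a virtual extension of length `L + len − 1`; wrapped hits
keep `start ∈ [0, L)` with `end = start + len` interpreted modulo `L`. At
the genome sizes of this assay (a few hundred kb) a direct scan with
early mismatch exit is faster in practice than seeded filtering and has
no heuristics to verify; its output is checked against an independent
brute-force scan written in plain R. A hit is flagged `unique` only when
exactly one hit attains the minimal mismatch count; downstream counting
uses unique hits by default (the published multimapper policy is not
stated, so the conservative choice is declared here). The PAM is attached
at mapping time: the 3 nt 5′ of the protospacer on its own strand, i.e.
the genomic reverse complement for minus-strand hits.

Distances: `distance_to_target` is the signed offset from the cut-site
coordinate to the hit's nearest edge (negative = upstream on the declared
coding strand; 0 = covering the cut). `distance_to_hen` is the minimal
unsigned gap to the HEN-site interval (0 when overlapping), matching how
proximity is counted in endonuclease-site accounting.

## PAM summary

`summarize_pams()` filters to unique hits with support ≥ `min_reads`
(default 10, the threshold used for PAM extraction in this assay class),
then tallies k-mers (k = 3 by default; the adaptation PAM is reported as
a trinucleotide). The PFM normalises each column to 1 (exact to 1e-9 in
tests); consensus is the per-position argmax with lexicographic
tie-break; information content is `2 − H_j` bits with no small-sample
correction (depths here make the correction negligible, and omitting it
keeps the statistic exactly reproducible). Whether the published modal
fraction is per unique spacer or per read is not stated; both weightings
are computed, with per-spacer as the default because read support
conflates amplification with acquisition. Zero contributing hits yield an
empty-summary sentinel rather than an error, so pipelines degrade
gracefully on sparse libraries.

## Hotspots and the target profile

The published hotspot identification is descriptive (coverage plots), so
the statistic here is the package's own, fully declared: non-overlapping
windows (default 1 kb) per replicon, null expectation
`λ = N·w/G` from a genome-wide uniform law, upper-tail Poisson p-values,
BH adjustment across all windows at `alpha = 0.05`, and maximal runs of
adjacent significant windows merged into calls annotated with overlapping
features. Unique-spacer counting is the primary statistic (read-weighted
counts are emitted alongside) to avoid PCR-jackpot artifacts. A Poisson
null ignores overdispersion; with unique-spacer counting at desk scale
this is adequate (the Monte-Carlo false-discovery test in the suite runs
at the nominal level), but strongly clustered real libraries may warrant
a negative-binomial null, which is out of scope.

`profile_target()` bins signed distances by strand (default ±5 kb, 100-nt
bins), fits the per-side geometric scale by maximum likelihood
(`ŝ = 1 + mean(|d|)`, the closed-form MLE; distances of exactly 0 sit in
the overlap bin and contribute to neither side, a truncation whose bias
at scale 500 is ≈ 0.2%), and reports the upstream coding-strand and
downstream template-strand fractions. Profile tests place the target
centrally so the geometric tail is not clipped by a replicon edge; with
edge-proximal targets the recovered scale is an underestimate by
construction.

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere; "+" is the replicon
  sequence as written. BED output is therefore a direct column dump.
* All randomness flows from configuration seeds; identical configurations
  byte-reproduce every output file (asserted in tests).
* Ties are always broken deterministically (lexicographic for sequences
  and consensus bases, position order for windows).
* Formats: FASTA/FASTQ via Biostrings; BED6 and TSV as plain tables;
  locus descriptions as YAML; run summaries as JSON.
* Degenerate inputs prefer sentinels over exceptions where the condition
  is data (no hits after filtering, no hits in the profile radius);
  configuration contradictions (window larger than a replicon, read
  length shorter than a construct, non-ACGT queries) raise errors.

## Problem sizes and what the tests show

The test suite validates each stage against planted truth and independent
oracles at desk scale: full libraries of 50,000 and 11,000 error-free
reads parsed completely; 5,000-event PAM recovery within binomial error
of the planted 76%; 2,600 distinct background spacers recovered exactly;
mapping checked against brute force for 200 queries on a 50-kb reference
at 0-2 mismatches; hotspot false-discovery rate estimated over 100
uniform-background replicates; decay-scale recovery at 20,000 events
within 10% median error. Passing these shows the implementation is
faithful to its own generative model; it does not by itself establish
performance on real libraries, whose error structure (indels, chimeric
PCR products, quality dropoff) and genome repetitiveness the generator
intentionally simplifies.

## Known limitations

* Hamming-only matching: indel sequencing errors shift the repeat frame
  and such reads are rejected rather than rescued.
* No error-tolerant spacer clustering: sequencing errors inside a spacer
  create low-support satellite calls; the read-support filter absorbs
  these for PAM work, but exact unique-spacer counts on noisy real data
  will overcount.
* Poisson (not negative-binomial) hotspot null; genome-wide uniform
  expectation rather than per-replicon baselines.
* The geometric decay model is a single-scale summary; real profiles may
  be multi-phasic.
* PCR amplification bias is not modelled; read-weighted statistics on
  real data inherit it.
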