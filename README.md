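# haloadapt

Analysis of CRISPR **spacer acquisition (adaptation) assays** in type I-B
systems, as sequenced in GC-rich archaea such as *Haloferax volcanii*. In
these assays the leader-proximal end of a CRISPR array is PCR-amplified and
sequenced; reads from cells that acquired a spacer carry one (occasionally
two) extra repeat–spacer units between the leader and the first endogenous
spacer. `haloadapt` takes such amplicon libraries from raw reads to:

* **novel-spacer calls** — mismatch-tolerant detection of inserted
  repeat–spacer units, aggregated with read support;
* **protospacer maps** — exhaustive Hamming-distance placement of each
  spacer on a multi-replicon reference (circular replicons honoured),
  with all-best-tier multimapper reporting;
* **PAM consensus** — the trinucleotide immediately 5′ of each
  protospacer, summarised as counts, a position frequency matrix,
  consensus, modal-motif fraction and per-position information content;
* **acquisition hotspots** — Poisson tests on non-overlapping genome
  windows with Benjamini–Hochberg correction, merged into hotspot calls
  annotated with overlapping features (transposases, rRNA, provirus);
* **target-site profiles** — strand-resolved distance histograms around a
  self-targeting (or homing-endonuclease) cut site, with a per-side
  geometric decay-scale fit and upstream/downstream strand-bias fractions.

A first-class **synthetic-data generator** plants acquisition events with
known origins (target-proximal with distance decay and a strand rule,
hotspot-concentrated, or uniform background), a configurable modal-PAM
fraction, and substitution sequencing errors — so every stage can be
validated against a truth table at desk scale.

## The model in brief

*Parsing.* A read is `adapter + k random bases (k = 0–3) + leader anchor +
(repeat + spacer)×m + repeat + endogenous-spacer anchor`. Anchors and
repeats are matched by Hamming distance (defaults: 2 mismatches for
anchors, 3 for repeats; substitutions only — appropriate for
substitution-dominated short-read errors). Reads are tried in both
orientations; inter-repeat segments not matching an endogenous spacer are
novel spacers, reported leader-proximal first.

*PAM.* For hits passing the read-support filter (default ≥ 10 reads,
uniquely placed), the upstream trinucleotide is tallied into a PFM
`p(b, j)`; information content per position is `2 − H_j` with
`H_j = −Σ_b p(b,j) log2 p(b,j)`. The modal fraction is the share of whole
3-mers equal to the most frequent 3-mer (per unique spacer by default;
per-read weighting also emitted).

*Hotspots.* With `N` unique spacers on a genome of length `G`, a window of
width `w` has null expectation `λ = N·w/G`; windows get upper-tail Poisson
p-values `P(X ≥ x | λ)`, BH-adjusted across all windows; adjacent
significant windows merge into hotspot calls.

*Target profile.* Signed distance `d` from the cut site (negative =
upstream on the coding strand). Offsets per side are modelled as geometric
with scale `s`; the MLE is `ŝ = 1 + mean(|d|)`. The strand rule observed
under self-targeting — upstream spacers from the coding strand, downstream
from the template strand — is reported as two fractions.

## Worked example

```r
library(haloadapt)

sim <- simulation_config(seed = 7, n_prespacers = 400, n_reads = 20000)
summary <- run_pipeline(run_config("runs/demo", sim = sim))
str(summary, max.level = 1)
```

yields (elided):

```
$ n_reads            : int 20000
$ expanded_reads     : int 20000
$ unexpanded_reads   : int 0
$ rejected_reads     : int 0
$ unique_spacers     : int 342
$ replicon_fractions : chromosome 0.962, plasmid1 0.038
$ pam per_spacer     : modal TAC, fraction 0.743 (n = 342)
$ n_hotspots         : int 5
$ target_profile     : decay upstream 792 nt / downstream 1127 nt,
                       upstream coding-strand fraction 0.943,
                       downstream template-strand fraction 0.878
```

All 20,000 error-free reads are recognised as expansion-bearing; the 400
planted events collapse to 342 unique spacer sequences (independent draws
can coincide). The recovered modal PAM fraction (~0.74 per spacer) tracks
the planted 0.76, and `runs/demo/hotspots.tsv` shows the called hotspots
sitting on the planted enrichment sites:

```
replicon    start   end     observed  expected  q          features
chromosome  47000   53000   129       9.33      2.8e-74    crtI-target,ISH-3
chromosome  118000  119000  14        1.55      4.1e-08    ISH-5
chromosome  124000  125000  17        1.55      6.5e-11    ISH-2
chromosome  130000  131000  21        1.55      5.2e-15    ISH-1
chromosome  193000  194000  9         1.55      8.9e-04    ISH-4
```

Per-stage functions (`sample_prespacers()`, `parse_reads()`,
`map_spacers()`, `summarize_pams()`, `call_hotspots()`,
`profile_target()`) expose the same computations on your own data; a thin
command-line wrapper lives in `inst/scripts/run-pipeline.R`. See the
methods vignette (`vignettes/haloadapt-methods.Rmd`) for the full model,
parameter and design discussion.

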