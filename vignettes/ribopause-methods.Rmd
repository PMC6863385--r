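---
title: "Methods: P-site calibration, trimmed metagenes and pause scoring in ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: P-site calibration, trimmed metagenes and pause scoring in ribopause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

## The problem

Ribosome profiling sequences the ~26–35 nt mRNA fragments protected by
translating ribosomes. Each read reports one ribosome position, but only
indirectly: the codon held in the ribosomal P-site lies a fixed,
read-length-dependent distance downstream of the read's 5′ end. Once that
offset is known, footprints become codon-resolution occupancy, and two
hallmarks of translational regulation become measurable: accumulation of
ribosomes at the start codon, and local stalling at hard-to-translate
motifs — most prominently triproline (PPP) and its neighbours SPP and PPV,
whose smooth elongation requires hypusinated eIF5A. In B cells this
matters because TFEB, the short-lived master regulator of the
autophagy–lysosome programme, carries a PPP-containing motif (SPPPVP
context) and its synthesis collapses when eIF5A hypusination is inhibited
(e.g. by GC7).

A complication motivates one more model ingredient: severe stalls can
trigger no-go decay of the mRNA, so a *stronger* stall does not have to
produce *more* footprints at the motif — degradation removes the very
reads that would report it. An observed "no further increase" in motif
occupancy under GC7 is therefore compatible with increased stalling. The
package treats this as a read-loss process and makes it simulable.

Because public footprint data come without ground truth, every analysis
step here is validated by **parameter recovery**: a simulator plants known
offsets, enrichments and pause multipliers, and the analysis layer must
recover them from the reads alone.

## The generative model

For a transcript with CDS codons $c = 0, \dots, K-1$, a footprint's P-site
codon is drawn with probability proportional to

$$w_c = \lambda \cdot s^{\,[c = 0]} \cdot m^{\,[c \in \text{motif}]}$$

where $\lambda$ is the base density (reads/codon), $s \ge 1$ the
start-codon enrichment and $m \ge 1$ the pause multiplier at planted motif
codons. The read length $L$ is categorical over 26–35 nt, the 5′ end is
placed at `cds_start + 3c − o(L)` with the planted offset $o(L)$, the full
adapter is appended, and qualities are Phred 40 (Phred 10 for the
low-quality class). With probability `nogo_drop` a read whose P-site lies
in a motif codon is discarded before output — the no-go-decay read loss.
Contaminant reads are substrings of bundled synthetic rRNA-like sequences;
spike-in reads are drawn flat from a second, `spike|`-prefixed transcript
set, mirroring a concatenated two-species reference.

Defaults follow the library design they emulate: adapter
`ATCTCGTATGCCGTCTTCTGCTTG`, quality cutoff Phred 20, calibratable lengths
26–35 nt with 88% of the length mass on the gel-selected 27–30 nt range,
and a spike-in fraction of 1/6 (a 20:4 RNA mass ratio of primary to spike
material). The planted offset map (11–15 nt, 12 nt for a 28-mer) follows
canonical elongating-ribosome geometry; the published experiment reports
neither its empirical length distribution nor its fitted offsets, so these
two defaults are the package's own choices and are stated here once.

What the simulator deliberately does **not** model: sequencing errors
(reads are error-free so exact-match alignment is complete and the
alignment-truth bijection is testable; a uniform substitution rate would
be the natural extension), splicing, UMIs, ligation/RNase sequence biases,
codon-specific dwell times beyond the planted multipliers, and any
transcript-abundance distribution (all transcripts are sampled from the
same weight pool). Passing recovery tests therefore demonstrates
correctness of the *analysis arithmetic* under a faithful but idealized
library, not robustness to every artefact of real footprint data.

## Preprocessing

Adapter trimming takes the prefix before the leftmost exact occurrence of
the adapter's first 8 nt; inserts shorter than 20 nt, or reads without a
match, are discarded. Mismatch-tolerant trimming is out of scope because
simulated adapters are exact. The quality rule "Phred < 20" is read as the
**mean** per-read Phred (a per-base minimum is available via
`quality_method = "min"`); the boundary is inclusive, mean ≥ 20 keeps.
Contaminant depletion removes a read iff it is an exact substring of a
contaminant sequence. Alignment is exact multi-pattern matching
(Aho–Corasick via Biostrings `PDict`) on the sense strand; only uniquely
matching reads are kept — multimappers are counted and dropped rather than
randomly placed, so all counts are deterministic. A minimal SAM
import/export (primary, forward-strand, indel-free records) provides
interoperability with external aligners.

Every read lands in exactly one ledger category
(`input = adapter_discarded + quality_discarded + contaminant + unaligned +
multimapped + length_excluded + kept`), and the pipeline refuses to
continue if conservation fails.

## P-site offset calibration

For each length $L$, the histogram of 5′ ends relative to the start
codon's first nucleotide is built over a window of −40…+20 nt (wide enough
to contain the initiating-ribosome peak for all calibratable lengths).
The offset is minus the modal position; ties break toward the smaller
offset. Lengths with fewer than `min_support` window reads (default 100)
are marked uncalibrated and their reads are skipped-and-counted downstream
rather than imputed from neighbouring lengths — silent imputation bias is
worse than visible data loss. An offset outside $[0, L]$ is treated as
uncalibrated as well. P-site assignment floors to the codon,
`(p − cds_start) %/% 3`, ignoring sub-codon phase: no frame-filtering rule
is imposed, and frame-aware refinement is out of scope.

## Metagene profiles

Two rules define the profile:

1. **Exclusion first.** Transcripts with no reads in the window of
   interest are excluded before any other filter.
2. **Per-position 0.1% trimming.** For each window position, values
   strictly above the nearest-rank $1-f$ quantile and strictly below the
   $f$ quantile ($f = 0.001$) are removed before averaging.

"Signal" is the per-transcript, window-mean-normalized count (raw-count
averaging available with `normalize = FALSE`): normalization makes
profiles depth-independent and so comparable across libraries. The
nearest-rank quantile (`stats::quantile(type = 1)`) with strict
inequalities gives reproducible integer semantics: for $n \ge 1/f$ it
removes the extreme ~0.1% of values, and for $n < 1/f$ the cuts are the
extremes themselves, so nothing is dropped and the trimmed mean degrades
to the plain mean. Default windows are −20…+100 codons around the start
and −100…+20 around the stop; both are configurable, as no windows are
prescribed by the data the defaults emulate.

## Pause scores and condition contrasts

Motif occurrences come from in-frame translation of each CDS, overlapping
matches included (`PPPP` contains two `PPP`s; an `SPPPVP` context contains
one `PPP`, one `SPP` and one `PPV`), with at least 5 flanking codons
required inside the CDS. The scalar pause score of an occurrence is

$$\text{score} = \frac{\text{mean count over the motif codons}}
                      {\text{mean count over flank codons}}$$

with the flank spanning codons 5–50 away on each side, minus codons
belonging to any other occurrence and minus the first/last 5 CDS codons
(initiation/termination ramps would contaminate the background). The
score averages all motif codons rather than electing a single registration
codon — whether the stall registers in the P- or A-site is left to the
per-offset motif metagene (−5…+7 codons), which exposes it for inspection.
Occurrences with background below 0.5 reads/codon are flagged unusable;
division by zero cannot occur. The aggregate is the **median** over usable
occurrences (robust to the heavy right tail of ratio statistics; the mean
is available behind a flag). These definitions make the score exactly 1 on
uniform coverage, scale-invariant, and — by parameter recovery — an
estimator of the planted multiplier $m$ within 15% at the depths below.

Two conditions are contrasted by the ratio of aggregate scores
(B over A) with a seeded percentile bootstrap over occurrences
(default 1000 replicates). A confidence interval containing 1 states "no
further increase" directly, which is the reading the no-go scenario
requires; no named test is invoked because none is defined for this
contrast. In the simulated GC7 analogue, condition B doubles the stall
($m: 4 \to 8$) while no-go decay removes motif-codon reads; at a drop
probability of 0.5 the read loss exactly offsets the doubling
($8 \times 0.5 = 4$), reproducing occupancy parity — the CI contains 1 —
while heavier decay (0.75) pushes observed occupancy *below* the untreated
library ($8 \times 0.25 = 2$), so its CI lies entirely under 1. Both
regimes are exercised in the tests; the parity calibration follows from
this arithmetic, not from fitting to any observed outcome.

## Spike-in normalization

Libraries spiked with a fixed amount of foreign material can be rescaled
by their spike-in read counts: library $i$ gets factor
$\text{spike}_i / \text{geomean}(\text{spike}_\cdot)$, so factors have
geometric mean 1 and no library is a designated reference. Species are
assigned by the `spike|` transcript-ID prefix. Normalization is **off by
default** in the pipeline: a spike-in also serves bench-side RNA
accounting, and whether footprint counts should be rescaled by it is an
analysis decision, so the factors are always reported but only applied on
request.

## Numerical and degenerate-input conventions

* Coordinates are 0-based, half-open, transcript-relative; CDS is
  `[cds_start, cds_end)`; codon $i$ spans nt `[cds_start + 3i,
  cds_start + 3i + 3)`.
* Offset ties break toward the smaller offset; modal positions are exact
  integer comparisons, no smoothing.
* Empty windows, all-excluded metagenes and zero-occurrence motif sets
  return flagged empty objects, never errors; zero spike-in counts and
  uncalibratable libraries are hard errors, because silent continuation
  would corrupt everything downstream.
* All randomness flows through a single integer seed per spec/run;
  identical config + seed reproduce byte-identical output tables.
* Simulated 5′ ends falling outside the transcript are resampled and the
  resample count is reported.
* Backgrounds of generated CDSes exclude every residue used by a planted
  motif, and planted blocks sit at least 6 codons apart, which makes the
  planted truth table provably exhaustive — the property the
  translate-and-scan oracle tests rely on.

## Problem sizes used in the validation suite

Parameter-recovery experiments run at 200 transcripts with 2×10⁵ reads
(offset recovery, start-peak recovery; seeds 1–10 and 1–5) and 5×10⁵ reads
(pause-multiplier recovery at $m \in \{2, 4, 8\}$, seeds 1–5; motif
metagenes; condition contrasts). Recovery runs use the simulator's
true-alignment table directly — the FASTQ → trim → deplete → align path is
separately verified as a bijection against truth at 10⁴ reads — and the
bundled toy configuration (5 transcripts, 2000 reads) exercises the full
pipeline end to end. At these scales offset recovery is exact for every
length with ≥ 500 window reads, and median pause scores sit within 15% of
the planted multiplier.

## A worked miniature

```{r example}
spec <- sim_spec(n_transcripts = 20, depth = 30000,
                 frac_contaminant = 0, frac_spikein = 0, frac_lowq = 0,
                 seed = 1)
tx  <- generate_transcriptome(spec)
lib <- simulate_library(tx)
pp  <- preprocess_reads(lib$reads, tx$sequences)
pp$ledger
off <- calibrate_offsets(pp$alignments, tx$annotation)
off[off$calibrated, ]
cov <- psite_coverage(pp$alignments, off, tx$annotation)
occ <- scan_motifs(tx$sequences,
                   tx$annotation[tx$annotation$species == "primary", ], "PPP")
sc  <- pause_scores(cov, occ)
attr(sc, "median_score")
```

## Known limitations

Real libraries bring mismatches, multimapping across paralogues, biased
fragment ends, uneven transcript abundance and incomplete annotations;
none of these is modelled, and exact-match alignment is a deliberate
substitute for (not a reimplementation of) a mismatch-tolerant aligner.
The no-go module models only the read-loss consequence of decay, not
mRNA half-lives. Offset calibration assumes a start-codon peak exists;
libraries without initiation enrichment (e.g. run-off conditions) will
calibrate poorly, and the support threshold then correctly refuses.
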