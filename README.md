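# ribopause

Post-alignment analysis of ribosome profiling (Ribo-seq) libraries, built
for the translation-control questions around eIF5A and polyproline
stalling: P-site offset calibration per read length, codon-resolution
occupancy, outlier-trimmed metagene profiles, tripeptide-motif pause
scoring with bootstrap condition contrasts, spike-in normalization — and a
footprint **simulator with a per-read truth table**, so that every
analysis step is validated by parameter recovery rather than by eye.

It is aimed at analysts who have (or simulate) ribosome-protected
fragments over a transcriptome with CDS annotation and want codon-level
answers to: *where are ribosomes enriched (start codon)? do they stall at
PPP/SPP/PPV motifs? does a treatment change that stalling — and could
no-go decay be hiding the change?*

## The statistics at the core

* **P-site offset.** For each read length *L* ∈ 26–35 nt, pool 5′-end
  positions relative to the start codon over all transcripts;
  *o(L) = −argmax* of that histogram (ties toward the smaller offset;
  lengths with < `min_support` window reads stay uncalibrated). A read's
  P-site codon is then `⌊(five_prime + o(L) − cds_start)/3⌋`.
* **Metagene profile.** Per transcript, window counts are normalized by
  the transcript's window mean; transcripts with zero reads in the window
  are excluded before any other filter; each position's column is averaged
  after removing the highest and lowest 0.1% of signals (nearest-rank
  quantiles, strict cuts — a no-op when *n* < 1/f).
* **Pause score.** For a motif occurrence,
  `score = mean(motif codons) / mean(flank codons 5–50 away)`, flanks
  purged of other occurrences and CDS edges; aggregate = median over
  usable occurrences; conditions compared as a B:A ratio with a seeded
  percentile bootstrap.
* **Spike-in factors.** `factor_i = spike_i / geomean(spike)`, geometric
  mean 1 across libraries, applied on request.

## A worked example

```r
library(ribopause)

spec <- sim_spec(n_transcripts = 20, depth = 30000,
                 frac_contaminant = 0, frac_spikein = 0, frac_lowq = 0,
                 seed = 1)
tx  <- generate_transcriptome(spec)   # planted PPP motifs + truth table
lib <- simulate_library(tx)           # FASTQ-style reads, adapter appended
pp  <- preprocess_reads(lib$reads, tx$sequences)
pp$ledger
#>    input adapter_discarded quality_discarded contaminant unaligned
#> 1: 30000                 0                 0           0         0
#>    multimapped length_excluded  kept
#>              0               0 30000

off <- calibrate_offsets(pp$alignments, tx$annotation)
off[off$calibrated, ]
#>    length offset support sharpness calibrated
#> 1:     27     11     402 0.3507463       TRUE
#> 2:     28     12     741 0.3265857       TRUE
#> 3:     29     13     772 0.2940415       TRUE
#> 4:     30     13     449 0.3496659       TRUE

cov  <- psite_coverage(pp$alignments, off, tx$annotation)
prof <- metagene_profile(cov, "start")
prof[prof$position %in% 0:2, ]
#>    position      mean     n
#> 1:        0 4.4638787    20
#> 2:        1 0.8779990    20
#> 3:        2 0.8199016    20

occ <- scan_motifs(tx$sequences,
                   tx$annotation[tx$annotation$species == "primary", ], "PPP")
sc  <- pause_scores(cov, occ)
attr(sc, "median_score")
#> [1] 3.897234
```

Reading the numbers: every simulated read survives the filter ledger
(error-free reads, no contaminant/low-quality classes in this spec); the
calibrated offsets 11/12/13/13 nt for 27–30-mers are exactly the planted
ones (only lengths with enough start-window reads calibrate at this
depth); the start-codon metagene peaks at 4.46 at codon 0 — the planted
5-fold initiation enrichment, read through window-mean normalization — and
the median PPP pause score 3.90 recovers the planted pause multiplier 4.

`run_pipeline(run_config(...))` chains all of the above and writes TSV
tables plus a JSON run report; `inst/cli/ribopause.R` wraps it for shell
use with a YAML config. A full account of the model, parameter choices
and validation design is in `vignettes/ribopause-methods.Rmd`.

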