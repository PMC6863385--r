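#' Default read-length weights for simulated footprints
#'
#' Categorical distribution over read lengths 26--35 nt with most of the mass
#' on 27--30 nt, the gel-purified size range of ribosome-protected fragments.
#'
#' @return Named numeric vector summing to 1; names are lengths in nt.
#' @export
default_length_weights <- function() {
  c(`26` = 0.02, `27` = 0.16, `28` = 0.30, `29` = 0.26, `30` = 0.16,
    `31` = 0.03, `32` = 0.02, `33` = 0.02, `34` = 0.02, `35` = 0.01)
}

#' Default planted 5'-end-to-P-site offsets
#'
#' Canonical elongating-ribosome geometry: about 12 nt for a 28-mer, growing
#' by roughly 1 nt per 2 nt of read length.
#'
#' @return Named integer vector, names are read lengths 26--35.
#' @export
default_offset_map <- function() {
  c(`26` = 11L, `27` = 11L, `28` = 12L, `29` = 13L, `30` = 13L,
    `31` = 13L, `32` = 14L, `33` = 14L, `34` = 15L, `35` = 15L)
}

#' Specification of a synthetic ribosome-profiling experiment
#'
#' Collects every knob of the footprint simulator: transcript architecture,
#' planted tripeptide motifs, start-codon enrichment, motif pause multiplier,
#' per-length P-site offsets, library composition (adapter, low-quality,
#' contaminant and spike-in fractions) and the optional no-go-decay read loss
#' at motif codons.
#'
#' @param n_transcripts Number of primary-species transcripts.
#' @param utr5_len,cds_codons,utr3_len Integer length-2 vectors `c(min, max)`;
#'   UTR lengths in nt, CDS length in codons (including start and stop),
#'   each drawn uniformly per transcript.
#' @param planted_motifs Named integer vector: names are peptide motifs
#'   (e.g. `"PPP"`, `"SPP"`, `"SPPPVP"`), values the number of occurrences
#'   planted per transcript.
#' @param base_density Nominal mean footprints per CDS codon (lambda > 0);
#'   sets the default `depth` when `depth` is `NULL`.
#' @param start_enrichment Sampling weight multiplier at the start codon
#'   (s >= 1).
#' @param pause_multiplier Sampling weight multiplier at planted motif codons
#'   (m >= 1).
#' @param offset_map Named integer vector, read length -> planted 5'-end to
#'   P-site offset o(L); names must be exactly the support of
#'   `length_weights`.
#' @param length_weights Named numeric vector over read lengths, summing to 1.
#' @param depth Total reads in the library (all classes). `NULL` means
#'   `round(base_density * total CDS codons)`.
#' @param adapter 3' adapter appended in full to every read.
#' @param frac_lowq,frac_contaminant,frac_spikein Fractions in \[0, 1\] of
#'   `depth` emitted as low-quality (Phred 10), rRNA-like contaminant, and
#'   yeast-spike-in reads. The spike-in default 1/6 follows a 20:4 RNA mass
#'   ratio of primary to spike material.
#' @param nogo_drop Probability that a footprint whose P-site falls in a
#'   planted motif codon is discarded before output, emulating read loss by
#'   no-go decay at strong stalls.
#' @param n_spike_transcripts Number of spike-in (yeast-like) transcripts.
#' @param seed Integer seed; all outputs are deterministic given the spec.
#'
#' @return An object of class `sim_spec` (validated list).
#' @seealso [generate_transcriptome()], [simulate_library()]
#' @export
sim_spec <- function(n_transcripts = 50L,
                     utr5_len = c(30L, 60L),
                     cds_codons = c(100L, 200L),
                     utr3_len = c(60L, 120L),
                     planted_motifs = c(PPP = 1L),
                     base_density = 2,
                     start_enrichment = 5,
                     pause_multiplier = 4,
                     offset_map = default_offset_map(),
                     length_weights = default_length_weights(),
                     depth = NULL,
                     adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                     frac_lowq = 0.02,
                     frac_contaminant = 0.05,
                     frac_spikein = 1 / 6,
                     nogo_drop = 0,
                     n_spike_transcripts = 20L,
                     seed = 1L) {
  spec <- structure(list(
    n_transcripts = as.integer(n_transcripts),
    utr5_len = as.integer(utr5_len), cds_codons = as.integer(cds_codons),
    utr3_len = as.integer(utr3_len),
    planted_motifs = planted_motifs,
    base_density = base_density,
    start_enrichment = start_enrichment,
    pause_multiplier = pause_multiplier,
    offset_map = offset_map, length_weights = length_weights,
    depth = if (is.null(depth)) NULL else as.integer(depth),
    adapter = adapter,
    frac_lowq = frac_lowq, frac_contaminant = frac_contaminant,
    frac_spikein = frac_spikein, nogo_drop = nogo_drop,
    n_spike_transcripts = as.integer(n_spike_transcripts),
    seed = as.integer(seed)
  ), class = "sim_spec")
  validate_sim_spec(spec)
}

#' @rdname sim_spec
#' @param spec A `sim_spec` object.
#' @export
validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with(spec, {
    if (n_transcripts < 1L) stopf("n_transcripts must be >= 1")
    for (nm in c("utr5_len", "cds_codons", "utr3_len")) {
      r <- spec[[nm]]
      if (length(r) != 2L || r[1] > r[2] || r[1] < 0L)
        stopf("%s must be c(min, max) with 0 <= min <= max", nm)
    }
    if (base_density <= 0) stopf("base_density (lambda) must be > 0")
    if (start_enrichment < 1) stopf("start_enrichment must be >= 1")
    if (pause_multiplier < 1) stopf("pause_multiplier must be >= 1")
    if (abs(sum(length_weights) - 1) > 1e-8)
      stopf("length_weights must sum to 1 (got %g)", sum(length_weights))
    if (any(length_weights < 0)) stopf("length_weights must be >= 0")
    supp <- names(length_weights)[length_weights > 0]
    if (!setequal(names(offset_map), names(length_weights)) &&
        !setequal(names(offset_map), supp))
      stopf("offset_map keys must be the support of length_weights")
    if (!all(supp %in% names(offset_map)))
      stopf("offset_map is missing lengths: %s",
            paste(setdiff(supp, names(offset_map)), collapse = ", "))
    L <- as.integer(names(offset_map))
    if (any(offset_map < 0L) || any(offset_map > L))
      stopf("offsets must satisfy 0 <= o(L) <= L")
    for (nm in c("frac_lowq", "frac_contaminant", "frac_spikein", "nogo_drop")) {
      f <- spec[[nm]]
      if (f < 0 || f > 1) stopf("%s must be in [0, 1]", nm)
    }
    if (frac_lowq + frac_contaminant + frac_spikein > 1)
      stopf("class fractions sum to > 1")
    if (!nzchar(adapter)) stopf("adapter must be non-empty")
    if (!is.null(planted_motifs) && length(planted_motifs)) {
      if (is.null(names(planted_motifs)) || any(!nzchar(names(planted_motifs))))
        stopf("planted_motifs must be a named vector (motif -> count)")
      if (any(planted_motifs < 0)) stopf("motif counts must be >= 0")
    }
  })
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("sim_spec:", x$n_transcripts, "transcripts (+",
      x$n_spike_transcripts, "spike-in), CDS",
      paste(x$cds_codons, collapse = "-"), "codons\n")
  cat("  motifs:", paste(sprintf("%s x%d", names(x$planted_motifs),
                                 x$planted_motifs), collapse = ", "), "\n")
  cat(sprintf("  s = %g (start), m = %g (motif), nogo_drop = %g\n",
              x$start_enrichment, x$pause_multiplier, x$nogo_drop))
  cat(sprintf("  fractions: lowq %g, contaminant %g, spikein %g; seed %d\n",
              x$frac_lowq, x$frac_contaminant, x$frac_spikein, x$seed))
  invisible(x)
}
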