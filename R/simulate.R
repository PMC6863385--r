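#' Simulate a ribosome-footprint FASTQ library with per-read truth
#'
#' Draws footprint P-sites codon-wise with sampling weight proportional to
#' `base_density * start_enrichment` at the start codon and
#' `base_density * pause_multiplier` at planted motif codons, converts each
#' P-site to a 5' end via the planted per-length offset, and emits reads as
#' fragment + full adapter with Phred 40 qualities (Phred 10 for the
#' low-quality class). Spike-in reads are drawn flat over spike-transcript
#' CDS codons; contaminant reads are substrings of the bundled synthetic
#' rRNA-like sequences. With probability `nogo_drop` a footprint whose
#' P-site lies in a motif codon is discarded before output (no-go-decay
#' read loss), so the emitted library can under-report strong stalls.
#'
#' @param txome A `sim_transcriptome` from [generate_transcriptome()].
#' @param spec A [sim_spec()]; defaults to the one stored in `txome`.
#' @param emit `"reads"` to materialise read sequences and qualities,
#'   `"truth"` to produce only the per-read truth table (faster; used for
#'   large parameter-recovery runs).
#' @return Object of class `sim_library`: list with `reads` (data.table
#'   read_id/seq/qual, or NULL under `emit = "truth"`), `truth` (data.table
#'   read_id, class in footprint/lowq/spikein/contaminant, transcript_id,
#'   psite_codon, five_prime, length), `n_resampled` (reads redrawn because
#'   their 5' end fell outside the transcript), `n_nogo_dropped`, and the
#'   `spec`.
#' @examples
#' tx <- generate_transcriptome(sim_spec(n_transcripts = 3, depth = 500, seed = 7))
#' lib <- simulate_library(tx)
#' table(lib$truth$class)
#' @export
simulate_library <- function(txome, spec = txome$spec,
                             emit = c("reads", "truth")) {
  stopifnot(inherits(txome, "sim_transcriptome"))
  emit <- match.arg(emit)
  validate_sim_spec(spec)
  set.seed(derive_seed(spec$seed, 2L))

  ann <- txome$annotation
  prim <- ann[species == "primary"]
  spk <- ann[species == "spike"]
  depth <- spec$depth
  if (is.null(depth)) {
    total_codons <- prim[, sum((cds_end - cds_start) %/% 3L)]
    depth <- as.integer(round(spec$base_density * total_codons))
  }
  n_contam <- as.integer(round(spec$frac_contaminant * depth))
  n_spike <- as.integer(round(spec$frac_spikein * depth))
  n_lowq <- as.integer(round(spec$frac_lowq * depth))
  n_fp <- depth - n_contam - n_spike - n_lowq
  if (n_fp < 0L) stopf("class fractions leave no footprint reads")
  if (n_spike > 0L && nrow(spk) == 0L)
    stopf("frac_spikein > 0 but no spike-in transcripts")

  lw <- spec$length_weights
  lens_avail <- as.integer(names(lw))
  omap <- spec$offset_map

  # --- footprint-like reads (true footprints + low-quality class) ---------
  fp <- sample_footprints(prim, txome$motifs, spec, n_fp + n_lowq,
                          lens_avail, lw, omap)
  n_resampled <- fp$n_resampled
  # no-go decay: drop motif-codon reads before output
  n_nogo <- 0L
  if (spec$nogo_drop > 0 && nrow(fp$tab)) {
    drop <- fp$tab$is_motif & runif(nrow(fp$tab)) < spec$nogo_drop
    n_nogo <- sum(drop)
    fp$tab <- fp$tab[!drop]
  }
  fp$tab[, class := "footprint"]
  if (n_lowq > 0L && nrow(fp$tab)) {
    ix <- sample.int(nrow(fp$tab), min(n_lowq, nrow(fp$tab)))
    fp$tab[ix, class := "lowq"]
  }

  # --- spike-in reads: flat over spike CDS codons -------------------------
  if (n_spike > 0L) {
    sp <- sample_footprints(spk, txome$motifs[0], spec, n_spike,
                            lens_avail, lw, omap, flat = TRUE)
    n_resampled <- n_resampled + sp$n_resampled
    sp$tab[, class := "spikein"]
    truth <- rbind(fp$tab, sp$tab)
  } else truth <- fp$tab

  # --- contaminant reads --------------------------------------------------
  contam_tab <- NULL
  contam_seq <- NULL
  if (n_contam > 0L) {
    cont <- contaminant_sequences()
    ci <- sample.int(length(cont), n_contam, replace = TRUE)
    cl <- lens_avail[sample.int(length(lens_avail), n_contam,
                                replace = TRUE, prob = lw)]
    cw <- Biostrings::width(cont)[ci]
    if (any(cl > cw)) stopf("contaminant sequences shorter than read length")
    cs <- floor(runif(n_contam) * (cw - cl + 1))
    contam_tab <- data.table(
      transcript_id = NA_character_, psite_codon = NA_integer_,
      five_prime = NA_integer_, length = cl, is_motif = FALSE,
      class = "contaminant"
    )
    if (emit == "reads") {
      cchr <- as.character(cont)
      contam_seq <- substring(cchr[ci], cs + 1, cs + cl)
    }
  }

  truth[, is_motif := NULL]
  if (!is.null(contam_tab)) {
    n_real <- nrow(truth)
    contam_tab[, is_motif := NULL]
    all_tab <- rbind(truth, contam_tab)
  } else {
    n_real <- nrow(truth)
    all_tab <- truth
  }

  # shuffle read order, assign ids
  n_all <- nrow(all_tab)
  perm <- sample.int(n_all)
  reads <- NULL
  if (emit == "reads") {
    txchr <- as.character(txome$sequences)
    sq <- character(n_all)
    ix_real <- seq_len(n_real)
    sq[ix_real] <- substring(txchr[all_tab$transcript_id[ix_real]],
                             all_tab$five_prime[ix_real] + 1,
                             all_tab$five_prime[ix_real] + all_tab$length[ix_real])
    if (!is.null(contam_seq)) sq[(n_real + 1):n_all] <- contam_seq
    sq <- paste0(sq, spec$adapter)
    qual <- strrep(ifelse(all_tab$class == "lowq", "+", "I"), nchar(sq))
    reads <- data.table(seq = sq, qual = qual)[perm]
  }
  all_tab <- all_tab[perm]
  all_tab[, read_id := sprintf("r%07d", .I)]
  setcolorder(all_tab, c("read_id", "class", "transcript_id", "psite_codon",
                         "five_prime", "length"))
  if (!is.null(reads)) {
    reads[, read_id := all_tab$read_id]
    setcolorder(reads, c("read_id", "seq", "qual"))
  }

  structure(list(reads = reads, truth = all_tab,
                 n_resampled = n_resampled, n_nogo_dropped = n_nogo,
                 spec = spec),
            class = "sim_library")
}

# draw n footprint-like reads over the CDS codons of `ann` transcripts.
# flat = TRUE ignores start/motif weighting (spike-in pool).
sample_footprints <- function(ann, motifs, spec, n, lens_avail, lw, omap,
                              flat = FALSE) {
  if (n == 0L)
    return(list(tab = data.table(transcript_id = character(),
                                 psite_codon = integer(),
                                 five_prime = integer(), length = integer(),
                                 is_motif = logical()),
                n_resampled = 0L))
  ncod <- (ann$cds_end - ann$cds_start) %/% 3L
  tx_of <- rep.int(seq_len(nrow(ann)), ncod)
  codon_of <- sequence(ncod) - 1L
  w <- rep.int(1, sum(ncod))
  is_motif <- logical(sum(ncod))
  if (!flat) {
    w[codon_of == 0L] <- spec$start_enrichment
    if (nrow(motifs)) {
      first <- cumsum(c(0L, head(ncod, -1L)))  # global index of codon 0 per tx
      names(first) <- ann$transcript_id
      for (r in seq_len(nrow(motifs))) {
        tid <- motifs$transcript_id[r]
        if (!tid %in% names(first)) next
        span <- motifs$codon_index[r] + seq_len(nchar(motifs$motif[r])) - 1L
        gi <- first[[tid]] + span + 1L
        w[gi] <- spec$pause_multiplier
        is_motif[gi] <- TRUE
      }
    }
  }
  tx_len <- ann$length
  cds_start <- ann$cds_start

  draw <- function(k) {
    gi <- sample.int(length(w), k, replace = TRUE, prob = w)
    L <- lens_avail[sample.int(length(lens_avail), k, replace = TRUE,
                               prob = lw)]
    o <- unname(omap[as.character(L)])
    fp <- cds_start[tx_of[gi]] + 3L * codon_of[gi] - o
    list(gi = gi, L = L, fp = fp,
         bad = fp < 0L | fp + L > tx_len[tx_of[gi]])
  }
  d <- draw(n)
  n_resampled <- 0L
  while (any(d$bad)) {
    ix <- which(d$bad)
    n_resampled <- n_resampled + length(ix)
    r <- draw(length(ix))
    d$gi[ix] <- r$gi; d$L[ix] <- r$L; d$fp[ix] <- r$fp
    d$bad[ix] <- r$bad
  }
  list(tab = data.table(
    transcript_id = ann$transcript_id[tx_of[d$gi]],
    psite_codon = codon_of[d$gi],
    five_prime = d$fp,
    length = d$L,
    is_motif = is_motif[d$gi]
  ), n_resampled = n_resampled)
}

#' Bundled synthetic rRNA-like contaminant sequences
#'
#' Three randomly generated, GC-rich sequences standing in for rRNA
#' contamination. They are synthetic: no homology to any real rRNA is
#' implied; their only role is to be an exact-match depletion target.
#'
#' @return A [Biostrings::DNAStringSet].
#' @export
contaminant_sequences <- function() {
  fa <- system.file("extdata", "contaminants_synthetic_rrna.fa",
                    package = "ribopause", mustWork = TRUE)
  Biostrings::readDNAStringSet(fa)
}

#' Extract the true alignment table of a simulated library
#'
#' The simulator knows where every non-contaminant read came from; this
#' returns those placements in the same shape [align_to_transcriptome()]
#' produces, for truth-based parameter-recovery runs and oracle tests.
#'
#' @param lib A `sim_library`.
#' @param classes Read classes to include.
#' @return data.table: read_id, transcript_id, five_prime, length.
#' @export
true_alignments <- function(lib, classes = c("footprint", "spikein")) {
  stopifnot(inherits(lib, "sim_library"))
  out <- lib$truth[class %in% classes,
                   .(read_id, transcript_id, five_prime, length)]
  out[]
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param reads data.table with read_id, seq, qual (e.g. `lib$reads`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (Phred+33).
#' @return data.table: read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.table(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)))
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", nrow(x$truth), "reads\n")
  print(x$truth[, .N, by = class])
  cat("resampled:", x$n_resampled, " no-go dropped:", x$n_nogo_dropped, "\n")
  invisible(x)
}
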