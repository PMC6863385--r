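#' Generate a synthetic transcriptome with planted tripeptide motifs
#'
#' Builds `n_transcripts` primary transcripts (UTR5 + CDS + UTR3, CDS opening
#' with ATG and closing with a stop codon) plus `n_spike_transcripts`
#' spike-in transcripts whose IDs carry the `spike|` prefix, mirroring a
#' concatenated two-species reference. Each primary CDS carries the planted
#' peptide motifs at recorded codon indices. Background residues exclude
#' every amino acid that appears in a planted motif and planted blocks are
#' spaced at least 6 codons apart, so the recorded occurrences are provably
#' the only occurrences — the truth table is exhaustive.
#'
#' @param spec A [sim_spec()].
#' @return An object of class `sim_transcriptome`: list with
#'   `sequences` (named [Biostrings::DNAStringSet]), `annotation`
#'   (data.table: transcript_id, length, cds_start, cds_end, species;
#'   coordinates 0-based half-open), `motifs` (data.table: transcript_id,
#'   motif, codon_index of the first residue, 0-based), and the `spec`.
#' @examples
#' tx <- generate_transcriptome(sim_spec(n_transcripts = 3, seed = 42))
#' tx$motifs
#' @export
generate_transcriptome <- function(spec) {
  validate_sim_spec(spec)
  set.seed(spec$seed)
  ct <- codons_by_aa()

  motif_res <- unique(unlist(strsplit(names(spec$planted_motifs), "")))
  background <- setdiff(setdiff(names(ct), "*"), motif_res)
  if (length(background) < 4L)
    stopf("planted motifs use too many residues; <4 background amino acids left")
  stop_codons <- ct[["*"]]

  min_cds <- minimum_cds_codons(spec$planted_motifs)
  if (spec$cds_codons[1] < min_cds)
    stopf("rejected spec: cds_codons min %d < %d required for motifs + flanks",
          spec$cds_codons[1], min_cds)

  n <- spec$n_transcripts
  ids <- sprintf("tx%04d", seq_len(n))
  u5 <- runif_int(n, spec$utr5_len[1], spec$utr5_len[2])
  nc <- runif_int(n, spec$cds_codons[1], spec$cds_codons[2])
  u3 <- runif_int(n, spec$utr3_len[1], spec$utr3_len[2])

  seqs <- character(n)
  motif_rows <- vector("list", n)
  for (i in seq_len(n)) {
    built <- build_cds(nc[i], spec$planted_motifs, background, ct, stop_codons)
    seqs[i] <- paste0(random_nt(u5[i]), built$cds, random_nt(u3[i]))
    if (nrow(built$motifs))
      motif_rows[[i]] <- data.table(transcript_id = ids[i], built$motifs)
  }
  ann <- data.table(
    transcript_id = ids,
    length = u5 + 3L * nc + u3,
    cds_start = u5,
    cds_end = u5 + 3L * nc,
    species = "primary"
  )

  # spike-in transcripts: same architecture, no planted motifs
  if (spec$n_spike_transcripts > 0L) {
    m <- spec$n_spike_transcripts
    sids <- sprintf("spike|sy%03d", seq_len(m))
    s5 <- runif_int(m, spec$utr5_len[1], spec$utr5_len[2])
    sc <- runif_int(m, spec$cds_codons[1], spec$cds_codons[2])
    s3 <- runif_int(m, spec$utr3_len[1], spec$utr3_len[2])
    sseq <- character(m)
    for (i in seq_len(m)) {
      built <- build_cds(sc[i], setNames(integer(0), character(0)),
                         background, ct, stop_codons)
      sseq[i] <- paste0(random_nt(s5[i]), built$cds, random_nt(s3[i]))
    }
    ann <- rbind(ann, data.table(
      transcript_id = sids, length = s5 + 3L * sc + s3,
      cds_start = s5, cds_end = s5 + 3L * sc, species = "spike"
    ))
    seqs <- c(seqs, sseq)
    ids <- c(ids, sids)
  }

  structure(list(
    sequences = Biostrings::DNAStringSet(setNames(seqs, ids)),
    annotation = ann,
    motifs = if (length(motif_rows)) rbindlist(motif_rows) else
      data.table(transcript_id = character(), motif = character(),
                 codon_index = integer()),
    spec = spec
  ), class = "sim_transcriptome")
}

# smallest CDS (codons, incl. start+stop) able to host all planted motifs
# with 5-codon flanks and 6-codon spacing between blocks
minimum_cds_codons <- function(planted_motifs) {
  if (!length(planted_motifs)) return(10L)
  lens <- nchar(names(planted_motifs))
  k <- sum(planted_motifs)
  # start(1) + lead flank(6) + blocks + gaps(6 each) + tail flank(6) + stop
  as.integer(2L + 6L + sum(rep(lens, planted_motifs)) + 6L * (k - 1L) + 6L)
}

random_nt <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# build one CDS of n_codons codons: ATG + residues + stop; plant motifs
build_cds <- function(n_codons, planted_motifs, background, ct, stop_codons) {
  n_aa <- n_codons - 2L  # residues between start M and stop
  residues <- sample(background, n_aa, replace = TRUE)

  placements <- data.table(motif = character(), codon_index = integer())
  if (length(planted_motifs) && sum(planted_motifs) > 0) {
    want <- rep(names(planted_motifs), planted_motifs)
    want <- want[sample.int(length(want))]  # randomise placement order
    max_len <- max(nchar(want))
    # candidate start codons (0-based codon index incl. start codon 0):
    # >= 6 after start, motif + 5 flank codons before the stop codon
    hi <- n_codons - max_len - 6L
    if (hi < 6L)
      stopf("rejected spec: CDS of %d codons too short for motif placement",
            n_codons)
    pool <- seq.int(6L, hi)
    for (mot in want) {
      len <- nchar(mot)
      ok <- pool[pool + len + 5L <= n_codons - 1L]
      if (!length(ok))
        stopf("rejected spec: CDS of %d codons too short for motif placement",
              n_codons)
      c0 <- ok[sample.int(length(ok), 1L)]
      placements <- rbind(placements,
                          data.table(motif = mot, codon_index = c0))
      drop <- pool >= c0 - (max_len + 5L) & pool <= c0 + len + 5L
      pool <- pool[!drop]
      # overwrite residues: codon_index c corresponds to residues[c]
      substr_idx <- seq.int(c0, c0 + len - 1L)
      residues[substr_idx] <- strsplit(mot, "")[[1]]
    }
  }
  codons <- sample_codons(residues, ct)
  cds <- paste0("ATG", paste(codons, collapse = ""),
                stop_codons[sample.int(length(stop_codons), 1L)])
  setorder(placements, codon_index)
  list(cds = cds, motifs = placements)
}

#' Write a simulated transcriptome to disk
#'
#' @param txome A `sim_transcriptome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: FASTA, annotation TSV
#'   (transcript_id, length, cds_start, cds_end, species) and motif truth TSV.
#' @export
write_transcriptome <- function(txome, dir) {
  stopifnot(inherits(txome, "sim_transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcriptome.fa")
  Biostrings::writeXStringSet(txome$sequences, fa)
  ann <- file.path(dir, "annotation.tsv")
  fwrite(txome$annotation, ann, sep = "\t")
  mot <- file.path(dir, "motif_truth.tsv")
  fwrite(txome$motifs, mot, sep = "\t")
  invisible(c(fasta = fa, annotation = ann, motifs = mot))
}

#' Read a transcriptome FASTA and CDS annotation from disk
#'
#' @param fasta Path to a transcriptome FASTA.
#' @param annotation Path to a tab-separated annotation with columns
#'   transcript_id, cds_start, cds_end (0-based half-open) and optionally
#'   species; transcript length is taken from the FASTA.
#' @return A list with `sequences` (DNAStringSet) and `annotation`
#'   (data.table), shaped like the fields of a `sim_transcriptome`.
#' @export
read_transcriptome <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate transcript IDs in FASTA: %s",
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  ann <- fread(annotation)
  req <- c("transcript_id", "cds_start", "cds_end")
  if (!all(req %in% names(ann)))
    stopf("annotation must have columns %s", paste(req, collapse = ", "))
  if (!"species" %in% names(ann))
    ann[, species := ifelse(startsWith(transcript_id, "spike|"),
                            "spike", "primary")]
  ann[, length := Biostrings::width(seqs)[match(transcript_id, names(seqs))]]
  bad <- ann[cds_start < 0 | cds_end > length | cds_start >= cds_end |
               (cds_end - cds_start) %% 3L != 0L]
  if (nrow(bad))
    stopf("invalid CDS interval for: %s",
          paste(head(bad$transcript_id, 5), collapse = ", "))
  list(sequences = seqs, annotation = ann)
}
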