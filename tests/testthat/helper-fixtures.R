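# shared fixtures and independent oracles

# small simulated experiment used across tests
small_spec <- function(seed = 1L, ...) {
  sim_spec(n_transcripts = 20L, cds_codons = c(80L, 140L),
           depth = 20000L, seed = seed, ...)
}

# independent translation oracle (seqinr, not Biostrings)
oracle_translate <- function(nt) {
  paste(seqinr::translate(strsplit(tolower(nt), "")[[1]]), collapse = "")
}

# independent overlapping-motif scan: translate with seqinr, lookahead regex
oracle_scan <- function(nt_cds, motif) {
  aa <- oracle_translate(nt_cds)
  m <- gregexpr(paste0("(?=", motif, ")"), aa, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based codon index
}

# brute-force sort-and-slice trimmed mean (nearest-rank, strict cuts)
oracle_trimmed_mean <- function(values, f) {
  if (f == 0) return(mean(values))
  s <- sort(values)
  n <- length(s)
  lo <- s[max(1L, ceiling(f * n))]
  hi <- s[ceiling((1 - f) * n)]
  mean(s[s >= lo & s <= hi])
}

# naive double-loop metagene (no trimming), start-anchored, normalized
oracle_metagene_start <- function(counts_list, window) {
  pos <- seq.int(window[1], window[2])
  acc <- matrix(NA_real_, length(counts_list), length(pos))
  r <- 0L
  for (v in counts_list) {
    idx <- pos
    ok <- idx >= 0 & idx < length(v)
    row <- rep(NA_real_, length(pos))
    row[ok] <- v[idx[ok] + 1L]
    if (sum(row, na.rm = TRUE) == 0) next
    r <- r + 1L
    acc[r, ] <- row / mean(row, na.rm = TRUE)
  }
  acc <- acc[seq_len(r), , drop = FALSE]
  apply(acc, 2L, function(col) mean(col[!is.na(col)]))
}

# hand-built codon coverage object for arithmetic tests
make_coverage <- function(counts_list, cds_start = 0L) {
  ann <- data.table::data.table(
    transcript_id = names(counts_list),
    length = cds_start + 3L * lengths(counts_list),
    cds_start = cds_start,
    cds_end = cds_start + 3L * lengths(counts_list),
    species = "primary"
  )
  structure(list(counts = counts_list,
                 out_of_cds = setNames(integer(length(counts_list)),
                                       names(counts_list)),
                 skipped = 0L,
                 assigned = sum(unlist(lapply(counts_list, sum))),
                 annotation = ann),
            class = "codon_coverage")
}

# coverage built straight from a simulated library's truth table
truth_coverage <- function(lib, txome) {
  al <- true_alignments(lib)
  offs <- data.table::data.table(
    length = as.integer(names(txome$spec$offset_map)),
    offset = as.integer(txome$spec$offset_map),
    support = 1000L, sharpness = 1, calibrated = TRUE)
  data.table::setattr(offs, "class", c("psite_offsets", class(offs)))
  psite_coverage(al, offs, txome$annotation)
}
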