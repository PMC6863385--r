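#' Trim the 3' adapter from reads
#'
#' The insert is the prefix before the leftmost exact occurrence of the
#' adapter's first `seed_len` nucleotides; qualities are trimmed in step.
#' Reads with no adapter match, or whose insert is shorter than
#' `min_insert` nt, are discarded (the shortest calibratable footprint is
#' well above 20 nt). Empty reads get their own discard code.
#'
#' @param reads data.table with read_id, seq, qual (see [read_fastq()]).
#' @param adapter Adapter sequence (non-empty).
#' @param seed_len Length of the exact-match adapter seed (default 8 nt).
#' @param min_insert Minimum insert length kept after trimming.
#' @return List: `kept` (trimmed read table, input order preserved) and
#'   `discarded` (data.table read_id, reason in
#'   empty/no_adapter/too_short).
#' @export
trim_adapter <- function(reads, adapter, seed_len = 8L, min_insert = 20L) {
  if (!nzchar(adapter)) stopf("adapter must be non-empty")
  seed <- substr(adapter, 1L, min(seed_len, nchar(adapter)))
  pos <- regexpr(seed, reads$seq, fixed = TRUE)
  insert_len <- ifelse(pos > 0L, pos - 1L, -1L)
  empty <- !nzchar(reads$seq)
  reason <- rep(NA_character_, nrow(reads))
  reason[insert_len < 0L] <- "no_adapter"
  reason[insert_len >= 0L & insert_len < min_insert] <- "too_short"
  reason[empty] <- "empty"
  keep <- is.na(reason)
  kept <- reads[keep]
  il <- insert_len[keep]
  kept[, `:=`(seq = substr(seq, 1L, il), qual = substr(qual, 1L, il))]
  list(kept = kept,
       discarded = data.table(read_id = reads$read_id[!keep],
                              reason = reason[!keep]))
}

#' Filter reads on Phred quality
#'
#' Keeps a read iff its mean per-base Phred score is at least
#' `min_mean_phred` (default 20, the conventional low-quality cutoff).
#' `method = "min"` instead requires every base to reach the threshold.
#'
#' @param reads Trimmed read table.
#' @param min_mean_phred Threshold in Phred units.
#' @param method `"mean"` (default) or `"min"` per-base criterion.
#' @return List: `kept` and `discarded` read tables (input order).
#' @export
quality_filter <- function(reads, min_mean_phred = 20, method = c("mean", "min")) {
  method <- match.arg(method)
  stat <- switch(method,
    mean = mean_phred(reads$qual),
    min = vapply(reads$qual, function(q)
      if (nzchar(q)) min(utf8ToInt(q)) - 33 else NA_real_,
      numeric(1), USE.NAMES = FALSE))
  keep <- !is.na(stat) & stat >= min_mean_phred
  list(kept = reads[keep], discarded = reads[!keep])
}

#' Deplete contaminant reads
#'
#' A read is removed iff its sequence occurs as an exact substring of any
#' contaminant sequence (the exact-match analogue of discarding reads that
#' align to an rRNA reference). Survivors are unchanged and keep their
#' input order.
#'
#' @param reads Read table.
#' @param contaminants [Biostrings::DNAStringSet] of contaminant sequences;
#'   empty set passes everything through with a warning.
#' @return List: `kept`, `removed` (read tables).
#' @export
deplete_contaminants <- function(reads, contaminants) {
  if (length(contaminants) == 0L) {
    warning("empty contaminant set: pass-through")
    return(list(kept = reads, removed = reads[0]))
  }
  n <- nrow(reads)
  hit <- logical(n)
  clean <- !grepl("[^ACGT]", reads$seq)
  dt <- data.table(i = which(clean), seq = reads$seq[clean])
  dt[, w := nchar(seq)]
  for (wd in unique(dt$w)) {
    sub <- dt[w == wd]
    us <- unique(sub$seq)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(us))
    cnt <- rowSums(Biostrings::vcountPDict(pd, contaminants))
    matched <- us[cnt > 0L]
    if (length(matched)) hit[sub$i[sub$seq %in% matched]] <- TRUE
  }
  list(kept = reads[!hit], removed = reads[hit])
}

#' Align reads to a transcriptome by unique exact match
#'
#' Aho-Corasick multi-pattern exact matching (Biostrings `PDict`) on the
#' sense strand: a read with exactly one occurrence across all transcripts
#' yields one alignment record; zero occurrences counts as unaligned; two
#' or more (across or within transcripts) counts as multimapped and is
#' dropped. Output order follows input read order.
#'
#' @param reads Trimmed, filtered read table.
#' @param transcripts Named [Biostrings::DNAStringSet]; duplicate names are
#'   a hard error.
#' @return List: `alignments` (data.table read_id, transcript_id,
#'   five_prime \[0-based\], length), `unaligned`, `multimapped` (counts).
#' @export
align_to_transcriptome <- function(reads, transcripts) {
  if (anyDuplicated(names(transcripts)))
    stopf("duplicate transcript IDs: %s",
          paste(unique(names(transcripts)[duplicated(names(transcripts))]),
                collapse = ", "))
  n <- nrow(reads)
  useq <- unique(reads$seq)
  nhit <- setNames(integer(length(useq)), useq)
  hit_tx <- setNames(character(length(useq)), useq)
  hit_pos <- setNames(integer(length(useq)), useq)
  clean <- !grepl("[^ACGT]", useq) & nzchar(useq)
  by_w <- split(useq[clean], nchar(useq[clean]))
  for (grp in by_w) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(grp))
    for (j in seq_along(transcripts)) {
      m <- Biostrings::matchPDict(pd, transcripts[[j]])
      starts <- Biostrings::startIndex(m)
      k <- elementNROWS(starts)
      nz <- which(k > 0L)
      if (!length(nz)) next
      sq <- grp[nz]
      first_time <- nhit[sq] == 0L
      hit_tx[sq[first_time]] <- names(transcripts)[j]
      hit_pos[sq[first_time]] <- vapply(starts[nz[first_time]], `[`,
                                        integer(1), 1L) - 1L
      nhit[sq] <- nhit[sq] + k[nz]
    }
  }
  status <- nhit[reads$seq]
  aligned <- !is.na(status) & status == 1L
  multi <- !is.na(status) & status > 1L
  alignments <- data.table(
    read_id = reads$read_id[aligned],
    transcript_id = unname(hit_tx[reads$seq[aligned]]),
    five_prime = unname(hit_pos[reads$seq[aligned]]),
    length = nchar(reads$seq[aligned])
  )
  list(alignments = alignments,
       unaligned = sum(!aligned & !multi),
       multimapped = sum(multi))
}

#' Filter alignments on footprint length
#'
#' @param alignments Alignment table.
#' @param min_len,max_len Closed allowed range, default 26--35 nt (the
#'   calibratable footprint range).
#' @return List: `kept` alignments, `excluded` count.
#' @export
length_filter <- function(alignments, min_len = 26L, max_len = 35L) {
  if (min_len > max_len) stopf("inverted length range [%d, %d]", min_len, max_len)
  keep <- alignments$length >= min_len & alignments$length <= max_len
  list(kept = alignments[keep], excluded = sum(!keep))
}

#' Run the full preprocessing chain with read bookkeeping
#'
#' FASTQ-level reads to length-filtered transcriptome alignments:
#' adapter trimming, quality filtering, contaminant depletion, exact-match
#' alignment, length filtering. Every read ends up in exactly one ledger
#' category (conservation: input equals the sum of all other fields).
#'
#' @param reads Read table ([read_fastq()] or `lib$reads`).
#' @param transcripts Named DNAStringSet transcriptome.
#' @param contaminants DNAStringSet of contaminant sequences (or NULL to
#'   skip depletion).
#' @param adapter Adapter sequence.
#' @param min_mean_phred,quality_method See [quality_filter()].
#' @param min_len,max_len See [length_filter()].
#' @param min_insert,seed_len See [trim_adapter()].
#' @return List: `alignments`, `ledger` (one-row data.table: input,
#'   adapter_discarded, quality_discarded, contaminant, unaligned,
#'   multimapped, length_excluded, kept).
#' @export
preprocess_reads <- function(reads, transcripts, contaminants = NULL,
                             adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                             min_mean_phred = 20,
                             quality_method = "mean",
                             min_len = 26L, max_len = 35L,
                             min_insert = 20L, seed_len = 8L) {
  if (min_len > max_len) stopf("inverted length range [%d, %d]", min_len, max_len)
  input <- nrow(reads)
  tr <- trim_adapter(reads, adapter, seed_len = seed_len,
                     min_insert = min_insert)
  qf <- quality_filter(tr$kept, min_mean_phred, method = quality_method)
  if (!is.null(contaminants) && length(contaminants)) {
    dc <- deplete_contaminants(qf$kept, contaminants)
  } else {
    dc <- list(kept = qf$kept, removed = qf$kept[0])
  }
  al <- align_to_transcriptome(dc$kept, transcripts)
  lf <- length_filter(al$alignments, min_len, max_len)
  ledger <- data.table(
    input = input,
    adapter_discarded = nrow(tr$discarded),
    quality_discarded = nrow(qf$discarded),
    contaminant = nrow(dc$removed),
    unaligned = al$unaligned,
    multimapped = al$multimapped,
    length_excluded = lf$excluded,
    kept = nrow(lf$kept)
  )
  list(alignments = lf$kept, ledger = ledger)
}

#' Check FilterLedger conservation
#'
#' @param ledger One-row ledger table from [preprocess_reads()].
#' @return TRUE iff input equals the sum of every other category.
#' @export
ledger_conserved <- function(ledger) {
  others <- setdiff(names(ledger), "input")
  ledger$input == sum(unlist(ledger[, others, with = FALSE]))
}
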