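#' Metagene histogram of 5' ends around the start codon
#'
#' Pools, over all annotated transcripts, the positions of read 5' ends
#' relative to the first nucleotide of the start codon, restricted to reads
#' of one length. This is the raw material for P-site offset calibration:
#' initiating ribosomes pile up with their P-site on the AUG, so the modal
#' 5'-end position at `-o(L)` reveals the offset.
#'
#' @param alignments Alignment table.
#' @param annotation Annotation data.table (transcript_id, cds_start, ...).
#' @param length_nt Read length L to select.
#' @param window Integer c(a, b), nt relative to the start codon's first nt
#'   (default c(-40, 20), covering initiating-ribosome geometry for all
#'   calibratable lengths).
#' @return data.table (position, count) over the full window grid, with
#'   attribute `flagged = TRUE` when no read falls in the window.
#' @export
five_prime_histogram <- function(alignments, annotation, length_nt,
                                 window = c(-40L, 20L)) {
  if (window[1] > window[2]) stopf("empty calibration window")
  dt <- as.data.table(alignments)[length == length_nt]
  dt <- merge(dt, annotation[, .(transcript_id, cds_start)],
              by = "transcript_id", sort = FALSE)
  rel <- dt$five_prime - dt$cds_start
  rel <- rel[rel >= window[1] & rel <= window[2]]
  grid <- seq.int(window[1], window[2])
  cnt <- tabulate(rel - window[1] + 1L, nbins = length(grid))
  out <- data.table(position = grid, count = cnt)
  setattr(out, "flagged", sum(cnt) == 0L)
  out[]
}

#' Calibrate per-read-length P-site offsets from start-codon metagenes
#'
#' For each read length L the offset is minus the modal 5'-end position in
#' the start-codon window, o(L) = -argmax; ties are broken toward the
#' smaller offset. Lengths with fewer than `min_support` reads in the
#' window, or whose mode implies an offset outside \[0, L\], are marked
#' uncalibrated and excluded downstream.
#'
#' @param alignments Length-filtered alignment table.
#' @param annotation Annotation table.
#' @param lengths Read lengths to calibrate (default 26:35).
#' @param min_support Minimum window reads for a calibrated entry.
#' @param window Calibration window in nt around the start codon.
#' @return `psite_offsets` data.table: length, offset (NA when
#'   uncalibrated), support, sharpness (modal fraction of window reads),
#'   calibrated (logical).
#' @examples
#' ## planted offsets are recovered exactly on simulated data; see vignette
#' @export
calibrate_offsets <- function(alignments, annotation, lengths = 26:35,
                              min_support = 100L, window = c(-40L, 20L)) {
  rows <- lapply(lengths, function(L) {
    h <- five_prime_histogram(alignments, annotation, L, window)
    supp <- sum(h$count)
    if (supp < min_support)
      return(data.table(length = L, offset = NA_integer_, support = supp,
                        sharpness = NA_real_, calibrated = FALSE))
    mx <- max(h$count)
    modal_pos <- max(h$position[h$count == mx])  # tie -> smaller offset
    off <- -modal_pos
    ok <- off >= 0L && off <= L
    data.table(length = L, offset = if (ok) as.integer(off) else NA_integer_,
               support = supp, sharpness = mx / supp, calibrated = ok)
  })
  out <- rbindlist(rows)
  if (!any(out$calibrated))
    stopf("no read length could be calibrated; deeper input required")
  setattr(out, "class", c("psite_offsets", class(out)))
  out[]
}

#' Assign P-sites and accumulate codon-resolution coverage
#'
#' Each read's P-site nucleotide is `five_prime + o(length)`. If it falls
#' inside the CDS the codon `(p - cds_start) %/% 3` is incremented
#' (sub-codon phase is ignored); otherwise the read counts as out-of-CDS.
#' Reads of uncalibrated lengths are skipped and counted. Conservation:
#' codon counts + out-of-CDS + skipped = input alignments.
#'
#' @param alignments Alignment table.
#' @param offsets A `psite_offsets` table from [calibrate_offsets()].
#' @param annotation Annotation table covering every aligned transcript.
#' @return `codon_coverage` object: list with `counts` (named list of
#'   integer vectors, one per annotated transcript, indexed by CDS codon),
#'   `out_of_cds` (named integer vector), `skipped` (count),
#'   `assigned` (count), `annotation`.
#' @export
psite_coverage <- function(alignments, offsets, annotation) {
  al <- as.data.table(alignments)
  missing_tx <- setdiff(unique(al$transcript_id), annotation$transcript_id)
  if (length(missing_tx))
    stopf("annotation missing for aligned transcript(s): %s",
          paste(head(missing_tx, 5), collapse = ", "))
  off <- offsets[calibrated == TRUE, .(length, offset)]
  al <- merge(al, off, by = "length", all.x = TRUE, sort = FALSE)
  skipped <- sum(is.na(al$offset))
  al <- al[!is.na(offset)]
  al <- merge(al, annotation[, .(transcript_id, cds_start, cds_end)],
              by = "transcript_id", sort = FALSE)
  al[, p := five_prime + offset]
  al[, in_cds := p >= cds_start & p < cds_end]
  al[, codon := fifelse(in_cds, (p - cds_start) %/% 3L, NA_integer_)]

  ncod <- setNames((annotation$cds_end - annotation$cds_start) %/% 3L,
                   annotation$transcript_id)
  counts <- lapply(ncod, function(k) integer(k))
  cc <- al[in_cds == TRUE, .N, by = .(transcript_id, codon)]
  for (tid in unique(cc$transcript_id)) {
    sub <- cc[transcript_id == tid]
    v <- counts[[tid]]
    v[sub$codon + 1L] <- sub$N
    counts[[tid]] <- v
  }
  ooc <- setNames(integer(length(ncod)), names(ncod))
  oc <- al[in_cds == FALSE, .N, by = transcript_id]
  ooc[oc$transcript_id] <- oc$N

  structure(list(counts = counts, out_of_cds = ooc, skipped = skipped,
                 assigned = nrow(al), annotation = annotation),
            class = "codon_coverage")
}

#' @export
print.psite_offsets <- function(x, ...) {
  cat("P-site offsets (", sum(x$calibrated), "of", nrow(x),
      "lengths calibrated)\n")
  NextMethod()
}

#' @export
print.codon_coverage <- function(x, ...) {
  cat("codon_coverage:", length(x$counts), "transcripts,",
      x$assigned, "assigned reads (", sum(x$out_of_cds), "out-of-CDS,",
      x$skipped, "skipped )\n")
  invisible(x)
}

#' Total codon-level conservation check for a coverage object
#'
#' @param coverage A `codon_coverage`.
#' @param n_alignments Number of alignments fed to [psite_coverage()].
#' @return TRUE iff codon counts + out-of-CDS + skipped equal
#'   `n_alignments`.
#' @export
coverage_conserved <- function(coverage, n_alignments) {
  sum(vapply(coverage$counts, sum, numeric(1))) +
    sum(coverage$out_of_cds) + coverage$skipped == n_alignments
}

#' Write an offset table or codon coverage as TSV
#'
#' @param x A `psite_offsets` or `codon_coverage`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psite_tsv <- function(x, path) {
  if (inherits(x, "codon_coverage")) {
    dt <- rbindlist(lapply(names(x$counts), function(tid)
      data.table(transcript_id = tid,
                 codon_index = seq_along(x$counts[[tid]]) - 1L,
                 count = x$counts[[tid]])))
    fwrite(dt, path, sep = "\t")
  } else {
    fwrite(as.data.table(x), path, sep = "\t")
  }
  invisible(path)
}
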