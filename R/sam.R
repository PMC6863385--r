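#' Write alignments as a headered SAM file
#'
#' Minimal single-end, forward-strand SAM (flag 0, pure-match CIGAR,
#' `*` sequence placeholders) for interoperability with samtools-style
#' tooling.
#'
#' @param alignments Alignment table (read_id, transcript_id, five_prime,
#'   length).
#' @param transcripts Named DNAStringSet (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sam <- function(alignments, transcripts, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(transcripts),
                   Biostrings::width(transcripts)))
  body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                  alignments$read_id, alignments$transcript_id,
                  alignments$five_prime + 1L, alignments$length)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Import alignments from a SAM file
#'
#' Accepts primary, forward-strand alignments with an indel-free CIGAR
#' (`<n>M`); everything else (reverse strand, secondary/supplementary,
#' unmapped, indel-containing) is counted and dropped. Positions are
#' converted from SAM 1-based to the package's 0-based five_prime.
#'
#' @param path SAM file path.
#' @return List: `alignments` (data.table read_id, transcript_id,
#'   five_prime, length) and `dropped` (count).
#' @export
import_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(list(alignments = data.table(read_id = character(),
                                        transcript_id = character(),
                                        five_prime = integer(),
                                        length = integer()),
                dropped = 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  rname <- vapply(f, `[`, character(1), 3L)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  cigar <- vapply(f, `[`, character(1), 6L)
  ok <- bitwAnd(flag, 4L) == 0L &          # mapped
    bitwAnd(flag, 16L) == 0L &             # forward strand
    bitwAnd(flag, 2304L) == 0L &           # primary (not 0x100/0x800)
    grepl("^[0-9]+M$", cigar)
  qname <- vapply(f, `[`, character(1), 1L)
  list(alignments = data.table(
    read_id = qname[ok],
    transcript_id = rname[ok],
    five_prime = pos[ok] - 1L,
    length = as.integer(sub("M$", "", cigar[ok]))
  ), dropped = sum(!ok))
}
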