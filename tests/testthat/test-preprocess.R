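adapter <- "ATCTCGTATGCCGTCTTCTGCTTG"

read_tbl <- function(seqs, quals = strrep("I", nchar(seqs)),
                     ids = sprintf("q%03d", seq_along(seqs))) {
  data.table::data.table(read_id = ids, seq = seqs, qual = quals)
}

test_that("adapter trimming returns the insert and flags boundary cases", {
  insert <- strrep("ACGT", 7)  # 28 nt
  r <- read_tbl(c(paste0(insert, adapter),  # normal
                  adapter,                  # insert length 0
                  paste0(strrep("A", 10), adapter),  # too short
                  strrep("G", 30),          # no adapter
                  ""))                      # empty
  out <- trim_adapter(r, adapter)
  expect_identical(out$kept$seq, insert)
  expect_identical(nchar(out$kept$qual), 28L)
  expect_identical(out$discarded$reason,
                   c("too_short", "too_short", "no_adapter", "empty"))
})

test_that("simulated inserts are recovered exactly against the truth table", {
  spec <- sim_spec(n_transcripts = 10L, depth = 1000L,
                   frac_contaminant = 0, frac_spikein = 0, frac_lowq = 0,
                   seed = 8L)
  lib <- simulate_library(generate_transcriptome(spec))
  out <- trim_adapter(lib$reads, spec$adapter)
  expect_identical(nrow(out$discarded), 0L)
  expect_identical(nchar(out$kept$seq), lib$truth$length)
})

test_that("quality filtering thresholds on the mean Phred score", {
  q40 <- strrep("I", 30)            # Phred 40 throughout
  q10 <- strrep("+", 30)            # Phred 10 throughout
  # 100 bases summing to 1997 -> mean 19.97; and exactly 2000 -> mean 20
  q1997 <- paste0(strrep("5", 97), strrep("4", 3))  # 97*20 + 3*19 = 1997
  stopifnot(sum(utf8ToInt(q1997) - 33) == 1997)
  q2000 <- strrep("5", 100)                         # 100 * 20
  r <- read_tbl(rep(strrep("A", c(30, 30, 100, 100)), 1),
                quals = c(q40, q10, q1997, q2000))
  out <- quality_filter(r, 20)
  expect_identical(out$kept$read_id, c("q001", "q004"))
  expect_identical(out$discarded$read_id, c("q002", "q003"))
})

test_that("contaminant depletion removes exact substrings only", {
  cont <- contaminant_sequences()
  inside <- substr(as.character(cont[[1]]), 101, 130)
  tx <- generate_transcriptome(sim_spec(n_transcripts = 2L, seed = 1L))
  ann <- tx$annotation[1, ]
  cds_read <- substr(as.character(tx$sequences[[ann$transcript_id]]),
                     ann$cds_start + 1L, ann$cds_start + 30L)
  out <- deplete_contaminants(read_tbl(c(inside, cds_read)), cont)
  expect_identical(out$removed$seq, inside)
  expect_identical(out$kept$seq, cds_read)
  expect_warning(deplete_contaminants(read_tbl(cds_read),
                                      Biostrings::DNAStringSet()),
                 "pass-through")
})

test_that("depletion count equals the truth contaminant count exactly", {
  spec <- sim_spec(n_transcripts = 10L, depth = 1e4L,
                   frac_contaminant = 0.1, frac_spikein = 0, frac_lowq = 0,
                   seed = 9L)
  lib <- simulate_library(generate_transcriptome(spec))
  trimmed <- trim_adapter(lib$reads, spec$adapter)$kept
  out <- deplete_contaminants(trimmed, contaminant_sequences())
  expect_identical(nrow(out$removed),
                   sum(lib$truth$class == "contaminant"))
})

test_that("unique exact-match alignment recovers truth and drops multimappers", {
  txs <- Biostrings::DNAStringSet(c(
    t1 = paste0("CCGTAC", strrep("A", 30), "GGATCCGTTACA"),
    t2 = paste0("TTTGCA", strrep("A", 30), "CTTGACGGATTC")))
  r <- read_tbl(c(substr(as.character(txs[[1]]), 3, 30),  # unique to t1
                  strrep("A", 28)))                       # in both
  out <- align_to_transcriptome(r, txs)
  expect_identical(out$alignments$transcript_id, "t1")
  expect_identical(out$alignments$five_prime, 2L)
  expect_identical(out$multimapped, 1L)
  expect_identical(out$unaligned, 0L)
  expect_error(
    align_to_transcriptome(r, Biostrings::DNAStringSet(c(a = "ACGT", a = "ACGT"))),
    "duplicate transcript IDs")
})

test_that("length filtering keeps the closed 26-35 range", {
  al <- data.table::data.table(read_id = sprintf("r%d", 1:4),
                               transcript_id = "t", five_prime = 0L,
                               length = c(25L, 26L, 35L, 36L))
  out <- length_filter(al)
  expect_identical(out$kept$length, c(26L, 35L))
  expect_identical(out$excluded, 2L)
  empty <- length_filter(al[0])
  expect_identical(nrow(empty$kept), 0L)
  expect_error(length_filter(al, 30L, 20L), "inverted")
})

test_that("full preprocessing conserves the ledger and recovers truth", {
  spec <- sim_spec(n_transcripts = 15L, depth = 1e4L, seed = 10L)
  tx <- generate_transcriptome(spec)
  lib <- simulate_library(tx)
  pp <- preprocess_reads(lib$reads, tx$sequences, contaminant_sequences())
  expect_true(ledger_conserved(pp$ledger))
  expect_identical(pp$ledger$contaminant,
                   sum(lib$truth$class == "contaminant"))
  expect_identical(pp$ledger$quality_discarded,
                   sum(lib$truth$class == "lowq"))
  # kept alignments recover the true placement for 100% of reads
  truth <- lib$truth[match(pp$alignments$read_id, lib$truth$read_id), ]
  expect_identical(pp$alignments$transcript_id, truth$transcript_id)
  expect_identical(pp$alignments$five_prime, truth$five_prime)
  # order stability: output order is input read order
  expect_false(is.unsorted(match(pp$alignments$read_id, lib$reads$read_id)))
})

test_that("SAM export/import round-trips and drops non-conforming records", {
  tx <- generate_transcriptome(sim_spec(n_transcripts = 3L, seed = 2L))
  lib <- simulate_library(tx, spec = sim_spec(n_transcripts = 3L, seed = 2L,
                                              depth = 500L,
                                              frac_contaminant = 0,
                                              frac_lowq = 0))
  al <- true_alignments(lib)
  d <- withr::local_tempdir()
  sam <- file.path(d, "aln.sam")
  export_sam(al, tx$sequences, sam)
  back <- import_sam(sam)
  expect_identical(back$dropped, 0L)
  expect_equal(as.data.frame(back$alignments), as.data.frame(al))
  # reverse-strand, secondary, unmapped and indel records are dropped
  writeLines(c("@HD\tVN:1.6",
               "r1\t0\tt\t10\t255\t28M\t*\t0\t0\t*\t*",
               "r2\t16\tt\t10\t255\t28M\t*\t0\t0\t*\t*",
               "r3\t256\tt\t10\t255\t28M\t*\t0\t0\t*\t*",
               "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
               "r5\t0\tt\t10\t255\t10M2D16M\t*\t0\t0\t*\t*"),
             file.path(d, "mixed.sam"))
  mixed <- import_sam(file.path(d, "mixed.sam"))
  expect_identical(mixed$alignments$read_id, "r1")
  expect_identical(mixed$alignments$five_prime, 9L)
  expect_identical(mixed$dropped, 4L)
})
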