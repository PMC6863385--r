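test_that("with no enrichment the codon histogram is flat (chi-square GOF)", {
  spec <- sim_spec(n_transcripts = 20L, start_enrichment = 1,
                   pause_multiplier = 1, nogo_drop = 0,
                   frac_lowq = 0, frac_contaminant = 0, frac_spikein = 0,
                   depth = 1e5L, seed = 1L)
  tx <- generate_transcriptome(spec)
  lib <- simulate_library(tx, emit = "truth")
  tr <- lib$truth
  ann <- tx$annotation[tx$annotation$species == "primary", ]
  ncod <- setNames((ann$cds_end - ann$cds_start) %/% 3L, ann$transcript_id)
  # global codon id = transcript offset + codon
  first <- cumsum(c(0L, head(ncod, -1L)))
  names(first) <- names(ncod)
  gid <- first[tr$transcript_id] + tr$psite_codon + 1L
  counts <- tabulate(gid, nbins = sum(ncod))
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / sum(ncod), sum(ncod))))
  expect_gt(gof$p.value, 0.01)
})

test_that("motif codons are enriched by the pause multiplier", {
  spec <- sim_spec(n_transcripts = 50L, pause_multiplier = 4,
                   start_enrichment = 1,
                   frac_lowq = 0, frac_contaminant = 0, frac_spikein = 0,
                   depth = 5e5L, seed = 2L)
  tx <- generate_transcriptome(spec)
  lib <- simulate_library(tx, emit = "truth")
  tr <- lib$truth
  is_motif <- rep(FALSE, nrow(tr))
  key <- paste(tr$transcript_id, tr$psite_codon)
  motif_keys <- unlist(lapply(seq_len(nrow(tx$motifs)), function(i)
    paste(tx$motifs$transcript_id[i],
          tx$motifs$codon_index[i] + 0:(nchar(tx$motifs$motif[i]) - 1L))))
  n_motif_codons <- length(motif_keys)
  ann <- tx$annotation[tx$annotation$species == "primary", ]
  n_codons <- sum((ann$cds_end - ann$cds_start) %/% 3L)
  mean_motif <- sum(key %in% motif_keys) / n_motif_codons
  mean_other <- sum(!key %in% motif_keys) / (n_codons - n_motif_codons)
  expect_lt(abs(mean_motif / mean_other - 4), 0.3)
})

test_that("spike-in reads appear at the configured mixing fraction", {
  spec <- sim_spec(n_transcripts = 10L, frac_spikein = 0.2,
                   frac_lowq = 0, frac_contaminant = 0,
                   depth = 1000L, seed = 3L)
  lib <- simulate_library(generate_transcriptome(spec), emit = "truth")
  n_spike <- sum(lib$truth$class == "spikein")
  expect_true(abs(n_spike - 200L) <= 25L)
  expect_true(all(startsWith(
    lib$truth$transcript_id[lib$truth$class == "spikein"], "spike|")))
})

test_that("emitted classes partition the library and match the truth table", {
  spec <- small_spec(seed = 4L, frac_lowq = 0.05, frac_contaminant = 0.1,
                     frac_spikein = 0.15)
  lib <- simulate_library(generate_transcriptome(spec))
  cls <- table(lib$truth$class)
  expect_identical(nrow(lib$reads), nrow(lib$truth))
  expect_identical(sum(cls), nrow(lib$truth))
  expect_identical(unname(cls[["contaminant"]]), as.integer(round(0.1 * spec$depth)))
  expect_identical(unname(cls[["spikein"]]), as.integer(round(0.15 * spec$depth)))
  expect_identical(unname(cls[["lowq"]]), as.integer(round(0.05 * spec$depth)))
  # no-go dropping removes reads from both output and truth, symmetrically
  spec2 <- small_spec(seed = 4L, nogo_drop = 0.5)
  lib2 <- simulate_library(generate_transcriptome(spec2))
  expect_identical(nrow(lib2$reads) + lib2$n_nogo_dropped,
                   spec2$depth)
  expect_gt(lib2$n_nogo_dropped, 0L)
})

test_that("the empirical read-length distribution matches the weights", {
  spec <- sim_spec(n_transcripts = 20L, depth = 1e5L,
                   frac_lowq = 0, frac_contaminant = 0, frac_spikein = 0,
                   seed = 5L)
  lib <- simulate_library(generate_transcriptome(spec), emit = "truth")
  n <- nrow(lib$truth)
  obs <- table(factor(lib$truth$length, levels = 26:35))
  for (L in names(spec$length_weights)) {
    p <- spec$length_weights[[L]]
    sd3 <- 3 * sqrt(n * p * (1 - p))
    expect_lt(abs(obs[[L]] - n * p), max(sd3, 1))
  }
})

test_that("identical spec and seed give byte-identical FASTQ and truth", {
  spec <- sim_spec(n_transcripts = 5L, depth = 2000L, seed = 6L)
  tx <- generate_transcriptome(spec)
  a <- simulate_library(tx)
  b <- simulate_library(tx)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  d <- withr::local_tempdir()
  write_fastq(a$reads, file.path(d, "a.fastq"))
  write_fastq(b$reads, file.path(d, "b.fastq"))
  expect_identical(readLines(file.path(d, "a.fastq")),
                   readLines(file.path(d, "b.fastq")))
})

test_that("reads carry fragment + full adapter and class-typed qualities", {
  spec <- sim_spec(n_transcripts = 3L, depth = 500L, frac_lowq = 0.2,
                   frac_contaminant = 0, frac_spikein = 0, seed = 7L)
  tx <- generate_transcriptome(spec)
  lib <- simulate_library(tx)
  expect_true(all(nchar(lib$reads$seq) ==
                    lib$truth$length + nchar(spec$adapter)))
  lowq <- lib$truth$class == "lowq"
  expect_true(all(grepl("^\\++$", lib$reads$qual[lowq])))
  expect_true(all(grepl("^I+$", lib$reads$qual[!lowq])))
  # fragment is a verbatim copy of the transcript at the recorded 5' end
  i <- which(!lowq)[1:50]
  frag <- substr(lib$reads$seq[i], 1L, lib$truth$length[i])
  txchr <- as.character(tx$sequences)
  expect_identical(frag, unname(substring(txchr[lib$truth$transcript_id[i]],
                                          lib$truth$five_prime[i] + 1L,
                                          lib$truth$five_prime[i] +
                                            lib$truth$length[i])))
})
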