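test_that("an SPPPVP context yields overlapping PPP, SPP and PPV hits", {
  spec <- sim_spec(n_transcripts = 5L, planted_motifs = c(SPPPVP = 1L),
                   seed = 21L)
  tx <- generate_transcriptome(spec)
  prim <- tx$annotation[tx$annotation$species == "primary", ]
  c0 <- tx$motifs$codon_index[tx$motifs$transcript_id == prim$transcript_id[1]]
  ppp <- scan_motifs(tx$sequences, prim, "PPP")
  spp <- scan_motifs(tx$sequences, prim, "SPP")
  ppv <- scan_motifs(tx$sequences, prim, "PPV")
  one <- function(x) x[x$transcript_id == prim$transcript_id[1], ]
  expect_identical(one(ppp)$codon_index, c0 + 1L)   # S[PPP]VP
  expect_identical(one(spp)$codon_index, c0)        # [SPP]PVP
  expect_identical(one(ppv)$codon_index, c0 + 2L)   # SP[PPV]P
  expect_identical(nrow(ppp), 5L)
})

test_that("proline-free CDSes yield no occurrences; PPPP yields two PPPs", {
  # default backgrounds exclude proline, so spike transcripts are P-free
  tx <- generate_transcriptome(small_spec(seed = 22L))
  spike <- tx$annotation[tx$annotation$species == "spike", ]
  expect_identical(nrow(scan_motifs(tx$sequences, spike, "PPP")), 0L)
  tx4 <- generate_transcriptome(
    sim_spec(n_transcripts = 3L, planted_motifs = c(PPPP = 1L), seed = 23L))
  prim <- tx4$annotation[tx4$annotation$species == "primary", ]
  hits <- scan_motifs(tx4$sequences, prim, "PPP")
  expect_identical(nrow(hits), 6L)  # two overlapping PPPs per transcript
})

test_that("scanning recovers exactly the planted truth set", {
  tx <- generate_transcriptome(small_spec(seed = 24L))
  prim <- tx$annotation[tx$annotation$species == "primary", ]
  hits <- scan_motifs(tx$sequences, prim, "PPP")
  got <- data.table::setorder(hits[, c("transcript_id", "codon_index")])
  want <- data.table::setorder(
    tx$motifs[tx$motifs$motif == "PPP", c("transcript_id", "codon_index")])
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("an internal stop skips the transcript with a warning", {
  seqs <- Biostrings::DNAStringSet(c(
    bad = paste0("ATG", strrep("GCT", 10), "TAA", strrep("GCT", 10), "TAA")))
  ann <- data.table::data.table(transcript_id = "bad",
                                length = Biostrings::width(seqs),
                                cds_start = 0L,
                                cds_end = Biostrings::width(seqs),
                                species = "primary")
  expect_warning(hits <- scan_motifs(seqs, ann, "AAA"), "internal stop")
  expect_identical(nrow(hits), 0L)
})

test_that("pause score arithmetic: motif mean over flank mean", {
  v <- rep(2L, 120)
  v[51:53] <- 8L
  cov <- make_coverage(list(t1 = v))
  occ <- data.table::data.table(transcript_id = "t1", motif = "PPP",
                                codon_index = 50L, context = "")
  sc <- pause_scores(cov, occ)
  expect_identical(sc$score, 4)
  expect_identical(sc$background, 2)
  expect_true(sc$usable)
  # uniform coverage scores exactly 1
  sc1 <- pause_scores(make_coverage(list(t1 = rep(3L, 120))), occ)
  expect_identical(sc1$score, 1)
})

test_that("scores are scale-invariant and medians ignore unusable rows", {
  set.seed(25)
  v <- rpois(200, 6) + 1L
  cov <- make_coverage(list(t1 = v, t2 = integer(200)))
  occ <- data.table::data.table(transcript_id = "t1", motif = "PPP",
                                codon_index = c(60L, 120L), context = "")
  sc <- pause_scores(cov, occ)
  cov10 <- make_coverage(list(t1 = v * 10L, t2 = integer(200)))
  sc10 <- pause_scores(cov10, occ)
  expect_equal(sc10$score, sc$score)
  # an unusable (zero-background) occurrence leaves the aggregate unchanged
  occ2 <- rbind(occ, data.table::data.table(
    transcript_id = "t2", motif = "PPP", codon_index = 60L, context = ""))
  sc2 <- pause_scores(cov, occ2)
  expect_false(sc2$usable[3])
  expect_identical(attr(sc2, "median_score"), attr(sc, "median_score"))
})

test_that("the flank background excludes other occurrences' codons", {
  v <- rep(2L, 160)
  v[71:73] <- 40L   # occurrence A at codon 70
  v[81:83] <- 40L   # occurrence B at codon 80, inside A's flank window
  cov <- make_coverage(list(t1 = v))
  occ <- data.table::data.table(transcript_id = "t1", motif = "PPP",
                                codon_index = c(70L, 80L), context = "")
  sc <- pause_scores(cov, occ)
  expect_identical(sc$background, c(2, 2))
  expect_identical(sc$score, c(20, 20))
})

test_that("motif metagene is flat at 1 on uniform coverage, peaked when planted", {
  occ <- data.table::data.table(transcript_id = "t1", motif = "PPP",
                                codon_index = 60L, context = "")
  flat <- motif_metagene(make_coverage(list(t1 = rep(4L, 150))), occ)
  expect_true(all(abs(flat$mean - 1) < 1e-12))
  expect_true(attr(motif_metagene(make_coverage(list(t1 = rep(4L, 150))),
                                  occ[0]), "flagged"))
})

test_that("condition comparison: identity ratio, refusal on tiny tables", {
  set.seed(26)
  fake_scores <- function(x) {
    dt <- data.table::data.table(transcript_id = "t", motif = "PPP",
                                 codon_index = seq_along(x), score = x,
                                 background = 2, usable = TRUE)
    data.table::setattr(dt, "class", c("pause_scores", class(dt)))
    dt
  }
  a <- fake_scores(rlnorm(50, log(4), 0.2))
  cmp <- compare_conditions(a, a, n_boot = 200L, seed = 1L)
  expect_equal(cmp$ratio, 1)
  expect_true(cmp$ci[1] <= 1 && 1 <= cmp$ci[2])
  # deterministic given seed
  cmp2 <- compare_conditions(a, a, n_boot = 200L, seed = 1L)
  expect_identical(cmp$ci, cmp2$ci)
  expect_error(compare_conditions(a[1:5, ], a, seed = 1L), ">= 10 usable")
  expect_error(compare_conditions(a, a, n_boot = 10L), "seed is mandatory")
})

test_that("planted pause multipliers are recovered by the median score", {
  spec <- sim_spec(n_transcripts = 100L, pause_multiplier = 4,
                   depth = 2e5L, frac_contaminant = 0, frac_spikein = 0,
                   frac_lowq = 0, seed = 27L)
  tx <- generate_transcriptome(spec)
  cov <- truth_coverage(simulate_library(tx, emit = "truth"), tx)
  occ <- scan_motifs(tx$sequences,
                     tx$annotation[tx$annotation$species == "primary", ],
                     "PPP")
  sc <- pause_scores(cov, occ)
  expect_gt(attr(sc, "n_usable"), 50L)
  expect_lt(abs(attr(sc, "median_score") - 4) / 4, 0.15)
})
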