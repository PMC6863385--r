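#' Locate tripeptide motifs in annotated CDSes
#'
#' Translates each CDS in frame and reports every (possibly overlapping)
#' occurrence of the peptide motif that keeps at least `flank` codons of
#' CDS on each side — so `PPPP` yields two `PPP` occurrences, and the
#' TFEB-style context `SPPPVP` contains one `PPP`, one `SPP` and one `PPV`.
#' Transcripts whose CDS carries an internal stop are skipped with a
#' warning.
#'
#' @param sequences Named DNAStringSet (or a `sim_transcriptome`).
#' @param annotation Annotation table (ignored when a `sim_transcriptome`
#'   is given).
#' @param motif Peptide motif, e.g. `"PPP"`, `"SPP"`, `"PPV"`.
#' @param flank Minimum flanking codons inside the CDS on each side.
#' @return data.table: transcript_id, motif, codon_index (0-based, first
#'   residue), context (amino acids from 5 codons before to 5 after).
#' @export
scan_motifs <- function(sequences, annotation = NULL, motif = "PPP",
                        flank = 5L) {
  if (inherits(sequences, "sim_transcriptome")) {
    annotation <- sequences$annotation
    sequences <- sequences$sequences
  }
  stopifnot(!is.null(annotation), nzchar(motif))
  mlen <- nchar(motif)
  out <- vector("list", nrow(annotation))
  for (r in seq_len(nrow(annotation))) {
    tid <- annotation$transcript_id[r]
    s <- annotation$cds_start[r]
    e <- annotation$cds_end[r]
    aa <- translate_cds(substr(as.character(sequences[[tid]]), s + 1L, e))
    n_cod <- nchar(aa)
    if (n_cod < mlen + 2L * flank) next
    body <- substr(aa, 1L, n_cod - 1L)  # residues before the stop
    if (grepl("*", body, fixed = TRUE)) {
      warning("internal stop codon in CDS of ", tid, "; transcript skipped")
      next
    }
    starts <- which(substring(aa, seq_len(n_cod - mlen + 1L),
                              seq_len(n_cod - mlen + 1L) + mlen - 1L) == motif)
    if (!length(starts)) next
    c0 <- starts - 1L  # 0-based codon index
    keep <- c0 >= flank & (c0 + mlen - 1L) <= (n_cod - 1L - flank)
    c0 <- c0[keep]
    if (!length(c0)) next
    ctx <- substring(aa, pmax(1L, c0 + 1L - 5L),
                     pmin(n_cod, c0 + mlen + 5L))
    out[[r]] <- data.table(transcript_id = tid, motif = motif,
                           codon_index = c0, context = ctx)
  }
  res <- rbindlist(out)
  if (!nrow(res))
    res <- data.table(transcript_id = character(), motif = character(),
                      codon_index = integer(), context = character())
  res[]
}

# flank codon indices for one occurrence: codons `flank[1]..flank[2]` away
# on each side, clipped to the CDS interior (first/last `edge_exclude`
# codons dropped) and purged of codons belonging to other occurrences
flank_codons <- function(c0, mlen, n_cod, flank, edge_exclude, other_codons) {
  left <- seq.int(c0 - flank[2], c0 - flank[1])
  right <- seq.int(c0 + mlen - 1L + flank[1], c0 + mlen - 1L + flank[2])
  f <- c(left, right)
  f <- f[f >= edge_exclude & f <= n_cod - 1L - edge_exclude]
  setdiff(f, other_codons)
}

#' Score ribosome pausing at motif occurrences
#'
#' The pause score of an occurrence is the mean P-site count over its
#' motif codons divided by the mean over flanking background codons
#' (codons `flank[1]` to `flank[2]` away on each side, excluding codons of
#' any other occurrence and the first/last `edge_exclude` CDS codons, which
#' carry initiation/termination ramps). Occurrences whose background mean
#' is below `floor` reads/codon (or whose flank set is empty) are flagged
#' unusable and never divide by zero. Uniform coverage scores exactly 1;
#' the score is invariant to rescaling all counts.
#'
#' @param coverage A `codon_coverage`.
#' @param occurrences Occurrence table from [scan_motifs()].
#' @param flank c(inner, outer) flank distance in codons (default 5..50).
#' @param floor Minimum usable background mean (reads/codon).
#' @param edge_exclude CDS edge codons excluded from the background.
#' @return `pause_scores` data.table: per occurrence transcript_id, motif,
#'   codon_index, score, background, usable; attributes `median_score`
#'   (over usable occurrences) and `n_usable`.
#' @export
pause_scores <- function(coverage, occurrences, flank = c(5L, 50L),
                         floor = 0.5, edge_exclude = 5L) {
  stopifnot(inherits(coverage, "codon_coverage"))
  if (flank[1] < 1L || flank[1] > flank[2]) stopf("invalid flank range")
  occ <- as.data.table(occurrences)
  res <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    tid <- occ$transcript_id[i]
    v <- coverage$counts[[tid]]
    if (is.null(v))
      stopf("coverage missing for transcript %s", tid)
    n_cod <- length(v)
    c0 <- occ$codon_index[i]
    mlen <- nchar(occ$motif[i])
    others <- occ[transcript_id == tid & codon_index != c0]
    other_codons <- unlist(lapply(seq_len(nrow(others)), function(j)
      others$codon_index[j] + seq_len(nchar(others$motif[j])) - 1L))
    motif_cod <- c0 + seq_len(mlen) - 1L
    other_codons <- setdiff(other_codons, motif_cod)
    f <- flank_codons(c0, mlen, n_cod, flank, edge_exclude, other_codons)
    bg <- if (length(f)) mean(v[f + 1L]) else NA_real_
    usable <- !is.na(bg) && bg >= floor
    score <- if (usable && bg > 0) mean(v[motif_cod + 1L]) / bg else NA_real_
    res[[i]] <- data.table(transcript_id = tid, motif = occ$motif[i],
                           codon_index = c0, score = score,
                           background = bg, usable = usable)
  }
  out <- if (length(res)) rbindlist(res) else
    data.table(transcript_id = character(), motif = character(),
               codon_index = integer(), score = numeric(),
               background = numeric(), usable = logical())
  setattr(out, "median_score", median(out$score[out$usable]))
  setattr(out, "n_usable", sum(out$usable))
  setattr(out, "class", c("pause_scores", class(out)))
  out[]
}

#' Aggregate pause score of a score table
#'
#' @param scores A `pause_scores` table.
#' @param method `"median"` (robust to the heavy right tail of ratio
#'   scores; default) or `"mean"`.
#' @return Length-1 numeric over usable occurrences.
#' @export
aggregate_pause_score <- function(scores, method = c("median", "mean")) {
  method <- match.arg(method)
  x <- scores$score[scores$usable]
  if (!length(x)) return(NA_real_)
  if (method == "median") median(x) else mean(x)
}

#' Motif-anchored metagene profile
#'
#' Positional occupancy around motif occurrences: for each occurrence the
#' counts at codon offsets `window[1]..window[2]` from the motif's first
#' codon are normalized by that occurrence's flanking-background mean (the
#' same background as [pause_scores()]), then each offset column is
#' averaged with [trimmed_column_mean()]. Uniform coverage gives a flat
#' profile at 1; a planted pause multiplier m appears as a peak of height
#' about m at offsets 0..motif length - 1.
#'
#' @inheritParams pause_scores
#' @param window Codon offsets relative to the motif first codon
#'   (default c(-5, 7)).
#' @param trim_frac Per-offset trim fraction.
#' @return `metagene_profile`-classed data.table (position, mean, n); the
#'   `flagged` attribute is TRUE when no occurrence was usable.
#' @export
motif_metagene <- function(coverage, occurrences, window = c(-5L, 7L),
                           trim_frac = 0.001, flank = c(5L, 50L),
                           floor = 0.5, edge_exclude = 5L) {
  stopifnot(inherits(coverage, "codon_coverage"))
  occ <- as.data.table(occurrences)
  pos <- seq.int(window[1], window[2])
  rows <- matrix(NA_real_, nrow = nrow(occ), ncol = length(pos))
  usable <- logical(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    tid <- occ$transcript_id[i]
    v <- coverage$counts[[tid]]
    if (is.null(v)) next
    n_cod <- length(v)
    c0 <- occ$codon_index[i]
    mlen <- nchar(occ$motif[i])
    others <- occ[transcript_id == tid & codon_index != c0]
    other_codons <- setdiff(
      unlist(lapply(seq_len(nrow(others)), function(j)
        others$codon_index[j] + seq_len(nchar(others$motif[j])) - 1L)),
      c0 + seq_len(mlen) - 1L)
    f <- flank_codons(c0, mlen, n_cod, flank, edge_exclude, other_codons)
    bg <- if (length(f)) mean(v[f + 1L]) else NA_real_
    if (is.na(bg) || bg < floor || bg == 0) next
    usable[i] <- TRUE
    idx <- c0 + pos
    ok <- idx >= 0L & idx < n_cod
    rows[i, ok] <- v[idx[ok] + 1L] / bg
  }
  rows <- rows[usable, , drop = FALSE]
  if (!nrow(rows)) {
    out <- data.table(position = pos, mean = NA_real_, n = 0L)
    return(new_metagene_profile(out, "motif", window, trim_frac, 0L,
                                sum(!usable), flagged = TRUE))
  }
  means <- numeric(length(pos)); nn <- integer(length(pos))
  for (j in seq_along(pos)) {
    col <- rows[, j][!is.na(rows[, j])]
    nn[j] <- length(col)
    means[j] <- if (length(col)) trimmed_column_mean(col, trim_frac) else NA_real_
  }
  out <- data.table(position = pos, mean = means, n = nn)
  new_metagene_profile(out, "motif", window, trim_frac, nrow(rows),
                       sum(!usable), flagged = FALSE)
}

#' Compare pause scores between two conditions by bootstrap ratio
#'
#' The contrast is the ratio of aggregate (median) scores, B over A, with a
#' seeded percentile bootstrap over occurrences. A confidence interval
#' containing 1 communicates "no further increase" directly — the
#' observable expected when stronger stalling is offset by no-go-decay
#' read loss.
#'
#' @param table_a,table_b `pause_scores` tables for conditions A and B;
#'   each needs at least 10 usable occurrences.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed (mandatory: results are deterministic given
#'   it).
#' @param conf Confidence level of the percentile interval.
#' @return List: ratio, ci (length 2), conf, n_boot, n_a, n_b, seed.
#' @export
compare_conditions <- function(table_a, table_b, n_boot = 1000L, seed,
                               conf = 0.95) {
  if (missing(seed)) stopf("compare_conditions: seed is mandatory")
  a <- table_a$score[table_a$usable]
  b <- table_b$score[table_b$usable]
  if (length(a) < 10L || length(b) < 10L)
    stopf("need >= 10 usable occurrences per condition (got %d and %d)",
          length(a), length(b))
  ratio <- median(b) / median(a)
  set.seed(derive_seed(seed, 7L))
  boots <- vapply(seq_len(n_boot), function(i) {
    median(sample(b, replace = TRUE)) / median(sample(a, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  list(ratio = ratio, ci = ci, conf = conf, n_boot = n_boot,
       n_a = length(a), n_b = length(b), seed = seed)
}
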