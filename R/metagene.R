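#' Outlier-trimmed column mean
#'
#' Nearest-rank quantile trimming: values strictly above the (1 - f)
#' quantile and strictly below the f quantile are removed, then the
#' arithmetic mean is taken. With `trim_frac = 0`, or with fewer than
#' `1 / trim_frac` values (so that the nearest-rank cuts are the extremes
#' themselves), this degrades to the plain mean — the small-n behaviour
#' that makes 0.1% trimming a no-op on shallow windows.
#'
#' @param values Non-empty numeric vector.
#' @param trim_frac Fraction f in \[0, 0.5) trimmed at each tail.
#' @return The trimmed mean (length-1 numeric).
#' @examples
#' trimmed_column_mean(c(rep(1, 9), 1e6), 0.001)  # n < 1/f: plain mean
#' @export
trimmed_column_mean <- function(values, trim_frac = 0.001) {
  if (!length(values)) stopf("trimmed_column_mean: empty input")
  if (trim_frac < 0 || trim_frac >= 0.5)
    stopf("trim_frac must be in [0, 0.5)")
  if (trim_frac == 0) return(mean(values))
  lo <- quantile(values, trim_frac, type = 1, names = FALSE)
  hi <- quantile(values, 1 - trim_frac, type = 1, names = FALSE)
  mean(values[values >= lo & values <= hi])
}

#' Landmark-anchored metagene profile with exclusion and trimming rules
#'
#' Builds the average positional footprint signal across transcripts,
#' anchored at the start codon (position 0 = first CDS codon) or the stop
#' codon (position 0 = stop codon). Transcripts with no reads anywhere in
#' the window are excluded before any other filter; each remaining
#' transcript's window is normalized by its own mean count over the window
#' (making profiles depth-independent), and each position's column of
#' signals is averaged after removing the highest and lowest `trim_frac`
#' (default 0.1%) by [trimmed_column_mean()]. Window positions outside a
#' transcript's CDS are missing for that transcript, so per-position n can
#' be below `transcripts_used`.
#'
#' @param coverage A `codon_coverage` from [psite_coverage()].
#' @param landmark `"start"` or `"stop"`.
#' @param window Integer c(a, b) in codons relative to the landmark
#'   (defaults: start c(-20, 100), stop c(-100, 20)).
#' @param trim_frac Per-position two-sided trim fraction.
#' @param normalize If FALSE, raw counts are averaged instead of
#'   window-mean-normalized signals.
#' @param species Restrict to transcripts of this species
#'   (`NULL` = all).
#' @return `metagene_profile` object: data.table (position, mean, n) plus
#'   attributes landmark, window, trim_frac, transcripts_used,
#'   transcripts_excluded, flagged (TRUE when every transcript was
#'   excluded).
#' @export
metagene_profile <- function(coverage, landmark = c("start", "stop"),
                             window = NULL, trim_frac = 0.001,
                             normalize = TRUE, species = "primary") {
  stopifnot(inherits(coverage, "codon_coverage"))
  landmark <- match.arg(landmark)
  if (is.null(window))
    window <- if (landmark == "start") c(-20L, 100L) else c(-100L, 20L)
  if (window[1] > window[2]) stopf("inverted metagene window")

  ann <- coverage$annotation
  if (!is.null(species) && "species" %in% names(ann)) {
    keep_tx <- ann[["species"]] %in% species
    ann <- ann[keep_tx, ]
  }
  ids <- intersect(ann$transcript_id, names(coverage$counts))
  pos <- seq.int(window[1], window[2])

  rows <- matrix(NA_real_, nrow = length(ids), ncol = length(pos))
  for (i in seq_along(ids)) {
    v <- coverage$counts[[ids[i]]]
    k <- length(v)
    anchor <- if (landmark == "start") 0L else k - 1L
    idx <- anchor + pos
    ok <- idx >= 0L & idx < k
    rows[i, ok] <- v[idx[ok] + 1L]
  }
  # zero-read-in-window transcripts are excluded before any other filter
  in_window_reads <- rowSums(rows, na.rm = TRUE)
  has_any <- apply(rows, 1L, function(r) any(!is.na(r))) & in_window_reads > 0
  excluded <- sum(!has_any)
  rows <- rows[has_any, , drop = FALSE]

  if (!nrow(rows)) {
    out <- data.table(position = pos, mean = NA_real_, n = 0L)
    return(new_metagene_profile(out, landmark, window, trim_frac,
                                0L, excluded, flagged = TRUE))
  }
  if (normalize) {
    rm <- rowMeans(rows, na.rm = TRUE)
    rows <- rows / rm
  }
  means <- numeric(length(pos))
  nn <- integer(length(pos))
  for (j in seq_along(pos)) {
    col <- rows[, j]
    col <- col[!is.na(col)]
    nn[j] <- length(col)
    means[j] <- if (length(col)) trimmed_column_mean(col, trim_frac) else NA_real_
  }
  out <- data.table(position = pos, mean = means, n = nn)
  new_metagene_profile(out, landmark, window, trim_frac,
                       nrow(rows), excluded, flagged = FALSE)
}

new_metagene_profile <- function(dt, landmark, window, trim_frac,
                                 used, excluded, flagged) {
  setattr(dt, "landmark", landmark)
  setattr(dt, "window", window)
  setattr(dt, "trim_frac", trim_frac)
  setattr(dt, "transcripts_used", used)
  setattr(dt, "transcripts_excluded", excluded)
  setattr(dt, "flagged", flagged)
  setattr(dt, "class", c("metagene_profile", class(dt)))
  dt[]
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile (%s, window %d..%d, trim %g): %d used, %d excluded\n",
              attr(x, "landmark"), attr(x, "window")[1], attr(x, "window")[2],
              attr(x, "trim_frac"), attr(x, "transcripts_used"),
              attr(x, "transcripts_excluded")))
  NextMethod()
}

#' Write a metagene (or motif) profile as TSV
#'
#' @param profile A `metagene_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  fwrite(as.data.table(profile), path, sep = "\t")
  invisible(path)
}
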