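#' Spike-in normalization factors
#'
#' Library i gets factor `spike_i / geometric-mean(spike)`, so the factors
#' of a run have geometric mean 1 and no library is a designated
#' reference; downstream coverage is divided by its library's factor.
#'
#' @param spike_counts Named (or unnamed) numeric vector of spike-in read
#'   counts per library; every entry must be > 0 — with zero spike-in
#'   reads normalization is impossible.
#' @return data.table: library, spike_reads, factor.
#' @examples
#' spikein_factors(c(A = 1000, B = 4000))  # factors 0.5 and 2
#' @export
spikein_factors <- function(spike_counts) {
  if (any(spike_counts <= 0))
    stopf("every library needs > 0 spike-in reads for normalization")
  nm <- names(spike_counts)
  if (is.null(nm)) nm <- sprintf("lib%d", seq_along(spike_counts))
  data.table(library = nm, spike_reads = as.numeric(spike_counts),
             factor = as.numeric(spike_counts) / geo_mean(spike_counts))
}

#' Divide codon coverage by a normalization factor
#'
#' @param coverage A `codon_coverage`.
#' @param factor Positive scalar (e.g. from [spikein_factors()]).
#' @return The coverage with all codon counts divided by `factor`
#'   (numeric, no longer integer).
#' @export
normalize_coverage <- function(coverage, factor) {
  stopifnot(inherits(coverage, "codon_coverage"), factor > 0)
  coverage$counts <- lapply(coverage$counts, function(v) v / factor)
  coverage
}

#' Count aligned reads per species by transcript-ID prefix
#'
#' @param alignments Alignment table.
#' @param spike_prefix Transcript-ID prefix marking spike-in species.
#' @return Named numeric: primary and spike read counts.
#' @export
species_counts <- function(alignments, spike_prefix = "spike|") {
  spike <- startsWith(alignments$transcript_id, spike_prefix)
  c(primary = sum(!spike), spike = sum(spike))
}

#' Build and validate a pipeline run configuration
#'
#' All thresholds the pipeline uses, with the field-standard constants as
#' defaults (adapter, Phred 20 quality cutoff, 26--35 nt length range,
#' 0.1% metagene trim). Validation runs before any I/O.
#'
#' @param sim A [sim_spec()] to simulate input from, or NULL when reading
#'   files.
#' @param reads,transcriptome,annotation,contaminants Input paths (used
#'   when `sim` is NULL; `contaminants` may also be NULL to skip
#'   depletion).
#' @param adapter,min_mean_phred,min_len,max_len Preprocessing settings.
#' @param calibration_window,min_support P-site calibration settings.
#' @param start_window,stop_window,trim_frac Metagene settings (codons).
#' @param motifs Character vector of peptide motifs to score.
#' @param flank,bg_floor Pause-score background settings.
#' @param n_boot Bootstrap replicates for condition comparison.
#' @param spike_normalize Divide coverage by the library's spike factor
#'   (off by default; the spike-in design also serves bench-side RNA
#'   accounting, so normalization is opt-in).
#' @param seed Integer seed, mandatory.
#' @param out_dir Output directory.
#' @return Validated `run_config` list.
#' @export
run_config <- function(sim = NULL, reads = NULL, transcriptome = NULL,
                       annotation = NULL, contaminants = NULL,
                       adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                       min_mean_phred = 20,
                       min_len = 26L, max_len = 35L,
                       calibration_window = c(-40L, 20L),
                       min_support = 100L,
                       start_window = c(-20L, 100L),
                       stop_window = c(-100L, 20L),
                       trim_frac = 0.001,
                       motifs = "PPP",
                       flank = c(5L, 50L), bg_floor = 0.5,
                       n_boot = 1000L,
                       spike_normalize = FALSE,
                       seed = NULL, out_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "run_config")
  if (is.null(cfg$seed)) stopf("run_config: seed is mandatory")
  if (min_len > max_len) stopf("inverted length range [%d, %d]", min_len, max_len)
  if (calibration_window[1] > calibration_window[2])
    stopf("inverted calibration window")
  if (start_window[1] > start_window[2] || stop_window[1] > stop_window[2])
    stopf("inverted metagene window")
  if (trim_frac < 0 || trim_frac >= 0.5) stopf("trim_frac must be in [0, 0.5)")
  if (min_mean_phred < 0 || min_mean_phred > 41) stopf("bad quality threshold")
  if (flank[1] < 1L || flank[1] > flank[2]) stopf("invalid flank range")
  if (n_boot < 1L) stopf("n_boot must be >= 1")
  if (is.null(sim) && (is.null(reads) || is.null(transcriptome) ||
                       is.null(annotation)))
    stopf("either `sim` or reads+transcriptome+annotation paths required")
  if (!is.null(sim)) validate_sim_spec(sim)
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields map 1:1 to [run_config()] arguments; a `sim:` block is
#' passed to [sim_spec()].
#'
#' @param path YAML file path.
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_spec, y$sim)
  do.call(run_config, y)
}

#' Run the full footprint analysis pipeline
#'
#' simulate (optional) -> preprocess -> P-site calibration -> coverage ->
#' start/stop metagenes -> motif scan and pause scores, with every
#' intermediate written under `out_dir` and a machine-readable JSON run
#' report. Identical config + seed reproduce byte-identical output tables.
#'
#' @param config A validated [run_config()].
#' @return `run_report` list: ledger, offset table, spike-in summary,
#'   output file paths, aggregate pause scores, resolved config hash and
#'   seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (is.null(out)) stopf("run_pipeline: out_dir required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[ribopause] %-12s %6.1fs", name,
                                          proc.time()[["elapsed"]] - t0))

  # --- input: simulate or load -------------------------------------------
  if (!is.null(config$sim)) {
    stage("simulate")
    txome <- generate_transcriptome(config$sim)
    write_transcriptome(txome, out)
    lib <- simulate_library(txome)
    write_fastq(lib$reads, file.path(out, "reads.fastq"))
    fwrite(lib$truth, file.path(out, "read_truth.tsv"), sep = "\t")
    reads <- lib$reads
    seqs <- txome$sequences
    ann <- txome$annotation
    adapter <- config$sim$adapter
  } else {
    stage("load")
    txm <- read_transcriptome(config$transcriptome, config$annotation)
    seqs <- txm$sequences
    ann <- txm$annotation
    reads <- read_fastq(config$reads)
    adapter <- config$adapter
  }
  contam <- if (!is.null(config$sim)) {
    if (config$sim$frac_contaminant > 0) contaminant_sequences() else NULL
  } else if (!is.null(config$contaminants)) {
    Biostrings::readDNAStringSet(config$contaminants)
  } else NULL

  # --- preprocess ---------------------------------------------------------
  stage("preprocess")
  pp <- preprocess_reads(reads, seqs, contam, adapter = adapter,
                         min_mean_phred = config$min_mean_phred,
                         min_len = config$min_len, max_len = config$max_len)
  if (!ledger_conserved(pp$ledger))
    stopf("stage preprocess: ledger conservation violated")
  fwrite(pp$ledger, file.path(out, "filter_ledger.tsv"), sep = "\t")
  export_sam(pp$alignments, seqs, file.path(out, "alignments.sam"))

  # --- P-site calibration and coverage ------------------------------------
  stage("psite")
  offs <- calibrate_offsets(pp$alignments, ann,
                            lengths = config$min_len:config$max_len,
                            min_support = config$min_support,
                            window = config$calibration_window)
  write_psite_tsv(offs, file.path(out, "psite_offsets.tsv"))
  cov <- psite_coverage(pp$alignments, offs, ann)
  if (!coverage_conserved(cov, nrow(pp$alignments)))
    stopf("stage psite: coverage conservation violated")

  spike <- species_counts(pp$alignments)
  spike_summary <- NULL
  if (config$spike_normalize) {
    spike_summary <- spikein_factors(c(run = spike[["spike"]]))
    cov <- normalize_coverage(cov, spike_summary$factor[1])
  }
  write_psite_tsv(cov, file.path(out, "codon_coverage.tsv"))

  # --- metagenes ----------------------------------------------------------
  stage("metagene")
  prof_start <- metagene_profile(cov, "start", config$start_window,
                                 config$trim_frac)
  prof_stop <- metagene_profile(cov, "stop", config$stop_window,
                                config$trim_frac)
  write_profile_tsv(prof_start, file.path(out, "metagene_start.tsv"))
  write_profile_tsv(prof_stop, file.path(out, "metagene_stop.tsv"))

  # --- motifs and pause scores -------------------------------------------
  stage("pause")
  score_paths <- character(0)
  aggregates <- list()
  for (mot in config$motifs) {
    occ <- scan_motifs(seqs, ann[ann$species == "primary", ], mot)
    sc <- pause_scores(cov, occ, flank = config$flank,
                       floor = config$bg_floor)
    p <- file.path(out, sprintf("pause_scores_%s.tsv", mot))
    fwrite(as.data.table(sc), p, sep = "\t")
    prof <- motif_metagene(cov, occ, trim_frac = config$trim_frac,
                           flank = config$flank, floor = config$bg_floor)
    write_profile_tsv(prof, file.path(out, sprintf("motif_metagene_%s.tsv", mot)))
    score_paths <- c(score_paths, p)
    aggregates[[mot]] <- list(median_score = attr(sc, "median_score"),
                              n_usable = attr(sc, "n_usable"))
  }

  # --- report -------------------------------------------------------------
  stage("report")
  cfg_path <- file.path(out, "config_resolved.json")
  cfg_json <- config
  cfg_json$out_dir <- NULL  # hash covers analysis settings, not output paths
  cfg_json$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  jsonlite::write_json(unclass(cfg_json), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  report <- list(
    ledger = as.list(pp$ledger),
    offsets = as.data.frame(offs),
    spikein = if (is.null(spike_summary)) as.list(spike) else
      c(as.list(spike), list(factor = spike_summary$factor[1])),
    files = list(
      offsets = file.path(out, "psite_offsets.tsv"),
      coverage = file.path(out, "codon_coverage.tsv"),
      metagene_start = file.path(out, "metagene_start.tsv"),
      metagene_stop = file.path(out, "metagene_stop.tsv"),
      pause_scores = score_paths
    ),
    pause_aggregates = aggregates,
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    version = as.character(utils::packageVersion("ribopause"))
  )
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("ribopause run report (seed", x$seed, ")\n")
  cat("  ledger:", paste(names(x$ledger), unlist(x$ledger), sep = "=",
                         collapse = " "), "\n")
  for (m in names(x$pause_aggregates))
    cat(sprintf("  %s: median pause score %.3f (n = %d usable)\n", m,
                x$pause_aggregates[[m]]$median_score,
                x$pause_aggregates[[m]]$n_usable))
  invisible(x)
}
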