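# internal helpers shared across modules

# geometric mean of a strictly positive vector
geo_mean <- function(x) exp(mean(log(x)))

# uniform integer draw in [lo, hi] for each of n items
runif_int <- function(n, lo, hi) {
  if (hi < lo) stop("inverted range [", lo, ", ", hi, "]")
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# codons grouped by the amino acid they encode (standard genetic code)
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# sample one synonymous codon per residue, vectorised over a residue vector
sample_codons <- function(residues, codon_table = codons_by_aa()) {
  out <- character(length(residues))
  for (aa in unique(residues)) {
    idx <- which(residues == aa)
    cods <- codon_table[[aa]]
    if (is.null(cods)) stop("no codon for residue '", aa, "'")
    out[idx] <- cods[sample.int(length(cods), length(idx), replace = TRUE)]
  }
  out
}

# mean Phred score per read from Phred+33 quality strings (vectorised)
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

# translate an in-frame CDS nucleotide string to amino acids ('*' = stop)
translate_cds <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# derive a stream-specific 32-bit seed from a user seed
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1103 * stream) %% 2147483647)
}
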