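#' @import GenomicRanges IRanges S4Vectors
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq GENETIC_CODE
#' @importFrom stats rnbinom rpois rnorm runif setNames t.test pchisq
#' @importFrom utils read.table write.table
NULL

# strand-aware reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# DNA <-> RNA alphabet (internal sequence work is DNA; seed scanning uses RNA)
dna2rna <- function(x) chartr("Tt", "Uu", toupper(x))
rna2dna <- function(x) chartr("Uu", "Tt", toupper(x))

check_alphabet <- function(x, extra = "", what = "sequence") {
  bad <- grepl(sprintf("[^ACGTU%s]", extra), toupper(x))
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet in entry %d", what, which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct zero-padded circRNA identifiers
#'
#' Junctions are sorted by (chrom, start, end, strand) and numbered
#' sequentially with six-digit zero padding, e.g. `circ_mm_000042`.
#'
#' @param n number of identifiers
#' @param prefix identifier prefix
#' @return character vector of ids
#' @keywords internal
make_circ_ids <- function(n, prefix = "circ") {
  sprintf("%s_%06d", prefix, seq_len(n))
}

# order of a GRanges by (chrom, start, end, strand)
canonical_order <- function(gr) {
  order(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr),
        as.character(GenomicRanges::strand(gr)))
}

# derive a substream seed from a root seed (kept below 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
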