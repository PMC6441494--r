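# shared fixtures, built in code and memoized across test files

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_bundle <- function() {
  cached("bundle_nb", generate_dataset(synthetic_config(), seed = 1))
}

noiseless_bundle <- function() {
  cached("bundle_none", generate_dataset(synthetic_config(noise = "none"), seed = 1))
}

default_run <- function() {
  cached("run_nb", run_pipeline(default_bundle(), seed = 1))
}

noiseless_run <- function() {
  cached("run_none", run_pipeline(noiseless_bundle(), seed = 1))
}

# a small hand-built annotation: two genes on chr1 (one plus, one minus),
# gene A with three exons, gene B with two
toy_annotation <- function() {
  ex <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(101, 301, 501, 2001, 2501),
                     end = c(200, 400, 600, 2100, 2600)),
    strand = c("+", "+", "+", "-", "-"),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB"),
    transcript_id = c("txA1", "txA1", "txA1", "txB1", "txB1"))
  build_annotation(ex)
}

toy_junction <- function(start, end, strand = "+", chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                         name = "j1", support = 2)
}

# uniform codon usage (all w = 1)
uniform_usage <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  u <- setNames(rep(1, length(sense)), sense)
  u * 1000 / sum(u)
}

# biased usage: first codon of each family favoured (same shape as the
# generator's table but built independently here)
biased_usage <- function(ratio = 4) {
  code <- Biostrings::GENETIC_CODE
  sense <- sort(names(code)[code != "*"])
  aa <- code[sense]
  u <- setNames(numeric(length(sense)), sense)
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    u[fam] <- c(ratio, rep(1, length(fam) - 1))
  }
  u * 1000 / sum(u)
}

random_orf <- function(n_codons, w) {
  paste(sample(names(w), n_codons, replace = TRUE), collapse = "")
}

# independent order-1 Markov sampler used as a Monte-Carlo oracle for eCAI:
# plain count-based transition fit (no pseudocount), column-wise emission,
# direct-product CAI, type-7 quantile
oracle_ecai <- function(pool, w, n_draws, confidence = 0.95) {
  bases <- strsplit(paste(pool, collapse = ""), "")[[1]]
  ab <- c("A", "C", "G", "T")
  p0 <- table(factor(bases, ab)) / length(bases)
  tf <- table(factor(bases[-length(bases)], ab), factor(bases[-1], ab))
  tf <- tf / rowSums(tf)
  lens <- nchar(pool)
  n_i <- (sample(lens, n_draws, replace = TRUE) %/% 3L) * 3L
  l_max <- max(n_i)
  m <- matrix(NA_character_, n_draws, l_max)
  m[, 1] <- sample(ab, n_draws, replace = TRUE, prob = p0)
  for (j in 2:l_max) {
    for (b in ab) {
      sel <- which(m[, j - 1] == b)
      if (length(sel)) m[sel, j] <- sample(ab, length(sel), replace = TRUE,
                                           prob = tf[b, ])
    }
  }
  stops <- c("TAA", "TAG", "TGA")
  cais <- vapply(seq_len(n_draws), function(i) {
    s <- paste(m[i, seq_len(n_i[i])], collapse = "")
    starts <- seq(1, n_i[i], by = 3)
    cod <- substring(s, starts, starts + 2)
    # oracle handles internal stops by dropping them (the implementation
    # resamples; both leave a stop-free codon sample from the same chain)
    cod <- cod[!cod %in% stops]
    if (!length(cod)) return(NA_real_)
    prod(w[cod])^(1 / length(cod))
  }, numeric(1))
  as.numeric(quantile(cais[!is.na(cais)], confidence))
}
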