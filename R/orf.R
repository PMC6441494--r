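STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames
#'
#' Searches the given strand only, in all three frames, for ATG-initiated
#' ORFs of at least `min_len` nucleotides (stop codon included in the
#' length). Within a stop-to-stop segment only the 5'-most ATG is reported:
#' ORFs nested in a longer same-frame ORF are suppressed. ORFs reaching the
#' sequence end without a stop codon are reported open-ended and flagged.
#' In circular mode the doubled sequence is scanned so that ORFs spanning
#' the backsplice junction are found; they are reported once, at their
#' modular start, with length capped at the sequence length.
#'
#' @param sequence nucleotide sequence (DNA or RNA alphabet)
#' @param min_len minimum ORF length in nt, stop codon included (default 150)
#' @param circular_mode also search across the junction (default `FALSE`,
#'   matching a linear-FASTA search)
#' @return data.frame with `start` (0-based), `end` (exclusive; may exceed
#'   the sequence length in circular mode before capping), `length`,
#'   `frame` (0-2), `open_ended`, `orf_seq`
#' @export
find_orfs <- function(sequence, min_len = 150, circular_mode = FALSE) {
  s <- rna2dna(sequence)
  check_alphabet(s, what = "ORF search")
  L <- nchar(s)
  if (L < 3L) stop("sequence shorter than one codon", call. = FALSE)
  scan_s <- if (circular_mode) paste0(s, s) else s
  orfs <- find_orfs_linear(scan_s, min_len)
  if (circular_mode && nrow(orfs)) {
    orfs <- orfs[orfs$start < L, , drop = FALSE]
    # cap junction-spanning ORFs at one full pass around the circle
    too_long <- orfs$length > L
    if (any(too_long)) {
      capped <- (L %/% 3L) * 3L
      orfs$length[too_long] <- capped
      orfs$end[too_long] <- orfs$start[too_long] + capped
      orfs$open_ended[too_long] <- TRUE
      orfs$orf_seq[too_long] <- substr(orfs$orf_seq[too_long], 1L, capped)
      orfs <- orfs[orfs$length >= min_len, , drop = FALSE]
    }
    # the same linear ORF found in both copies collapses to one record
    orfs <- orfs[!duplicated(paste(orfs$start %% L, orfs$length)), , drop = FALSE]
  }
  rownames(orfs) <- NULL
  orfs
}

find_orfs_linear <- function(s, min_len) {
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + seq(1L, by = 3L, length.out = n_codons)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg_start <- 1L
    stops <- c(which(is_stop), NA_integer_)
    for (st in stops) {
      seg_end <- if (is.na(st)) n_codons else st
      if (seg_end >= seg_start) {
        atg <- which(is_atg[seg_start:seg_end])
        if (length(atg)) {
          i <- seg_start + atg[1L] - 1L  # 5'-most ATG; nested ones suppressed
          len <- (seg_end - i + 1L) * 3L
          if (len >= min_len) {
            start0 <- starts[i] - 1L
            out[[length(out) + 1L]] <- data.frame(
              start = start0, end = start0 + len, length = len, frame = frame,
              open_ended = is.na(st),
              orf_seq = substr(s, starts[i], starts[i] + len - 1L)
            )
          }
        }
      }
      if (is.na(st)) break
      seg_start <- st + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      frame = integer(), open_ended = logical(),
                      orf_seq = character()))
  }
  do.call(rbind, out)
}

#' Relative adaptiveness of codons
#'
#' `w(codon) = usage(codon) / max usage within its synonymous family`
#' (Sharp & Li). Codons of single-codon amino acids (Met, Trp) have `w = 1`.
#'
#' @param usage named numeric vector of per-thousand codon frequencies
#'   (see [read_codon_usage()])
#' @return named numeric vector `w` over the 61 sense codons, values in (0,1]
#' @export
relative_adaptiveness <- function(usage) {
  validate_codon_usage(usage)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  u <- usage[sense]
  fam_max <- tapply(u, aa, max)
  setNames(as.numeric(u / fam_max[aa]), sense)
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over the codons of an
#' ORF, stop codons excluded. Computed as `exp(mean(log w))` for numerical
#' stability.
#'
#' @param orf_seq ORF nucleotide sequence, length divisible by 3
#' @param w relative-adaptiveness table from [relative_adaptiveness()]
#' @return CAI in (0, 1]
#' @export
cai <- function(orf_seq, w) {
  s <- rna2dna(orf_seq)
  if (nchar(s) %% 3L != 0L) stop("ORF length must be divisible by 3", call. = FALSE)
  starts <- seq(1L, nchar(s), by = 3L)
  codons <- substring(s, starts, starts + 2L)
  codons <- codons[!codons %in% STOP_CODONS]
  if (!length(codons)) stop("ORF contains only stop codons", call. = FALSE)
  exp(mean(log(w[codons])))
}

# fit an order-k nucleotide Markov model (k in 0..2) to a pool of sequences
markov_fit <- function(seqs, order = 1) {
  stopifnot(order %in% 0:2)
  s <- paste(rna2dna(seqs), collapse = "")
  bases <- strsplit(s, "")[[1]]
  if (length(unique(bases)) < 2L) {
    stop("degenerate sequence pool: fewer than two distinct bases", call. = FALSE)
  }
  alphabet <- c("A", "C", "G", "T")
  base_freq <- table(factor(bases, alphabet))
  p0 <- as.numeric(base_freq) / sum(base_freq)
  trans <- NULL
  if (order >= 1) {
    ctx <- do.call(paste0, lapply(seq_len(order), function(k) {
      bases[seq_len(length(bases) - order) + k - 1L]
    }))
    nxt <- bases[(order + 1L):length(bases)]
    states <- apply(expand.grid(rep(list(alphabet), order)), 1, paste0, collapse = "")
    tab <- table(factor(ctx, states), factor(nxt, alphabet)) + 0.5  # pseudocount
    trans <- tab / rowSums(tab)
  }
  structure(list(order = order, p0 = setNames(p0, alphabet), trans = trans,
                 alphabet = alphabet), class = "markov_model")
}

# emit a batch of random sequences (vectorized over sequences per position)
markov_emit_batch <- function(model, lengths) {
  a <- model$alphabet
  n_seq <- length(lengths)
  l_max <- max(lengths)
  mat <- matrix(NA_character_, n_seq, l_max)
  if (model$order == 0L) {
    mat[] <- sample(a, n_seq * l_max, replace = TRUE, prob = model$p0)
  } else {
    k <- model$order
    for (j in seq_len(l_max)) {
      if (j <= k) {
        mat[, j] <- sample(a, n_seq, replace = TRUE, prob = model$p0)
      } else {
        ctx <- if (k == 1L) mat[, j - 1L] else
          do.call(paste0, lapply((j - k):(j - 1L), function(c0) mat[, c0]))
        for (st in unique(ctx)) {
          sel <- which(ctx == st)
          mat[sel, j] <- sample(a, length(sel), replace = TRUE,
                                prob = model$trans[st, ])
        }
      }
    }
  }
  vapply(seq_len(n_seq), function(i)
    paste(mat[i, seq_len(lengths[i])], collapse = ""), character(1))
}

# emit one random sequence of length n from a fitted model
markov_emit <- function(model, n) {
  a <- model$alphabet
  out <- character(n)
  if (model$order == 0L) {
    return(paste(sample(a, n, replace = TRUE, prob = model$p0), collapse = ""))
  }
  for (i in seq_len(n)) {
    if (i <= model$order) {
      out[i] <- sample(a, 1, prob = model$p0)
    } else {
      ctx <- paste(out[(i - model$order):(i - 1L)], collapse = "")
      out[i] <- sample(a, 1, prob = model$trans[ctx, ])
    }
  }
  paste(out, collapse = "")
}

# replace internal stop codons by resampling the offending codon from the model
scrub_internal_stops <- function(seq, model) {
  n_codons <- nchar(seq) %/% 3L
  if (n_codons < 2L) return(seq)
  repeat {
    starts <- seq(1L, by = 3L, length.out = n_codons - 1L)
    codons <- substring(seq, starts, starts + 2L)
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) return(seq)
    for (i in bad) {
      tries <- 0L
      repl <- markov_emit(model, 3L)
      while (repl %in% STOP_CODONS && tries < 100L) {
        repl <- markov_emit(model, 3L)
        tries <- tries + 1L
      }
      if (repl %in% STOP_CODONS) repl <- "GCT"
      substr(seq, starts[i], starts[i] + 2L) <- repl
    }
  }
}

#' Expected CAI under a Markov null
#'
#' Fits an order-`markov_order` nucleotide Markov model to the pooled ORF
#' population, emits `n_null` random sequences whose lengths are drawn with
#' replacement from the pool's length distribution (trimmed to whole codons,
#' internal stop codons resampled from the model), scores each with
#' [cai()], and returns the `confidence` quantile of the null CAI
#' distribution. The procedure is repeated `n_runs` times with derived
#' sub-seeds and the final eCAI is the average of the per-run quantiles.
#'
#' @param orf_seqs character vector: the observed ORF population
#' @param w relative-adaptiveness table
#' @param n_null null sequences per run (default 500)
#' @param markov_order nucleotide Markov order, 0-2 (default 1)
#' @param confidence quantile of the null distribution (default 0.95)
#' @param seed integer seed
#' @param n_runs independent runs averaged into the final value (default 5)
#' @return list with `ecai` (the averaged threshold), `per_run` quantiles,
#'   and `null_cai` (last run's null CAI values)
#' @export
ecai <- function(orf_seqs, w, n_null = 500, markov_order = 1, confidence = 0.95,
                 seed = 1, n_runs = 5) {
  stopifnot(length(orf_seqs) > 0)
  model <- markov_fit(orf_seqs, order = markov_order)
  lens <- nchar(orf_seqs)
  per_run <- numeric(n_runs)
  null_cai <- NULL
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, r))
    n_i <- sample(lens, n_null, replace = TRUE)
    n_i <- (n_i %/% 3L) * 3L
    n_i[n_i < 3L] <- 3L
    seqs <- markov_emit_batch(model, n_i)
    cais <- vapply(seqs, function(s) cai(scrub_internal_stops(s, model), w),
                   numeric(1), USE.NAMES = FALSE)
    per_run[r] <- as.numeric(quantile(cais, confidence))
    null_cai <- cais
  }
  list(ecai = mean(per_run), per_run = per_run, null_cai = null_cai)
}

#' Length-matched shuffled control sequence sets
#'
#' Draws random windows, length-matched to a reference length multiset,
#' uniformly from (1) the genome and (2) the concatenated transcript
#' sequences. These serve as negative-control inputs for ORF finding and
#' CAI scoring.
#'
#' @param genome `DNAStringSet` of chromosome sequences
#' @param transcript_seqs character vector or `DNAStringSet` of transcript
#'   sequences
#' @param lengths integer vector of window lengths to match
#' @param seed integer seed
#' @return list with `genomic` and `transcriptomic` character vectors, in
#'   the order of `lengths`
#' @export
shuffled_controls <- function(genome, transcript_seqs, lengths, seed = 1) {
  set.seed(derive_seed(seed, 77L))
  gl <- Biostrings::width(genome)
  genomic <- vapply(lengths, function(len) {
    feasible <- which(gl >= len)
    if (!length(feasible)) stop(sprintf("no chromosome can host a %d bp window", len),
                                call. = FALSE)
    chr <- feasible[sample.int(length(feasible), 1,
                               prob = gl[feasible] - len + 1)]
    st <- sample.int(gl[chr] - len + 1L, 1)
    as.character(Biostrings::subseq(genome[[chr]], st, st + len - 1L))
  }, character(1))
  tx <- paste(as.character(transcript_seqs), collapse = "")
  if (nchar(tx) < max(lengths)) {
    stop("transcriptome shorter than the longest requested window", call. = FALSE)
  }
  transcriptomic <- vapply(lengths, function(len) {
    st <- sample.int(nchar(tx) - len + 1L, 1)
    substr(tx, st, st + len - 1L)
  }, character(1))
  list(genomic = genomic, transcriptomic = transcriptomic)
}

#' Chi-squared test on a 2x2 contingency table
#'
#' Closed-form Pearson statistic without continuity correction,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to the chi-squared
#' distribution with one degree of freedom.
#'
#' @param a,b,c,d cell counts, row-wise: `[[a, b], [c, d]]`
#' @return list with `statistic`, `df = 1`, `p_value`
#' @export
chi2_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all table margins must be positive", call. = FALSE)
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
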