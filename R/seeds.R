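# Nearest-neighbor free-energy parameters for Watson-Crick RNA stacks
# (Turner 2004 dG37, kcal/mol), keyed by the 5'->3' dinucleotide on one
# strand; symmetric equivalents expanded. Duplex initiation +4.09.
NN_STACK <- c(
  AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
  CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
  CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42
)
NN_INIT <- 4.09

COMP_RNA <- c(A = "U", C = "G", G = "C", U = "A")

#' Scan a circRNA sequence for seed sites of one miRNA
#'
#' Finds every site whose target hexamer is the Watson-Crick reverse
#' complement of miRNA positions 2-7 (the 6mer core), then assigns the Bartel
#' seed category: upgraded to `7mer-m8` when the target also pairs miRNA
#' position 8, to `7mer-A1` when the target carries an `A` opposite miRNA
#' position 1, and to `8mer` when both hold. In circular mode (default) the
#' first `nchar(miRNA) - 1` bases are appended to the end of the sequence so
#' junction-spanning sites are found, and sites are de-duplicated by modular
#' position; rotating the sequence therefore yields the same multiset of
#' (category, site) calls.
#'
#' @param circ_seq circRNA mature sequence (character, DNA or RNA alphabet;
#'   `T` and `U` are equivalent)
#' @param mirna_seq mature miRNA sequence 5'->3' (length >= 8)
#' @param circular scan across the backsplice junction (default `TRUE`)
#' @param with_scores compute alignment score and duplex dG per site
#' @return data.frame with `start` (0-based position of the 6mer core on the
#'   mature sequence), `category`, and (if requested) `score` and `dg`
#' @export
scan_seeds <- function(circ_seq, mirna_seq, circular = TRUE, with_scores = TRUE) {
  s <- dna2rna(circ_seq)
  m <- dna2rna(mirna_seq)
  check_alphabet(s, what = "target")
  check_alphabet(m, what = "miRNA")
  if (nchar(m) < 8L) stop("miRNA must be at least 8 nt", call. = FALSE)
  L <- nchar(s)
  empty <- data.frame(start = integer(), category = character(),
                      score = numeric(), dg = numeric())
  if (L < 6L) return(empty)
  mb <- strsplit(m, "")[[1]]
  core <- paste(rev(COMP_RNA[mb[2:7]]), collapse = "")  # target 6mer, 5'->3'
  ext <- if (circular) paste0(s, substr(s, 1L, min(nchar(m) - 1L, L))) else s
  # overlapping occurrences matter for low-complexity cores
  pos <- find_all_occurrences(ext, core)
  pos <- pos[pos <= L]
  if (!length(pos)) return(empty)
  sb <- strsplit(s, "")[[1]]
  base_at <- function(q) {
    if (circular) sb[((q - 1L) %% L) + 1L]
    else if (q >= 1L && q <= L) sb[q] else NA_character_
  }
  category <- vapply(pos, function(p) {
    m8 <- base_at(p - 1L)
    a1 <- base_at(p + 6L)
    has_m8 <- !is.na(m8) && m8 == COMP_RNA[[mb[8]]]
    has_a1 <- !is.na(a1) && a1 == "A"
    if (has_m8 && has_a1) "8mer"
    else if (has_m8) "7mer-m8"
    else if (has_a1) "7mer-A1"
    else "6mer"
  }, character(1))
  out <- data.frame(start = pos - 1L, category = category)
  if (with_scores) {
    out$score <- vapply(pos, function(p)
      site_score(site_context(s, p, nchar(m), circular), m), numeric(1))
    out$dg <- vapply(pos, function(p)
      site_energy(s, p - 1L, m, circular), numeric(1))
  }
  out
}

find_all_occurrences <- function(text, pattern) {
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)
    if (p == -1L) break
    hits <- c(hits, from + p - 1L)
    from <- from + p
  }
  hits
}

# target context around a site: core 6mer +/- one miRNA length
site_context <- function(s, core_start, mir_len, circular) {
  L <- nchar(s)
  lo <- core_start - mir_len
  hi <- core_start + 5L + mir_len
  if (circular) {
    idx <- ((seq(lo, hi) - 1L) %% L) + 1L
    paste(strsplit(s, "")[[1]][idx], collapse = "")
  } else {
    substr(s, max(1L, lo), min(L, hi))
  }
}

#' Local complementarity alignment score of a miRNA against a target context
#'
#' Smith-Waterman local alignment of the miRNA against the reverse complement
#' of the target context, scoring +5 per Watson-Crick pair, +1 per G:U
#' wobble, -3 per mismatch, with gap open 8 and gap extend 2. A perfect
#' complement of an n-nt miRNA scores 5n. The scoring scheme is a documented,
#' configurable complementarity scorer, not a byte-compatible reimplementation
#' of any particular alignment tool.
#'
#' @param context target sequence context (5'->3')
#' @param mirna_seq miRNA sequence (5'->3')
#' @param match,wobble,mismatch,gap_open,gap_extend scoring parameters
#' @return numeric alignment score
#' @export
site_score <- function(context, mirna_seq, match = 5, wobble = 1, mismatch = -3,
                       gap_open = 8, gap_extend = 2) {
  # in complement space WC pairs become identities and G:U wobbles become
  # (G,A) and (U,C) against the reverse-complemented target
  sub <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                c("A", "C", "G", "T")))
  diag(sub) <- match
  sub["G", "A"] <- wobble
  sub["T", "C"] <- wobble
  p1 <- Biostrings::DNAString(rna2dna(mirna_seq))
  p2 <- Biostrings::reverseComplement(Biostrings::DNAString(rna2dna(context)))
  aln <- Biostrings::pairwiseAlignment(p1, p2, type = "local",
                                       substitutionMatrix = sub,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  Biostrings::score(aln)
}

#' Duplex free energy of a seed site
#'
#' Extends the perfect Watson-Crick pairing of the 6mer core in both
#' directions along the miRNA (positions 1 and 8, 9, ... while
#' complementarity holds), then sums nearest-neighbor stacking free energies
#' (Turner dG37 parameters) over the paired run plus the duplex initiation
#' term. More extended complementarity therefore always gives a lower
#' (more favourable) dG.
#'
#' @param circ_seq target sequence (mature circRNA)
#' @param site_start0 0-based start of the 6mer core (from [scan_seeds()])
#' @param mirna_seq miRNA sequence 5'->3'
#' @param circular allow pairing across the backsplice junction
#' @return dG in kcal/mol (finite; negative for favourable duplexes)
#' @export
site_energy <- function(circ_seq, site_start0, mirna_seq, circular = TRUE) {
  s <- dna2rna(circ_seq)
  m <- dna2rna(mirna_seq)
  L <- nchar(s)
  p <- site_start0 + 1L
  sb <- strsplit(s, "")[[1]]
  mb <- strsplit(m, "")[[1]]
  base_at <- function(q) {
    if (circular) sb[((q - 1L) %% L) + 1L]
    else if (q >= 1L && q <= L) sb[q] else NA_character_
  }
  paired <- function(k) {
    t <- base_at(p + 7L - k)  # target position opposite miRNA position k
    !is.na(t) && t == COMP_RNA[[mb[k]]]
  }
  k_hi <- 7L
  while (k_hi + 1L <= length(mb) && paired(k_hi + 1L)) k_hi <- k_hi + 1L
  k_lo <- if (paired(1L)) 1L else 2L
  run <- paste(mb[k_lo:k_hi], collapse = "")
  dinucs <- substring(run, seq_len(nchar(run) - 1L), 2:nchar(run))
  NN_INIT + sum(NN_STACK[dinucs])
}

#' Scan a set of circRNA sequences against a miRNA library
#'
#' @param circ_seqs named character vector or `DNAStringSet` of mature
#'   circRNA sequences
#' @param mirnas named character vector or `RNAStringSet` of mature miRNA
#'   sequences
#' @param circular scan across the backsplice junction
#' @param with_scores compute per-site score and dG
#' @return data.frame with `circ_id`, `mirna_id`, `start`, `category`, and
#'   optionally `score`, `dg`
#' @export
seed_scan <- function(circ_seqs, mirnas, circular = TRUE, with_scores = TRUE) {
  circ_seqs <- setNames(as.character(circ_seqs), names(circ_seqs))
  mirnas <- setNames(as.character(mirnas), names(mirnas))
  res <- list()
  for (ci in names(circ_seqs)) {
    for (mi in names(mirnas)) {
      hits <- scan_seeds(circ_seqs[[ci]], mirnas[[mi]], circular = circular,
                         with_scores = with_scores)
      if (nrow(hits)) {
        hits$circ_id <- ci
        hits$mirna_id <- mi
        res[[length(res) + 1L]] <- hits
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), category = character(),
                      score = numeric(), dg = numeric(),
                      circ_id = character(), mirna_id = character()))
  }
  do.call(rbind, res)
}

#' Filter seed matches and count unique circRNA-miRNA combinations
#'
#' Applies the alignment-score and free-energy gates (defaults: score >= 150,
#' dG <= -19 kcal/mol), counts surviving sites per (circRNA, miRNA) pair,
#' and summarizes per circRNA: the maximum number of sites for any single
#' miRNA and the number of distinct miRNAs with at least one surviving site.
#' Pass `min_score = -Inf, max_dg = Inf` to disable the gates.
#'
#' @param matches data.frame from [seed_scan()]
#' @param min_score minimum alignment score
#' @param max_dg maximum (most positive) duplex dG
#' @return list with `counts` (circ_id, mirna_id, n_sites; sorted by
#'   decreasing count) and `summary` (circ_id, max_single_mirna,
#'   distinct_mirnas, total_sites)
#' @export
filter_and_count <- function(matches, min_score = 150, max_dg = -19) {
  keep <- matches$category %in% c("8mer", "7mer-m8", "7mer-A1", "6mer")
  if (!is.null(matches$score)) keep <- keep & matches$score >= min_score
  if (!is.null(matches$dg)) keep <- keep & matches$dg <= max_dg
  m <- matches[keep, , drop = FALSE]
  if (!nrow(m)) {
    return(list(
      counts = data.frame(circ_id = character(), mirna_id = character(),
                          n_sites = integer()),
      summary = data.frame(circ_id = character(), max_single_mirna = integer(),
                           distinct_mirnas = integer(), total_sites = integer())
    ))
  }
  agg <- aggregate(list(n_sites = m$start), by = list(circ_id = m$circ_id, mirna_id = m$mirna_id),
                   FUN = length)
  agg <- agg[order(-agg$n_sites, agg$circ_id, agg$mirna_id), ]
  rownames(agg) <- NULL
  summ <- do.call(rbind, lapply(split(agg, agg$circ_id), function(d) {
    data.frame(circ_id = d$circ_id[1],
               max_single_mirna = max(d$n_sites),
               distinct_mirnas = nrow(d),
               total_sites = sum(d$n_sites))
  }))
  summ <- summ[order(-summ$max_single_mirna, summ$circ_id), ]
  rownames(summ) <- NULL
  list(counts = agg, summary = summ)
}
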