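#' Classify backsplice junctions against a gene annotation
#'
#' Each junction is assigned one of four mutually exclusive classes:
#' \describe{
#'   \item{genic_exonic}{both junction ends coincide exactly (to the base)
#'     with boundaries of annotated exons of one same-strand gene}
#'   \item{genic_other}{overlaps a same-strand gene body by >= 1 bp but the
#'     boundary condition fails}
#'   \item{antisense}{overlaps gene(s) on the opposite strand only}
#'   \item{intergenic}{no gene overlap}
#' }
#' Exon boundaries are matched against the union of exon intervals across all
#' transcripts of a gene, projected to non-overlapping blocks. When several
#' same-strand genes overlap a junction, the host is the gene matching the
#' most boundaries, ties broken by lexicographically smaller gene id.
#' Junctions on chromosomes absent from the annotation are classified
#' intergenic with a warning.
#'
#' @param junctions `GRanges` of junction spans (see [read_junction_calls()])
#' @param annotation `circ_annotation` object
#' @param prefix id prefix for [make_circ_ids()]
#' @return `GRanges` sorted by (chrom, start, end, strand) with metadata
#'   columns `circ_id`, `circ_class`, `gene_id` (`NA` for
#'   antisense/intergenic), `n_exons` (`NA` unless genic-exonic), `support`
#' @export
classify_junctions <- function(junctions, annotation, prefix = "circ") {
  junctions <- junctions[canonical_order(junctions)]
  ann_chroms <- unique(as.character(GenomicRanges::seqnames(annotation$genes)))
  off <- !as.character(GenomicRanges::seqnames(junctions)) %in% ann_chroms
  if (any(off)) {
    warning(sprintf("%d junction(s) on chromosomes absent from the annotation; classified intergenic",
                    sum(off)), call. = FALSE)
  }
  genes <- annotation$genes
  # gene-body overlap, strand-aware and strand-blind views (seqinfo merge
  # warnings are redundant with the off-annotation warning above)
  hits_sense <- suppressWarnings(
    GenomicRanges::findOverlaps(junctions, genes, ignore.strand = FALSE))
  hits_any <- suppressWarnings(
    GenomicRanges::findOverlaps(junctions, genes, ignore.strand = TRUE))

  blocks <- exon_union_blocks(annotation)

  n <- length(junctions)
  jst <- GenomicRanges::start(junctions)
  jen <- GenomicRanges::end(junctions)
  circ_class <- character(n)
  gene_id <- rep(NA_character_, n)
  n_exons <- rep(NA_integer_, n)
  sense_by_junc <- split(S4Vectors::subjectHits(hits_sense), factor(S4Vectors::queryHits(hits_sense), seq_len(n)))
  any_by_junc <- split(S4Vectors::subjectHits(hits_any), factor(S4Vectors::queryHits(hits_any), seq_len(n)))
  for (i in seq_len(n)) {
    sense <- sense_by_junc[[i]]
    if (length(sense) == 0L) {
      circ_class[i] <- if (length(any_by_junc[[i]]) > 0L) "antisense" else "intergenic"
      next
    }
    cand <- names(genes)[sense]
    nb <- vapply(cand, function(g) {
      sum(jst[i] %in% blocks$start[[g]], jen[i] %in% blocks$end[[g]])
    }, integer(1))
    best <- cand[order(-nb, cand)][1]
    gene_id[i] <- best
    circ_class[i] <- if (max(nb) == 2L) "genic_exonic" else "genic_other"
    if (circ_class[i] == "genic_exonic") {
      n_exons[i] <- sum(blocks$start[[best]] >= jst[i] & blocks$end[[best]] <= jen[i])
    }
  }
  out <- junctions
  S4Vectors::mcols(out) <- NULL
  out$circ_id <- make_circ_ids(n, prefix)
  out$circ_class <- circ_class
  out$gene_id <- gene_id
  out$n_exons <- n_exons
  out$support <- junctions$support %||% rep(NA_real_, n)
  out
}

# union of exon intervals per gene, projected to non-overlapping blocks;
# returned as plain per-gene start/end vectors (sorted by start)
exon_union_blocks <- function(annotation) {
  ex <- annotation$exons
  red <- unlist(GenomicRanges::reduce(GenomicRanges::split(ex, ex$gene_id)))
  g <- names(red)
  list(start = split(GenomicRanges::start(red), g),
       end = split(GenomicRanges::end(red), g))
}

#' Decompose circRNAs into exon and intron features
#'
#' Genic-exonic circRNAs are decomposed into the union exon blocks of their
#' host gene that fall boundary-to-boundary within the span, with intron
#' features filling the gaps between consecutive exon blocks (exons and
#' introns alternate and tile the span). circRNAs of every other class are
#' treated as a single exon feature covering the whole span.
#'
#' @param circs classified `GRanges` from [classify_junctions()]
#' @param annotation `circ_annotation` object
#' @return `GRanges` of features with `circ_id`, `kind` ("exon"/"intron"),
#'   `ordinal` (1-based position along the genomic span)
#' @export
decompose_features <- function(circs, annotation) {
  blocks <- exon_union_blocks(annotation)
  chroms <- as.character(GenomicRanges::seqnames(circs))
  strands <- as.character(GenomicRanges::strand(circs))
  jst <- GenomicRanges::start(circs)
  jen <- GenomicRanges::end(circs)
  feats <- vector("list", length(circs))
  for (i in seq_along(circs)) {
    if (circs$circ_class[i] == "genic_exonic") {
      g <- circs$gene_id[i]
      sel <- blocks$start[[g]] >= jst[i] & blocks$end[[g]] <= jen[i]
      if (!any(sel)) {
        stop(sprintf("internal inconsistency: genic_exonic circRNA %s has no exon blocks in span",
                     circs$circ_id[i]), call. = FALSE)
      }
      es <- blocks$start[[g]][sel]
      ee <- blocks$end[[g]][sel]
      d <- data.frame(start = es, end = ee, kind = "exon")
      if (length(es) > 1L) {
        d <- rbind(d, data.frame(start = ee[-length(ee)] + 1L,
                                 end = es[-1] - 1L, kind = "intron"))
      }
      d <- d[order(d$start), ]
    } else {
      d <- data.frame(start = jst[i], end = jen[i], kind = "exon")
    }
    d$chrom <- chroms[i]
    d$strand <- strands[i]
    d$circ_id <- circs$circ_id[i]
    d$ordinal <- seq_len(nrow(d))
    feats[[i]] <- d
  }
  fdf <- do.call(rbind, feats)
  GenomicRanges::GRanges(fdf$chrom, IRanges::IRanges(fdf$start, fdf$end),
                         strand = fdf$strand, kind = fdf$kind,
                         circ_id = fdf$circ_id, ordinal = fdf$ordinal)
}

#' Reconstruct the mature circRNA sequence
#'
#' Concatenates the exon features only (introns are excluded from mature
#' sequences throughout the pipeline) in transcription order, reverse
#' complementing minus-strand circRNAs. The returned string is one linear
#' pass around the circle starting at the 5'-most exonic base of the
#' transcript.
#'
#' @param circs classified `GRanges`
#' @param features feature `GRanges` from [decompose_features()]
#' @param genome `DNAStringSet` of chromosome sequences
#' @return named `DNAStringSet` (names = circ ids)
#' @export
reconstruct_sequences <- function(circs, features, genome) {
  ex <- features[features$kind == "exon"]
  chrom <- as.character(GenomicRanges::seqnames(ex))
  bad <- !chrom %in% names(genome)
  if (any(bad)) {
    stop(sprintf("feature on chromosome '%s' absent from genome", chrom[which(bad)[1]]),
         call. = FALSE)
  }
  over <- GenomicRanges::end(ex) > Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(over)) {
    stop(sprintf("feature of %s extends beyond chromosome end", ex$circ_id[which(over)[1]]),
         call. = FALSE)
  }
  pieces <- as.character(Biostrings::subseq(
    genome[chrom], start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)))
  seqs <- vapply(split(pieces, factor(ex$circ_id, unique(ex$circ_id))),
                 paste0, character(1), collapse = "")
  minus <- as.character(GenomicRanges::strand(circs))[match(names(seqs), circs$circ_id)] == "-"
  seqs[minus] <- revcomp(seqs[minus])
  out <- Biostrings::DNAStringSet(seqs)
  out[circs$circ_id[circs$circ_id %in% names(out)]]
}

#' Compare circRNAs against an external catalog by reciprocal overlap
#'
#' A circRNA is "known" at reciprocal fraction `f` if some catalog interval on
#' the same chromosome overlaps it such that overlap/length >= `f` for both
#' intervals. In single-nucleotide mode any 1-bp overlap counts. The maximal
#' level passed from `levels` is reported per circRNA.
#'
#' @param circs `GRanges` of circRNAs
#' @param catalog `GRanges` of catalog intervals
#' @param min_frac the reciprocal fraction defining `known` (0 < f <= 1)
#' @param single_nt if `TRUE`, any >= 1 bp overlap counts as known
#' @param levels overlap-level ladder reported per circRNA
#' @param ignore_strand compare coordinates only (default), as catalogs often
#'   lack reliable strand
#' @return data.frame with `circ_id`, `known`, `best_reciprocal`,
#'   `overlap_level` (`NA` if no overlap; `"single_nt"` when only a 1-bp
#'   overlap criterion is met)
#' @export
catalog_overlap <- function(circs, catalog, min_frac = 0.9, single_nt = FALSE,
                            levels = c(1, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5),
                            ignore_strand = TRUE) {
  stopifnot(min_frac > 0, min_frac <= 1)
  hits <- GenomicRanges::findOverlaps(circs, catalog, ignore.strand = ignore_strand)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    circs[S4Vectors::queryHits(hits)], catalog[S4Vectors::subjectHits(hits)],
    ignore.strand = ignore_strand))
  recip <- pmin(ov / GenomicRanges::width(circs)[S4Vectors::queryHits(hits)],
                ov / GenomicRanges::width(catalog)[S4Vectors::subjectHits(hits)])
  best <- rep(0, length(circs))
  agg <- tapply(recip, S4Vectors::queryHits(hits), max)
  best[as.integer(names(agg))] <- agg
  has_ov <- seq_along(circs) %in% S4Vectors::queryHits(hits)
  level <- vapply(seq_along(circs), function(i) {
    passed <- levels[levels <= best[i]]
    if (length(passed)) as.character(max(passed))
    else if (has_ov[i]) "single_nt"
    else NA_character_
  }, character(1))
  known <- if (single_nt) has_ov else best >= min_frac
  data.frame(
    circ_id = circs$circ_id %||% as.character(seq_along(circs)),
    known = known,
    best_reciprocal = best,
    overlap_level = level
  )
}
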