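#' Read backsplice junction calls (BED-like)
#'
#' Reads the tab- or space-delimited output of a backsplice-junction caller.
#' The first six columns are interpreted as BED6 (chrom, start, end, name,
#' score, strand); the score column carries the junction read support. No
#' filter is applied on read support: every well-formed record is kept.
#' Coordinates are converted from BED (0-based half-open) to the 1-based
#' closed convention of [GenomicRanges::GRanges].
#'
#' @param path path to the junction file
#' @return `GRanges` with metadata columns `name` and `support`
#' @export
read_junction_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(name = character(), support = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed junction record at line %d: expected >= 6 columns, got %d",
                 which(nf < 6L)[1], nf[which(nf < 6L)[1]]), call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop(sprintf("malformed junction record at line %d: non-numeric coordinates", bad[1]),
         call. = FALSE)
  }
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d: start (%d) must be < end (%d) and >= 0",
                 bad[1], start0[bad[1]], end0[bad[1]]), call. = FALSE)
  }
  strand <- m[, 6]
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("invalid strand at line %d: '%s'", bad[1], strand[bad[1]]), call. = FALSE)
  }
  support <- suppressWarnings(as.numeric(m[, 5]))
  support[is.na(support)] <- 0
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = sub("\\.", "*", strand),  # BED "." = unstranded
    name = m[, 4],
    support = support
  )
}

#' Write junction calls as BED6
#'
#' Inverse of [read_junction_calls()]: converts back to 0-based half-open
#' coordinates so that a read/write round trip is the identity.
#'
#' @param junctions `GRanges` with `name` and `support` columns
#' @param path output path
#' @export
write_junction_calls <- function(junctions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(junctions)),
    start = GenomicRanges::start(junctions) - 1L,
    end = GenomicRanges::end(junctions),
    name = junctions$name %||% paste0("j", seq_along(junctions)),
    score = junctions$support %||% 0,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(junctions)))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (GTF)
#'
#' Parses exon records of a GTF file into a gene model: a set of exons
#' carrying `gene_id` and `transcript_id`, plus per-gene spans. GTF
#' coordinates are 1-based inclusive and are kept as such in the returned
#' `GRanges` (the Bioconductor convention); BED-derived inputs are converted
#' at their own readers, so all internal coordinates agree.
#'
#' @param path path to a GTF file
#' @return an object of class `circ_annotation`: a list with `exons`
#'   (`GRanges` with `gene_id`, `transcript_id`) and `genes` (`GRanges` of
#'   gene spans, names = gene ids)
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop(sprintf("malformed GTF record at line %d: expected 9 columns", which(nf < 9L)[1]),
         call. = FALSE)
  }
  feat <- vapply(fields, `[`, "", 3L)
  keep <- which(feat == "exon")
  if (!length(keep)) stop("annotation contains no exon records", call. = FALSE)
  f <- fields[keep]
  attr_str <- vapply(f, `[`, "", 9L)
  get_attr <- function(key) {
    m <- regmatches(attr_str, regexpr(sprintf('%s "[^"]*"', key), attr_str))
    out <- rep(NA_character_, length(attr_str))
    hit <- grepl(sprintf('%s "', key), attr_str, fixed = TRUE)
    out[hit] <- sub(sprintf('%s "([^"]*)"', key), "\\1", m)
    out
  }
  gene_id <- get_attr("gene_id")
  tx_id <- get_attr("transcript_id")
  if (anyNA(gene_id) || anyNA(tx_id)) {
    stop("exon record missing gene_id or transcript_id attribute", call. = FALSE)
  }
  exons <- GenomicRanges::GRanges(
    seqnames = vapply(f, `[`, "", 1L),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(f, `[`, "", 4L)),
      end = as.integer(vapply(f, `[`, "", 5L))
    ),
    strand = vapply(f, `[`, "", 7L),
    gene_id = gene_id,
    transcript_id = tx_id
  )
  build_annotation(exons)
}

#' Build an annotation object from an exon `GRanges`
#'
#' @param exons `GRanges` with `gene_id` and `transcript_id` metadata columns
#'   (1-based inclusive coordinates)
#' @param seqlengths optional named integer vector of chromosome lengths; when
#'   supplied, exons beyond a chromosome end are an error
#' @return `circ_annotation` object
#' @export
build_annotation <- function(exons, seqlengths = NULL) {
  # a transcript with exons on both strands is malformed
  strands <- split(as.character(GenomicRanges::strand(exons)), exons$transcript_id)
  mixed <- names(strands)[vapply(strands, function(s) length(unique(s)) > 1L, logical(1))]
  if (length(mixed)) {
    stop(sprintf("transcript '%s' has exons on both strands", mixed[1]), call. = FALSE)
  }
  if (!is.null(seqlengths)) {
    chrom <- as.character(GenomicRanges::seqnames(exons))
    unknown <- !chrom %in% names(seqlengths)
    if (any(unknown)) {
      stop(sprintf("exon on undeclared chromosome '%s'", chrom[which(unknown)[1]]),
           call. = FALSE)
    }
    over <- GenomicRanges::end(exons) > seqlengths[chrom]
    if (any(over)) {
      stop(sprintf("exon beyond end of chromosome '%s'", chrom[which(over)[1]]),
           call. = FALSE)
    }
  }
  o <- order(as.character(GenomicRanges::seqnames(exons)), GenomicRanges::start(exons))
  exons <- exons[o]
  genes <- unlist(range(GenomicRanges::split(exons, exons$gene_id)))
  structure(list(exons = exons, genes = genes), class = "circ_annotation")
}

#' @export
print.circ_annotation <- function(x, ...) {
  cat(sprintf("circ_annotation: %d genes, %d transcripts, %d exon records\n",
              length(x$genes), length(unique(x$exons$transcript_id)), length(x$exons)))
  invisible(x)
}

#' Write an annotation as GTF
#'
#' @param annotation `circ_annotation` object
#' @param path output path
#' @export
write_annotation <- function(annotation, path) {
  ex <- annotation$exons
  lines <- sprintf(
    '%s\tcircpipe\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    as.character(GenomicRanges::seqnames(ex)),
    GenomicRanges::start(ex), GenomicRanges::end(ex),
    as.character(GenomicRanges::strand(ex)),
    ex$gene_id, ex$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base conservation track (bedGraph)
#'
#' Builds a dense per-chromosome score vector with an explicit missing mask
#' (`NA`), so that averaging can distinguish "score 0" from "no score".
#' bedGraph coordinates are 0-based half-open.
#'
#' @param path path to a bedGraph file
#' @param seqlengths optional named integer vector of chromosome lengths;
#'   defaults to the maximal covered position per chromosome
#' @return an object of class `cons_track`: list with `scores` (named list of
#'   numeric vectors, `NA` = no score) and `seqlengths`
#' @export
read_track <- function(path, seqlengths = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "score"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  if (any(!is.finite(df$score))) stop("non-finite conservation score", call. = FALSE)
  if (any(df$start >= df$end)) stop("empty bedGraph interval", call. = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(self)) {
    stop(sprintf("overlapping bedGraph intervals (records %d and %d)",
                 S4Vectors::queryHits(self)[1], S4Vectors::subjectHits(self)[1]),
         call. = FALSE)
  }
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(df$end, df$chrom), max, integer(1))
  }
  scores <- lapply(names(seqlengths), function(chr) {
    v <- rep(NA_real_, seqlengths[[chr]])
    sub <- df[df$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$score[i]
    }
    v
  })
  names(scores) <- names(seqlengths)
  structure(list(scores = scores, seqlengths = seqlengths), class = "cons_track")
}

#' Write a conservation track as bedGraph
#'
#' Adjacent equal-score covered bases are merged into intervals; masked
#' (`NA`) bases are omitted. Round-trips with [read_track()].
#'
#' @param track `cons_track` object
#' @param path output path
#' @export
write_track <- function(track, path) {
  rows <- lapply(names(track$scores), function(chr) {
    v <- track$scores[[chr]]
    covered <- !is.na(v)
    if (!any(covered)) return(NULL)
    # run-length encode (value, coverage) to merge constant stretches
    r <- rle(ifelse(covered, v, NA))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    data.frame(chrom = chr, start = starts[keep] - 1L, end = ends[keep],
               score = r$values[keep])
  })
  df <- do.call(rbind, rows)
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.cons_track <- function(x, ...) {
  cov <- vapply(x$scores, function(v) mean(!is.na(v)), numeric(1))
  cat(sprintf("cons_track: %d chromosomes, %.1f%% of bases covered\n",
              length(x$scores), 100 * mean(cov)))
  invisible(x)
}

#' Read a codon usage table
#'
#' Tab-delimited, two columns: codon (DNA triplet) and usage frequency per
#' thousand codons. All 61 sense codons must be present with non-negative
#' frequencies and every synonymous family must have at least one codon with
#' positive usage.
#'
#' @param path path to the TSV
#' @return named numeric vector of per-thousand frequencies (names = codons)
#' @export
read_codon_usage <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "numeric"))
  usage <- setNames(df[[2]], toupper(df[[1]]))
  validate_codon_usage(usage)
  usage
}

#' @rdname read_codon_usage
#' @param usage named numeric vector of per-thousand codon frequencies
#' @export
validate_codon_usage <- function(usage) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  missing <- setdiff(sense, names(usage))
  if (length(missing)) {
    stop(sprintf("codon usage table missing %d sense codons (e.g. %s)",
                 length(missing), missing[1]), call. = FALSE)
  }
  if (any(usage < 0)) stop("negative codon usage frequency", call. = FALSE)
  aa <- code[sense]
  fam_max <- tapply(usage[sense], aa, max)
  if (any(fam_max <= 0)) {
    stop(sprintf("synonymous family '%s' has all-zero usage",
                 names(fam_max)[fam_max <= 0][1]), call. = FALSE)
  }
  invisible(usage)
}

#' Write a codon usage table
#' @param usage named numeric vector (names = codons, values per-thousand)
#' @param path output path
#' @export
write_codon_usage <- function(usage, path) {
  write.table(data.frame(codon = names(usage), per_thousand = unname(usage)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the expressed-feature table
#'
#' One row per feature. The first six columns are BED (0-based half-open);
#' then the circRNA id, the overlapped gene name (or literal `"Intergenic"`),
#' the gene id, the number of exons (empty unless genic-exonic), the catalog
#' id if the circRNA matches a known catalog entry, and the minimal
#' reciprocal-overlap level at which it matches. Per-population mean RPKM
#' columns follow when supplied.
#'
#' @param features `GRanges` of features with `circ_id`, `kind`, `ordinal`
#' @param circs `GRanges` of circRNAs with `circ_id`, `circ_class`, `gene_id`,
#'   `n_exons`, and optionally `catalog_id`, `overlap_level`
#' @param path output path
#' @param rpkm optional matrix of per-population mean RPKM (rows = features)
#' @export
write_expressed_table <- function(features, circs, path, rpkm = NULL) {
  idx <- match(features$circ_id, circs$circ_id)
  gene_name <- ifelse(circs$circ_class[idx] == "intergenic", "Intergenic",
                      circs$gene_id[idx] %||% "")
  gene_name[is.na(gene_name)] <- "Intergenic"
  n_exons <- ifelse(circs$circ_class[idx] == "genic_exonic",
                    as.character(circs$n_exons[idx]), "")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(features)),
    start = GenomicRanges::start(features) - 1L,
    end = GenomicRanges::end(features),
    name = paste0(features$circ_id, "_", features$kind, features$ordinal),
    score = 0L,
    strand = as.character(GenomicRanges::strand(features)),
    circ_id = features$circ_id,
    gene_name = gene_name,
    gene_id = ifelse(is.na(circs$gene_id[idx]), "", circs$gene_id[idx]),
    n_exons = n_exons,
    catalog_id = if (is.null(circs$catalog_id)) "" else
      ifelse(is.na(circs$catalog_id[idx]), "", circs$catalog_id[idx]),
    overlap_level = if (is.null(circs$overlap_level)) "" else
      ifelse(is.na(circs$overlap_level[idx]), "", as.character(circs$overlap_level[idx]))
  )
  if (!is.null(rpkm)) df <- cbind(df, as.data.frame(rpkm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count or RPKM matrix from TSV
#'
#' First column is the row identifier; remaining columns are samples or
#' populations.
#'
#' @param path path to the TSV
#' @return numeric matrix with rownames
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a matrix as TSV (inverse of [read_matrix_tsv()])
#' @param m matrix with rownames
#' @param path output path
#' @param id_col name of the identifier column
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
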