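#' Stable feature identifiers
#'
#' @param features feature `GRanges` with `circ_id`, `kind`, `ordinal`
#' @return character vector, e.g. `"circ_000001_exon1"`
#' @export
feature_ids <- function(features) {
  paste0(features$circ_id, "_", features$kind, features$ordinal)
}

#' Count reads per feature
#'
#' A read increments a feature when it overlaps it by >= 1 bp on the same
#' strand; a read overlapping k features of a circRNA increments each of them
#' (no fractional assignment). Reads on chromosomes unknown to the feature
#' set are skipped and tallied in the `skipped` attribute.
#'
#' @param reads_by_sample named list of `GRanges`, one per sample
#' @param features feature `GRanges` from [decompose_features()]
#' @return integer matrix (features x samples) with rownames from
#'   [feature_ids()]; attribute `skipped` holds per-sample skipped-read counts
#' @export
count_features <- function(reads_by_sample, features) {
  stopifnot(is.list(reads_by_sample))
  fid <- feature_ids(features)
  known_chroms <- unique(as.character(GenomicRanges::seqnames(features)))
  counts <- matrix(0L, nrow = length(features), ncol = length(reads_by_sample),
                   dimnames = list(fid, names(reads_by_sample)))
  skipped <- integer(length(reads_by_sample))
  for (j in seq_along(reads_by_sample)) {
    reads <- reads_by_sample[[j]]
    off <- !as.character(GenomicRanges::seqnames(reads)) %in% known_chroms
    skipped[j] <- sum(off)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(reads, features, ignore.strand = FALSE))
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(features))
    counts[, j] <- tab
  }
  attr(counts, "skipped") <- setNames(skipped, names(reads_by_sample))
  counts
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (R * L)` with `R = library_size * 1e-6` and
#' `L = length_bp * 1e-3`.
#'
#' @param count read count (vectorized)
#' @param library_size total mapped reads in the sample
#' @param length_bp feature length in bp
#' @return numeric RPKM
#' @export
rpkm <- function(count, library_size, length_bp) {
  if (any(library_size <= 0)) stop("library size must be positive", call. = FALSE)
  if (any(length_bp <= 0)) stop("feature length must be positive", call. = FALSE)
  count / ((library_size * 1e-6) * (length_bp * 1e-3))
}

#' RPKM matrix from a count matrix
#'
#' @param counts matrix (features x samples)
#' @param library_sizes per-sample library sizes (recycled along columns)
#' @param lengths_bp per-feature lengths (recycled along rows)
#' @return numeric matrix of RPKM
#' @export
rpkm_matrix <- function(counts, library_sizes, lengths_bp) {
  stopifnot(length(library_sizes) == ncol(counts), length(lengths_bp) == nrow(counts))
  sweep(sweep(counts, 2, library_sizes * 1e-6, "/"), 1, lengths_bp * 1e-3, "/")
}

#' Per-population mean of a per-sample matrix
#'
#' Arithmetic mean over the biological replicates of each population.
#'
#' @param m matrix (rows x samples)
#' @param populations character vector mapping each column to a population
#' @return matrix (rows x populations), populations in first-appearance order
#' @export
population_means <- function(m, populations) {
  stopifnot(length(populations) == ncol(m))
  pops <- unique(populations)
  out <- matrix(vapply(pops, function(p) rowMeans(m[, populations == p, drop = FALSE]),
                       numeric(nrow(m))),
                nrow = nrow(m), dimnames = list(rownames(m), pops))
  out
}

#' Derive the expression threshold from validated circRNAs
#'
#' Mirrors the benchmark procedure in which a set of circRNAs is validated by
#' sequencing: their predicted introns are never detected in the mature
#' molecule, so the highest RPKM observed among those predicted-but-undetected
#' introns bounds the noise floor and becomes the minimum threshold for
#' calling expression. With no validation set the published default `3.5` is
#' used.
#'
#' @param validated_circ_ids ids of validated circRNAs (`NULL` for the default)
#' @param features feature `GRanges`
#' @param pop_rpkm per-population mean RPKM matrix (rows = [feature_ids()])
#' @param default threshold when no validation set is supplied
#' @return numeric threshold
#' @export
derive_threshold <- function(validated_circ_ids = NULL, features = NULL,
                             pop_rpkm = NULL, default = 3.5) {
  if (is.null(validated_circ_ids)) return(default)
  stopifnot(!is.null(features), !is.null(pop_rpkm))
  sel <- features$circ_id %in% validated_circ_ids & features$kind == "intron"
  if (!any(sel)) {
    stop("validated set contains no intron features; use the default threshold instead",
         call. = FALSE)
  }
  max(pop_rpkm[feature_ids(features)[sel], , drop = FALSE])
}

#' Call expressed features and circRNAs
#'
#' A feature is expressed iff its per-population mean RPKM exceeds the
#' threshold (strictly) in at least one population. A circRNA is expressed
#' iff at least one of its *exon* features is expressed; expressed introns do
#' not qualify a circRNA (they are retained in output tables but excluded
#' from mature sequences and downstream statistics).
#'
#' @param features feature `GRanges`
#' @param pop_rpkm per-population mean RPKM matrix (rows = [feature_ids()])
#' @param threshold expression threshold (default the published 3.5)
#' @return list with `feature_expressed` (named logical) and
#'   `expressed_circ_ids` (character)
#' @export
call_expressed <- function(features, pop_rpkm, threshold = 3.5) {
  fid <- feature_ids(features)
  stopifnot(all(fid %in% rownames(pop_rpkm)))
  expressed <- apply(pop_rpkm[fid, , drop = FALSE] > threshold, 1, any)
  exon_expr <- expressed & features$kind == "exon"
  list(
    feature_expressed = expressed,
    expressed_circ_ids = unique(features$circ_id[exon_expr])
  )
}

#' Meta-feature counts per circRNA
#'
#' Sums the read counts of all exon features belonging to one circRNA, per
#' sample (intron features are excluded, consistently with the exon-only
#' mature sequence).
#'
#' @param counts count matrix (rows = [feature_ids()])
#' @param features feature `GRanges`
#' @return integer matrix (circRNAs x samples)
#' @export
meta_feature_counts <- function(counts, features) {
  ex <- features$kind == "exon"
  fid <- feature_ids(features)[ex]
  circ <- factor(features$circ_id[ex], unique(features$circ_id[ex]))
  m <- counts[fid, , drop = FALSE]
  out <- apply(m, 2, function(col) tapply(col, circ, sum))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(levels(circ), colnames(counts)))
  out
}

#' Summed exon length per circRNA
#'
#' The effective length used for circRNA-level RPKM, consistent with the
#' exon-only mature sequence.
#'
#' @param features feature `GRanges`
#' @return named integer vector (names = circ ids)
#' @export
circ_exon_lengths <- function(features) {
  ex <- features[features$kind == "exon"]
  vapply(split(GenomicRanges::width(ex), factor(ex$circ_id, unique(ex$circ_id))),
         sum, numeric(1))
}
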