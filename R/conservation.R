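#' Mean conservation score over a set of intervals
#'
#' Arithmetic mean of the per-base scores over all covered bases of the
#' union of the given intervals; masked (uncovered) bases are excluded, not
#' imputed as zero. Returns `NA` when no base is covered.
#'
#' @param intervals `GRanges` (e.g. the exon features of one circRNA, or a
#'   flank)
#' @param track `cons_track` from [read_track()] or
#'   [generate_conservation_track()]
#' @return numeric mean (or `NA` if zero covered bases)
#' @export
region_mean <- function(intervals, track) {
  vals <- unlist(lapply(seq_along(intervals), function(i) {
    chr <- as.character(GenomicRanges::seqnames(intervals))[i]
    v <- track$scores[[chr]]
    if (is.null(v)) return(numeric(0))
    lo <- max(1L, GenomicRanges::start(intervals)[i])
    hi <- min(length(v), GenomicRanges::end(intervals)[i])
    if (lo > hi) return(numeric(0))
    v[lo:hi]
  }))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Flanking intervals of a circRNA
#'
#' Strand-aware 200-bp (by default) flanks: upstream is the 5' side of the
#' transcribed strand. Flanks are clipped at chromosome ends and the
#' realized width is recorded.
#'
#' @param circ a length-1 `GRanges`
#' @param flank_size flank width in bp (default 200)
#' @param seqlengths named integer vector of chromosome lengths (optional;
#'   used for clipping at the 3' chromosome end)
#' @return `GRanges` of length 2 with metadata column `side`
#'   ("upstream"/"downstream") and `realized_width`
#' @export
flanks <- function(circ, flank_size = 200, seqlengths = NULL) {
  stopifnot(length(circ) == 1L)
  chr <- as.character(GenomicRanges::seqnames(circ))
  st <- GenomicRanges::start(circ)
  en <- GenomicRanges::end(circ)
  chrlen <- if (!is.null(seqlengths)) seqlengths[[chr]] else Inf
  left <- c(max(1L, st - flank_size), st - 1L)
  right <- c(en + 1L, min(chrlen, en + flank_size))
  mk <- function(lohi) {
    if (lohi[1] > lohi[2]) IRanges::IRanges(start = integer(), end = integer())
    else IRanges::IRanges(lohi[1], lohi[2])
  }
  gr <- GenomicRanges::GRanges(chr, c(mk(left), mk(right)),
                               strand = GenomicRanges::strand(circ))
  side <- c("left", "right")[seq_along(gr)]
  if (length(gr) == 2L) {
    side <- if (as.character(GenomicRanges::strand(circ)) == "-") {
      c("downstream", "upstream")
    } else {
      c("upstream", "downstream")
    }
  }
  gr$side <- side
  gr$realized_width <- GenomicRanges::width(gr)
  gr
}

#' Draw a location-matched shuffled counterpart for a region
#'
#' A random window of identical length, uniform over feasible placements in
#' a class-appropriate reference: genic circRNA bodies shuffle within the
#' exonic reference (the union of annotated exons), genic flanks within the
#' intronic reference (gene bodies minus exons), and intergenic regions
#' anywhere in the genome.
#'
#' @param region length-1 `GRanges`
#' @param circ_class one of `genic_exonic`, `genic_other`, `antisense`,
#'   `intergenic`
#' @param is_flank is the region a flank (uses the intronic reference for
#'   genic circRNAs)?
#' @param annotation `circ_annotation`
#' @param seqlengths named integer vector of chromosome lengths
#' @return length-1 `GRanges` of the same width
#' @export
shuffle_matched <- function(region, circ_class, is_flank, annotation, seqlengths,
                            ref = NULL) {
  len <- GenomicRanges::width(region)
  stopifnot(length(region) == 1L)
  if (is.null(ref)) ref <- shuffle_reference(circ_class, is_flank, annotation, seqlengths)
  feasible <- ref[GenomicRanges::width(ref) >= len]
  if (!length(feasible)) {
    stop(sprintf("no reference block can host a %d bp shuffled region (%s%s)",
                 len, circ_class, if (is_flank) " flank" else ""), call. = FALSE)
  }
  slots <- GenomicRanges::width(feasible) - len + 1L
  i <- sample.int(length(feasible), 1, prob = slots)
  st <- GenomicRanges::start(feasible)[i] + sample.int(slots[i], 1) - 1L
  GenomicRanges::GRanges(GenomicRanges::seqnames(feasible)[i],
                         IRanges::IRanges(st, width = len),
                         strand = GenomicRanges::strand(region))
}

# reference blocks for shuffling, by class and region kind
shuffle_reference <- function(circ_class, is_flank, annotation, seqlengths) {
  whole <- GenomicRanges::GRanges(names(seqlengths),
                                  IRanges::IRanges(1L, unname(seqlengths)))
  if (circ_class %in% c("intergenic", "antisense")) return(whole)
  exonic <- GenomicRanges::reduce(annotation$exons, ignore.strand = TRUE)
  genic <- GenomicRanges::reduce(annotation$genes, ignore.strand = TRUE)
  if (!is_flank) {
    # exon-bounded bodies shuffle within exons; bodies that include intronic
    # sequence shuffle within whole gene bodies (exons and introns)
    return(if (circ_class == "genic_exonic") exonic else genic)
  }
  intronic <- GenomicRanges::setdiff(genic, exonic, ignore.strand = TRUE)
  if (!length(intronic)) genic else intronic
}

#' Compare real and shuffled conservation means
#'
#' Two-sample t test (Welch by default) on the per-region mean scores.
#' Degenerate identical groups return `t = 0`, `p = 1`.
#'
#' @param real_means numeric vector of per-region means (real regions)
#' @param shuffled_means numeric vector for the shuffled counterparts
#' @param var_equal use the pooled-variance Student variant
#' @return list with `mean_real`, `mean_shuffled`, `t`, `df`, `p_value`, `n`
#' @export
compare_conservation <- function(real_means, shuffled_means, var_equal = FALSE) {
  real_means <- real_means[!is.na(real_means)]
  shuffled_means <- shuffled_means[!is.na(shuffled_means)]
  stopifnot(length(real_means) >= 2, length(shuffled_means) >= 2)
  if (stats::sd(real_means) == 0 && stats::sd(shuffled_means) == 0 &&
      mean(real_means) == mean(shuffled_means)) {
    return(list(mean_real = mean(real_means), mean_shuffled = mean(shuffled_means),
                t = 0, df = length(real_means) + length(shuffled_means) - 2,
                p_value = 1, n = c(length(real_means), length(shuffled_means))))
  }
  tt <- t.test(real_means, shuffled_means, var.equal = var_equal)
  list(mean_real = mean(real_means), mean_shuffled = mean(shuffled_means),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = c(length(real_means), length(shuffled_means)))
}

#' Conservation analysis of a circRNA set
#'
#' For each circRNA, averages the track over the union of its exon features
#' (the body; introns excluded, consistent with the exon-only mature
#' sequence) and over its two flanks, draws one location-matched shuffled
#' counterpart per region, and tests real vs shuffled per region type.
#'
#' @param circs classified `GRanges`
#' @param features feature `GRanges`
#' @param track `cons_track`
#' @param annotation `circ_annotation`
#' @param seqlengths named chromosome lengths
#' @param flank_size flank width (default 200)
#' @param seed integer seed for shuffled placements
#' @param classes restrict to these circ classes (default all)
#' @return list with `per_region` data.frame (circ_id, region, real_mean,
#'   shuffled_mean) and `tests` (one [compare_conservation()] result per
#'   region type), plus `n_excluded` regions with zero covered bases
#' @export
conservation_analysis <- function(circs, features, track, annotation, seqlengths,
                                  flank_size = 200, seed = 1, classes = NULL) {
  if (!is.null(classes)) circs <- circs[circs$circ_class %in% classes]
  set.seed(derive_seed(seed, 13L))
  refs <- list()
  for (cls in unique(circs$circ_class)) {
    refs[[cls]] <- list(
      body = shuffle_reference(cls, FALSE, annotation, seqlengths),
      flank = shuffle_reference(cls, TRUE, annotation, seqlengths))
  }
  exidx <- split(which(features$kind == "exon"),
                 features$circ_id[features$kind == "exon"])
  rows <- list()
  for (i in seq_along(circs)) {
    cid <- circs$circ_id[i]
    cls <- circs$circ_class[i]
    body <- features[exidx[[cid]]]
    fl <- flanks(circs[i], flank_size, seqlengths)
    regs <- list(body = body)
    for (j in seq_along(fl)) regs[[fl$side[j]]] <- fl[j]
    for (rn in names(regs)) {
      reg <- regs[[rn]]
      if (!length(reg)) next
      real <- region_mean(reg, track)
      is_flank <- rn != "body"
      shuf <- if (is_flank) {
        shuffle_matched(reg, cls, TRUE, annotation, seqlengths, ref = refs[[cls]]$flank)
      } else {
        # body may be multi-exon: shuffle each exon block, average
        suppressWarnings(do.call(c, lapply(seq_along(reg), function(k)
          shuffle_matched(reg[k], cls, FALSE, annotation, seqlengths,
                          ref = refs[[cls]]$body))))
      }
      shuffled <- region_mean(shuf, track)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = cid, circ_class = cls,
        region = if (is_flank) "flank" else "body",
        side = rn, real_mean = real, shuffled_mean = shuffled
      )
    }
  }
  per_region <- do.call(rbind, rows)
  n_excluded <- sum(is.na(per_region$real_mean) | is.na(per_region$shuffled_mean))
  ok <- !is.na(per_region$real_mean) & !is.na(per_region$shuffled_mean)
  tests <- lapply(split(per_region[ok, ], per_region$region[ok]), function(d) {
    compare_conservation(d$real_mean, d$shuffled_mean)
  })
  list(per_region = per_region, tests = tests, n_excluded = n_excluded)
}
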