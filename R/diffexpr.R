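#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over rows with
#' all-positive counts, of the ratio of each sample's count to the row
#' geometric mean. This is the standard median-of-ratios normalization for
#' count matrices; no dispersion estimation or shrinkage is performed
#' downstream, as trajectory calls rest on raw fold-change thresholds.
#'
#' @param counts count matrix (rows = circRNAs, columns = samples)
#' @return numeric vector of size factors (one per column)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no row with all-positive counts; add a pseudocount before normalization",
         call. = FALSE)
  }
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(col) exp(median(col - loggeo)))
}

#' Normalize a count matrix by size factors
#'
#' @param counts count matrix
#' @param factors size factors from [size_factors()] (default: computed)
#' @return matrix of normalized counts
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  sweep(as.matrix(counts), 2, factors, "/")
}

#' Fold change between two population means
#'
#' `FC = (B + pc) / (A + pc)` on mean normalized counts, with a pseudocount
#' guarding against zeros.
#'
#' @param mean_a mean normalized count in the first population
#' @param mean_b mean normalized count in the second population
#' @param pseudocount added to both means (default 0.5)
#' @return numeric fold change (vectorized)
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  (mean_b + pseudocount) / (mean_a + pseudocount)
}

#' Classify a two-transition expression trajectory
#'
#' Each transition (first -> second population, second -> third) is labelled
#' `U` if FC >= `up`, `D` if FC <= `down`, else `F` (boundaries inclusive).
#' The trajectory label is the concatenation of the two letters, giving nine
#' classes: `FF` is unchanged, `UD` transiently up in the middle population,
#' `DU` transiently down, and so on. No multiple-testing correction is
#' applied; these are raw fold-change classes.
#'
#' @param fc1 fold change of the first transition (vectorized)
#' @param fc2 fold change of the second transition
#' @param up up-regulation threshold (default 1.5)
#' @param down down-regulation threshold (default 0.67)
#' @return character vector of labels among the 9 codes
#' @export
classify_trajectory <- function(fc1, fc2, up = 1.5, down = 0.67) {
  lab <- function(fc) ifelse(fc >= up, "U", ifelse(fc <= down, "D", "F"))
  paste0(lab(fc1), lab(fc2))
}

#' Trajectory calls for a count matrix over three populations
#'
#' Normalizes counts (median-of-ratios), averages per population, and
#' classifies the two consecutive transitions.
#'
#' @param counts meta-feature count matrix (circRNAs x samples)
#' @param populations character vector mapping each column to one of three
#'   populations, in biological order (e.g. PP, DP, N)
#' @param up,down fold-change thresholds
#' @param pseudocount passed to [fold_change()]
#' @param factors optional precomputed size factors
#' @return data.frame with `circ_id`, `fc1`, `fc2`, `label`
#' @export
trajectory_calls <- function(counts, populations, up = 1.5, down = 0.67,
                             pseudocount = 0.5, factors = NULL) {
  pops <- unique(populations)
  stopifnot(length(pops) == 3L)
  norm <- if (is.null(factors)) {
    normalize_counts(counts)
  } else {
    normalize_counts(counts, factors)
  }
  means <- population_means(norm, populations)
  fc1 <- fold_change(means[, 1], means[, 2], pseudocount)
  fc2 <- fold_change(means[, 2], means[, 3], pseudocount)
  data.frame(
    circ_id = rownames(counts),
    fc1 = unname(fc1),
    fc2 = unname(fc2),
    label = classify_trajectory(fc1, fc2, up, down)
  )
}

#' Tabulate trajectory labels
#'
#' @param calls data.frame from [trajectory_calls()] (or a character vector
#'   of labels)
#' @return named integer vector over all 9 label classes, summing to the
#'   number of calls
#' @export
pattern_summary <- function(calls) {
  labels <- if (is.data.frame(calls)) calls$label else calls
  lv <- as.vector(outer(c("U", "D", "F"), c("U", "D", "F"), paste0))
  table(factor(labels, levels = lv))
}
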