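#' Pearson correlation of circular and linear expression on the log2 scale
#'
#' @param circ_rpkm,linear_rpkm paired RPKM vectors (length >= 3)
#' @param pseudocount added before taking log2 (default 1e-3)
#' @return list with `r`, `r_squared`, `n`
#' @export
pearson_log <- function(circ_rpkm, linear_rpkm, pseudocount = 1e-3) {
  stopifnot(length(circ_rpkm) == length(linear_rpkm), length(circ_rpkm) >= 3)
  x <- log2(circ_rpkm + pseudocount)
  y <- log2(linear_rpkm + pseudocount)
  r <- cor(x, y, method = "pearson")
  list(r = r, r_squared = r^2, n = length(x))
}

#' Concordance of circRNA and shared-exon fold-change patterns
#'
#' Each transition's fold change is classified U/D/F with the same thresholds
#' used for trajectories. A pair is `opposite` if any transition has the
#' circRNA and the exon moving in opposite directions (U vs D), `same` if all
#' non-flat transitions agree in direction and at least one transition is
#' non-flat in both, and `mixed` otherwise (including all-flat pairs and
#' flat-vs-moving transitions). The three classes partition all pairs; the
#' conventional two-class summary is obtained by merging `mixed` into `same`.
#'
#' @param circ_fc matrix or data.frame of circRNA fold changes
#'   (pairs x transitions)
#' @param exon_fc matching fold changes of the shared exon in the linear
#'   transcript
#' @param up,down fold-change thresholds (defaults 1.5 and 0.67)
#' @return character vector in \{"same", "opposite", "mixed"\}
#' @export
exon_concordance <- function(circ_fc, exon_fc, up = 1.5, down = 0.67) {
  circ_fc <- as.matrix(circ_fc)
  exon_fc <- as.matrix(exon_fc)
  stopifnot(all(dim(circ_fc) == dim(exon_fc)))
  lab <- function(fc) ifelse(fc >= up, "U", ifelse(fc <= down, "D", "F"))
  lc <- matrix(lab(circ_fc), nrow = nrow(circ_fc))
  le <- matrix(lab(exon_fc), nrow = nrow(exon_fc))
  vapply(seq_len(nrow(lc)), function(i) {
    a <- lc[i, ]
    b <- le[i, ]
    opposite <- any((a == "U" & b == "D") | (a == "D" & b == "U"))
    if (opposite) return("opposite")
    both_moving <- a != "F" & b != "F"
    if (any(both_moving) && all(a[both_moving] == b[both_moving]) &&
        !any(xor(a == "F", b == "F"))) {
      return("same")
    }
    "mixed"
  }, character(1))
}

#' Overlap of circRNAs with alternatively spliced genes
#'
#' Reports (i) the genes expressing at least two linear isoforms, (ii) the
#' fraction of expressed circRNAs hosted by such genes, and (iii) the
#' circRNAs sharing at least one identical exon with a differentially
#' spliced isoform in every population.
#'
#' @param isoform_rpkm matrix of per-population isoform RPKM (rows =
#'   transcript ids)
#' @param isoform_gene named character vector mapping transcript id -> gene id
#' @param circs classified `GRanges` (with `gene_id`)
#' @param features feature `GRanges`
#' @param annotation `circ_annotation`
#' @param expressed_circ_ids ids of expressed circRNAs
#' @param threshold isoform-expression RPKM threshold (default 3.5, the same
#'   threshold used for circRNAs)
#' @return list with `as_genes`, `n_as_genes`, `n_expressed_genes`,
#'   `n_circ_in_as_genes`, `frac_circ_in_as_genes`, `n_circ_sharing_exon`
#' @export
alt_splicing_overlap <- function(isoform_rpkm, isoform_gene, circs, features,
                                 annotation, expressed_circ_ids,
                                 threshold = 3.5) {
  expr_iso <- rownames(isoform_rpkm)[apply(isoform_rpkm > threshold, 1, any)]
  genes_of_expr <- isoform_gene[expr_iso]
  n_iso_per_gene <- table(genes_of_expr)
  as_genes <- names(n_iso_per_gene)[n_iso_per_gene >= 2]
  circs <- circs[circs$circ_id %in% expressed_circ_ids]
  hosted <- !is.na(circs$gene_id) & circs$gene_id %in% as_genes
  # expressed in all populations, for clause (iii)
  iso_all_pops <- rownames(isoform_rpkm)[apply(isoform_rpkm > threshold, 1, all)]
  share <- vapply(seq_along(circs), function(i) {
    if (!hosted[i]) return(FALSE)
    ex <- features[features$circ_id == circs$circ_id[i] & features$kind == "exon"]
    cand <- annotation$exons[annotation$exons$gene_id == circs$gene_id[i] &
                             annotation$exons$transcript_id %in% iso_all_pops]
    if (!length(cand)) return(FALSE)
    any(paste(GenomicRanges::start(ex), GenomicRanges::end(ex)) %in%
          paste(GenomicRanges::start(cand), GenomicRanges::end(cand)))
  }, logical(1))
  list(
    as_genes = as_genes,
    n_as_genes = length(as_genes),
    n_expressed_genes = length(unique(genes_of_expr)),
    n_circ_in_as_genes = sum(hosted),
    frac_circ_in_as_genes = if (length(circs)) sum(hosted) / length(circs) else 0,
    n_circ_sharing_exon = sum(share)
  )
}
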