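#' Run the full circRNA characterization pipeline
#'
#' Executes the stages in order: junction classification and feature
#' decomposition, sequence reconstruction, per-feature counting and RPKM,
#' expression calling, trajectory classification, miRNA seed scanning and
#' counting, ORF finding with CAI/eCAI and shuffled-control comparison,
#' conservation analysis against location-matched shuffled backgrounds, and
#' circular-vs-linear comparison. Returns all stage outputs plus a run
#' manifest recording the in/out counts of every filter, so the
#' putative-to-expressed funnel is auditable.
#'
#' @param bundle a dataset bundle from [generate_dataset()] or [read_dataset()]
#' @param threshold expression threshold; the published default `3.5`, or
#'   `"auto"` to derive it from the bundle's validated circRNAs
#' @param up,down fold-change thresholds for trajectory classes
#' @param min_score,max_dg seed-site alignment-score and free-energy gates
#' @param orf_min_len minimum ORF length in nt
#' @param ecai_confidence eCAI confidence level
#' @param n_null null sequences per eCAI run
#' @param flank_size conservation flank width in bp
#' @param seed integer seed for the stochastic stages (shuffles, eCAI)
#' @param stages character vector of stages to run (default all, in order)
#' @return a list of stage results and `manifest`
#' @export
run_pipeline <- function(bundle, threshold = 3.5, up = 1.5, down = 0.67,
                         min_score = 150, max_dg = -19, orf_min_len = 150,
                         ecai_confidence = 0.95, n_null = 500,
                         flank_size = 200, seed = 1,
                         stages = c("annotate", "quantify", "diffexp", "seeds",
                                    "orfcai", "conserve", "compare_linear")) {
  res <- list()
  manifest <- list(seed = seed,
                   params = list(threshold = threshold, up = up, down = down,
                                 min_score = min_score, max_dg = max_dg,
                                 orf_min_len = orf_min_len,
                                 ecai_confidence = ecai_confidence,
                                 flank_size = flank_size))
  need <- function(stage, dep) {
    if (is.null(res[[dep]])) {
      stop(sprintf("stage '%s' requires stage '%s' to have run", stage, dep),
           call. = FALSE)
    }
  }
  sq <- setNames(Biostrings::width(bundle$genome), names(bundle$genome))

  if ("annotate" %in% stages) {
    circs <- classify_junctions(bundle$junctions, bundle$annotation)
    features <- decompose_features(circs, bundle$annotation)
    seqs <- reconstruct_sequences(circs, features, bundle$genome)
    res$annotate <- list(circs = circs, features = features, sequences = seqs)
    manifest$funnel <- c(putative = length(circs))
    manifest$classes <- table(circs$circ_class)
  }

  if ("quantify" %in% stages) {
    need("quantify", "annotate")
    counts <- count_features(bundle$reads_by_sample, res$annotate$features)
    rpkms <- rpkm_matrix(counts, bundle$library_sizes,
                         GenomicRanges::width(res$annotate$features))
    pop_rpkm <- population_means(rpkms, bundle$sample_populations)
    thr <- if (identical(threshold, "auto")) {
      derive_threshold(bundle$truth$validated_circ_ids, res$annotate$features, pop_rpkm)
    } else threshold
    calls <- call_expressed(res$annotate$features, pop_rpkm, thr)
    res$quantify <- list(counts = counts, rpkm = rpkms, pop_rpkm = pop_rpkm,
                         threshold = thr, feature_expressed = calls$feature_expressed,
                         expressed_circ_ids = calls$expressed_circ_ids)
    manifest$funnel <- c(manifest$funnel, expressed = length(calls$expressed_circ_ids))
  }

  expressed_subset <- function() {
    circs <- res$annotate$circs
    keep <- circs$circ_id %in% res$quantify$expressed_circ_ids
    list(circs = circs[keep],
         features = res$annotate$features[res$annotate$features$circ_id %in%
                                            circs$circ_id[keep]],
         seqs = res$annotate$sequences[intersect(names(res$annotate$sequences),
                                                 circs$circ_id[keep])])
  }

  if ("diffexp" %in% stages) {
    need("diffexp", "quantify")
    ex <- expressed_subset()
    meta <- meta_feature_counts(res$quantify$counts, ex$features)
    traj <- trajectory_calls(meta, bundle$sample_populations, up = up, down = down)
    res$diffexp <- list(meta_counts = meta, trajectories = traj,
                        pattern = pattern_summary(traj))
    manifest$trajectory_classes <- res$diffexp$pattern
  }

  if ("seeds" %in% stages) {
    need("seeds", "quantify")
    ex <- expressed_subset()
    matches <- seed_scan(ex$seqs, bundle$mirnas)
    counted <- filter_and_count(matches, min_score = min_score, max_dg = max_dg)
    res$seeds <- list(matches = matches, counts = counted$counts,
                      summary = counted$summary)
    manifest$seed_sites <- c(found = nrow(matches),
                             surviving = sum(counted$counts$n_sites))
  }

  if ("orfcai" %in% stages) {
    need("orfcai", "quantify")
    ex <- expressed_subset()
    w <- relative_adaptiveness(bundle$codon_usage)
    orf_table <- function(seqs) {
      rows <- lapply(names(seqs), function(id) {
        o <- find_orfs(as.character(seqs[[id]]), min_len = orf_min_len)
        if (nrow(o)) o$seq_id <- id
        o
      })
      out <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0])
      if (is.null(out)) return(NULL)
      out$cai <- vapply(out$orf_seq, cai, numeric(1), w = w)
      out
    }
    circ_orfs <- orf_table(as.list(as.character(ex$seqs)))
    ec <- if (!is.null(circ_orfs)) {
      ecai(circ_orfs$orf_seq, w, n_null = n_null, confidence = ecai_confidence,
           seed = derive_seed(seed, 41L))
    } else list(ecai = NA_real_)
    lens <- if (!is.null(circ_orfs)) {
      vapply(split(nchar(as.character(ex$seqs)), seq_along(ex$seqs)), identity, numeric(1))
    } else numeric(0)
    ctrl <- shuffled_controls(bundle$genome,
                              transcript_sequences(bundle$annotation, bundle$genome),
                              nchar(as.character(ex$seqs)),
                              seed = derive_seed(seed, 42L))
    gen_orfs <- orf_table(as.list(ctrl$genomic))
    tx_orfs <- orf_table(as.list(ctrl$transcriptomic))
    above <- function(tab) if (is.null(tab)) c(0L, 0L) else
      c(sum(tab$cai > ec$ecai), sum(tab$cai <= ec$ecai))
    ab_circ <- above(circ_orfs); ab_gen <- above(gen_orfs); ab_tx <- above(tx_orfs)
    chi_gen <- if (sum(ab_gen) > 0 && sum(ab_circ) > 0)
      chi2_2x2(ab_circ[1], ab_circ[2], ab_gen[1], ab_gen[2]) else NULL
    chi_tx <- if (sum(ab_tx) > 0 && sum(ab_circ) > 0)
      chi2_2x2(ab_circ[1], ab_circ[2], ab_tx[1], ab_tx[2]) else NULL
    res$orfcai <- list(circ_orfs = circ_orfs, ecai = ec$ecai,
                       genomic_orfs = gen_orfs, transcriptomic_orfs = tx_orfs,
                       above_expected = list(circ = ab_circ, genomic = ab_gen,
                                             transcriptomic = ab_tx),
                       chi2_genomic = chi_gen, chi2_transcriptomic = chi_tx)
    manifest$orfs <- c(circ = if (is.null(circ_orfs)) 0L else nrow(circ_orfs),
                       genomic = if (is.null(gen_orfs)) 0L else nrow(gen_orfs),
                       transcriptomic = if (is.null(tx_orfs)) 0L else nrow(tx_orfs))
  }

  if ("conserve" %in% stages) {
    need("conserve", "quantify")
    ex <- expressed_subset()
    res$conserve <- conservation_analysis(ex$circs, ex$features, bundle$track,
                                          bundle$annotation, sq,
                                          flank_size = flank_size,
                                          seed = derive_seed(seed, 51L))
  }

  if ("compare_linear" %in% stages) {
    need("compare_linear", "quantify")
    ex <- expressed_subset()
    genic <- ex$circs[!is.na(ex$circs$gene_id) &
                      ex$circs$gene_id %in% rownames(bundle$linear_rpkm)]
    meta <- meta_feature_counts(res$quantify$counts,
                                res$annotate$features[res$annotate$features$circ_id %in%
                                                        genic$circ_id])
    lens <- circ_exon_lengths(res$annotate$features)[rownames(meta)]
    circ_rpkm_s <- rpkm_matrix(meta, bundle$library_sizes, lens)
    circ_rpkm <- population_means(circ_rpkm_s, bundle$sample_populations)
    lin <- bundle$linear_rpkm[genic$gene_id[match(rownames(circ_rpkm), genic$circ_id)], ,
                              drop = FALSE]
    pear_all <- pearson_log(as.vector(circ_rpkm), as.vector(as.matrix(lin)))
    pear_pop <- lapply(colnames(circ_rpkm), function(p)
      pearson_log(circ_rpkm[, p], lin[, p]))
    names(pear_pop) <- colnames(circ_rpkm)
    conc <- NULL
    if (!is.null(bundle$exon_fc)) {
      traj <- trajectory_calls(meta, bundle$sample_populations, up = up, down = down)
      shared <- intersect(traj$circ_id, rownames(bundle$exon_fc))
      cfc <- as.matrix(traj[match(shared, traj$circ_id), c("fc1", "fc2")])
      rownames(cfc) <- shared
      conc <- setNames(exon_concordance(cfc, bundle$exon_fc[shared, , drop = FALSE],
                                        up = up, down = down), shared)
    }
    alt <- NULL
    if (!is.null(bundle$isoform_rpkm)) {
      alt <- alt_splicing_overlap(bundle$isoform_rpkm, bundle$isoform_gene,
                                  res$annotate$circs, res$annotate$features,
                                  bundle$annotation, res$quantify$expressed_circ_ids,
                                  threshold = res$quantify$threshold)
    }
    res$compare_linear <- list(pearson_overall = pear_all, pearson_by_pop = pear_pop,
                               concordance = conc, alt_splicing = alt)
    if (!is.null(conc)) manifest$concordance <- table(conc)
  }

  res$manifest <- manifest
  res
}

# spliced transcript sequences from the annotation (used as the
# "transcriptome" reference for shuffled controls)
transcript_sequences <- function(annotation, genome) {
  ex <- annotation$exons
  lst <- split(seq_along(ex), ex$transcript_id)
  vapply(lst, function(idx) {
    e <- ex[idx]
    e <- e[order(GenomicRanges::start(e))]
    s <- paste(as.character(Biostrings::subseq(
      genome[as.character(GenomicRanges::seqnames(e))],
      start = GenomicRanges::start(e), end = GenomicRanges::end(e))), collapse = "")
    if (as.character(GenomicRanges::strand(e))[1] == "-") revcomp(s) else s
  }, character(1))
}

#' Write a dataset bundle to a directory in standard formats
#'
#' FASTA for genome and miRNAs, GTF for the annotation, BED for junctions
#' and per-sample reads, bedGraph for the conservation track, TSV for the
#' expression tables, and `truth.json` for the manifest.
#'
#' @param bundle from [generate_dataset()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  write_annotation(bundle$annotation, file.path(dir, "annotation.gtf"))
  write_junction_calls(bundle$junctions, file.path(dir, "junctions.bed"))
  for (s in names(bundle$reads_by_sample)) {
    r <- bundle$reads_by_sample[[s]]
    r$name <- paste0("r", seq_along(r))
    r$support <- 1
    write_junction_calls(r, file.path(dir, "reads", paste0(s, ".bed")))
  }
  mir <- Biostrings::RNAStringSet(bundle$mirnas)
  Biostrings::writeXStringSet(mir, file.path(dir, "mirnas.fa"))
  write_codon_usage(bundle$codon_usage, file.path(dir, "codon_usage.tsv"))
  write_track(bundle$track, file.path(dir, "phylop.bedgraph"))
  write_matrix_tsv(bundle$linear_rpkm, file.path(dir, "linear_rpkm.tsv"), "gene_id")
  write_matrix_tsv(bundle$isoform_rpkm, file.path(dir, "isoform_rpkm.tsv"), "transcript_id")
  write_matrix_tsv(bundle$exon_fc, file.path(dir, "exon_fc.tsv"), "circ_id")
  writeLines(jsonlite::toJSON(list(sample_populations = bundle$sample_populations,
                                   library_sizes = as.list(bundle$library_sizes),
                                   isoform_gene = as.list(bundle$isoform_gene)),
                              auto_unbox = TRUE),
             file.path(dir, "design.json"))
  writeLines(jsonlite::toJSON(bundle$truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", na = "null"),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir bundle directory
#' @return a bundle list as produced by [generate_dataset()] (the truth
#'   manifest is returned as parsed JSON)
#' @export
read_dataset <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  design <- jsonlite::fromJSON(file.path(dir, "design.json"))
  read_files <- list.files(file.path(dir, "reads"), full.names = TRUE)
  reads <- lapply(read_files, read_junction_calls)
  names(reads) <- sub("\\.bed$", "", basename(read_files))
  sample_order <- names(design$library_sizes)
  reads <- reads[sample_order]
  mir <- Biostrings::readRNAStringSet(file.path(dir, "mirnas.fa"))
  list(
    genome = genome,
    annotation = read_annotation(file.path(dir, "annotation.gtf")),
    junctions = read_junction_calls(file.path(dir, "junctions.bed")),
    reads_by_sample = reads,
    library_sizes = unlist(design$library_sizes),
    sample_populations = design$sample_populations,
    mirnas = setNames(as.character(mir), sub(" .*", "", names(mir))),
    codon_usage = read_codon_usage(file.path(dir, "codon_usage.tsv")),
    track = read_track(file.path(dir, "phylop.bedgraph"),
                       seqlengths = setNames(Biostrings::width(genome), names(genome))),
    linear_rpkm = read_matrix_tsv(file.path(dir, "linear_rpkm.tsv")),
    isoform_rpkm = read_matrix_tsv(file.path(dir, "isoform_rpkm.tsv")),
    isoform_gene = unlist(design$isoform_gene),
    exon_fc = read_matrix_tsv(file.path(dir, "exon_fc.tsv")),
    truth = jsonlite::fromJSON(file.path(dir, "truth.json"))
  )
}

#' @importFrom Biostrings RNAStringSet readRNAStringSet
NULL
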