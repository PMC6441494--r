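#' Default settings for the synthetic dataset generator
#'
#' The defaults emulate the study design the pipeline targets: three
#' FACS-sorted cortical populations (proliferative progenitors, differentiative
#' progenitors, newborn neurons) with three biological replicates each, a
#' circRNA catalog dominated by genic-exonic molecules (97%), and
#' negative-binomial count noise. Scale is reduced to desk size: two 500-kb
#' chromosomes, 300 genes, 150 planted circRNAs, 50,000 reads per sample.
#'
#' @param ... named overrides of any default
#' @return a config list
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    seqlengths = c(chr1 = 500000L, chr2 = 500000L),
    n_genes = 300L,
    n_circ = 150L,
    class_mix = c(genic_exonic = 0.97, genic_other = 0.01,
                  antisense = 0.01, intergenic = 0.01),
    populations = c("PP", "DP", "N"),
    n_replicates = 3L,
    library_size = 50000L,
    noise = "nb",              # "nb", "poisson" or "none"
    nb_dispersion = 0.05,
    frac_expressed = 0.85,
    trajectory_mix = c(FF = 0.40, UU = 0.10, DD = 0.10, UD = 0.10, DU = 0.10,
                       UF = 0.05, FU = 0.05, DF = 0.05, FD = 0.05),
    fc_up_planted = 3, fc_down_planted = 1 / 3,
    exon_count_range = c(3L, 6L),
    exon_len_range = c(100L, 200L),
    intron_len_range = c(150L, 400L),
    gene_gap_range = c(400L, 800L),
    as_gene_frac = 0.2,
    read_length = 50L,
    n_mirnas = 5L,
    mirna_length = 22L,
    n_seed_circs = 10L,
    n_orf_circs = 12L,
    orf_n_codons = c(50L, 70L),
    cons_base = 0, cons_elevation = 0.5, cons_flank_elevation = 0.3,
    cons_noise_sd = 0.2,
    linear_target_r = 0.8,
    n_opposite_pairs = 2L,
    expression_threshold = 3.5
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic dataset with a truth manifest
#'
#' Builds a random genome, plants gene models (a fraction with a second,
#' exon-skipping isoform), plants circRNAs of the four classes with exact
#' class counts (largest-remainder rounding of the class mix), plants
#' per-population expression with trajectory labels, miRNA seed sites
#' (including one junction-spanning site), codon-biased ORFs, a conservation
#' track with elevated scores over expressed circRNA bodies and flanks, and
#' correlated linear host-gene expression. All randomness flows from the
#' single `seed`; the same (config, seed) yields an identical bundle.
#'
#' @param config from [synthetic_config()]
#' @param seed integer seed
#' @return a bundle list: `genome` (`DNAStringSet`), `annotation`,
#'   `junctions`, `reads_by_sample`, `library_sizes`, `sample_populations`,
#'   `mirnas`, `codon_usage`, `track`, `linear_rpkm`, `isoform_rpkm`,
#'   `isoform_gene`, `exon_fc`, `truth` (the manifest)
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1) {
  cfg <- config
  sq <- cfg$seqlengths

  ## 1. genome ----------------------------------------------------------
  set.seed(derive_seed(seed, 1L))
  genome <- vapply(sq, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))

  ## 2. gene models -----------------------------------------------------
  set.seed(derive_seed(seed, 2L))
  bg_width <- 20000L
  cursor <- setNames(rep(2000L + bg_width, length(sq)), names(sq))
  bg_blocks <- GenomicRanges::GRanges(names(sq), IRanges::IRanges(2000L, width = bg_width))
  exon_rows <- list(); gene_rows <- list(); gap_rows <- list()
  as_skip <- integer(0)
  n_as <- round(cfg$as_gene_frac * cfg$n_genes)
  as_genes_idx <- sort(sample.int(cfg$n_genes, n_as))
  for (g in seq_len(cfg$n_genes)) {
    chr <- names(sq)[which.min(cursor)]
    n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
    ex_w <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n_ex, replace = TRUE)
    in_w <- if (n_ex > 1) sample(cfg$intron_len_range[1]:cfg$intron_len_range[2],
                                 n_ex - 1, replace = TRUE) else integer(0)
    glen <- sum(ex_w) + sum(in_w)
    if (cursor[chr] + glen > sq[chr] - 1000L) {
      stop("infeasible config: genome too small for the requested gene count",
           call. = FALSE)
    }
    strand <- sample(c("+", "-"), 1)
    st <- cursor[chr]
    starts <- st + cumsum(c(0L, head(ex_w + c(in_w, 0L), -1)))
    ends <- starts + ex_w - 1L
    gid <- sprintf("gene%04d", g)
    exon_rows[[g]] <- data.frame(chr = chr, start = starts, end = ends,
                                 strand = strand, gene = gid,
                                 tx = paste0(gid, "_t1"), exon_idx = seq_len(n_ex))
    if (g %in% as_genes_idx && n_ex >= 3) {
      skip <- sample(2:(n_ex - 1), 1)
      as_skip[gid] <- skip
      keep <- setdiff(seq_len(n_ex), skip)
      exon_rows[[g]] <- rbind(exon_rows[[g]],
        data.frame(chr = chr, start = starts[keep], end = ends[keep],
                   strand = strand, gene = gid, tx = paste0(gid, "_t2"),
                   exon_idx = keep))
    }
    gene_rows[[g]] <- data.frame(chr = chr, start = st, end = st + glen - 1L,
                                 strand = strand, gene = gid, n_ex = n_ex)
    gap <- sample(cfg$gene_gap_range[1]:cfg$gene_gap_range[2], 1)
    gap_rows[[g]] <- data.frame(chr = chr, start = st + glen + 20L,
                                end = st + glen + gap - 20L)
    cursor[chr] <- st + glen + gap
  }
  exdf <- do.call(rbind, exon_rows)
  gdf <- do.call(rbind, gene_rows)
  gapdf <- do.call(rbind, gap_rows)
  gapdf <- gapdf[gapdf$end - gapdf$start >= 300L, ]
  annotation <- build_annotation(GenomicRanges::GRanges(
    exdf$chr, IRanges::IRanges(exdf$start, exdf$end), strand = exdf$strand,
    gene_id = exdf$gene, transcript_id = exdf$tx), seqlengths = sq)

  ## 3. circRNA placement -----------------------------------------------
  set.seed(derive_seed(seed, 3L))
  classes <- names(cfg$class_mix)
  n_per <- diff(c(0L, floor(cumsum(cfg$class_mix) * cfg$n_circ)))
  names(n_per) <- classes
  class_vec <- rep(classes, n_per)
  n_genic <- sum(n_per[c("genic_exonic", "genic_other", "antisense")])
  host_pool <- sample(gdf$gene, n_genic)   # distinct host genes
  circ <- list()
  hi <- 0L
  gap_pool <- gapdf[sample.int(nrow(gapdf)), ]
  gi <- 0L
  for (k in seq_along(class_vec)) {
    cls <- class_vec[k]
    if (cls != "intergenic") {
      hi <- hi + 1L
      host <- host_pool[hi]
      ge <- exdf[exdf$gene == host & exdf$tx == paste0(host, "_t1"), ]
      gs <- gdf[gdf$gene == host, ]
    }
    if (cls == "genic_exonic") {
      nb <- sample(seq_len(min(3L, nrow(ge))), 1)
      i0 <- sample.int(nrow(ge) - nb + 1L, 1)
      row <- data.frame(chr = gs$chr, start = ge$start[i0], end = ge$end[i0 + nb - 1L],
                        strand = gs$strand, class = cls, gene = host,
                        ex_from = i0, ex_to = i0 + nb - 1L)
    } else if (cls == "genic_other") {
      row <- data.frame(chr = gs$chr, start = ge$start[1] + 7L,
                        end = ge$end[nrow(ge)] - 9L, strand = gs$strand,
                        class = cls, gene = host, ex_from = NA, ex_to = NA)
    } else if (cls == "antisense") {
      len <- min(400L, gs$end - gs$start - 60L)
      row <- data.frame(chr = gs$chr, start = gs$start + 20L,
                        end = gs$start + 20L + len, strand = setdiff(c("+", "-"), gs$strand),
                        class = cls, gene = NA, ex_from = NA, ex_to = NA)
    } else {
      gi <- gi + 1L
      gp <- gap_pool[gi, ]
      len <- min(350L, gp$end - gp$start - 100L)
      row <- data.frame(chr = gp$chr, start = gp$start + 50L,
                        end = gp$start + 50L + len, strand = sample(c("+", "-"), 1),
                        class = cls, gene = NA, ex_from = NA, ex_to = NA)
    }
    circ[[k]] <- row
  }
  cdf <- do.call(rbind, circ)
  o <- order(cdf$chr, cdf$start, cdf$end, cdf$strand)
  cdf <- cdf[o, ]
  cdf$circ_id <- make_circ_ids(nrow(cdf))
  rownames(cdf) <- cdf$circ_id
  junctions <- GenomicRanges::GRanges(
    cdf$chr, IRanges::IRanges(cdf$start, cdf$end), strand = cdf$strand,
    name = cdf$circ_id, support = sample(2:50, nrow(cdf), replace = TRUE))

  # truth features: exon blocks and gaps for genic-exonic, span otherwise
  feats <- list()
  for (i in seq_len(nrow(cdf))) {
    if (cdf$class[i] == "genic_exonic") {
      ge <- exdf[exdf$gene == cdf$gene[i] & exdf$tx == paste0(cdf$gene[i], "_t1"), ]
      ex <- ge[cdf$ex_from[i]:cdf$ex_to[i], ]
      rows <- data.frame(chr = ex$chr, start = ex$start, end = ex$end,
                         kind = "exon")
      if (nrow(ex) > 1) {
        rows <- rbind(rows, data.frame(chr = ex$chr[-1],
                                       start = ex$end[-nrow(ex)] + 1L,
                                       end = ex$start[-1] - 1L, kind = "intron"))
      }
      rows <- rows[order(rows$start), ]
    } else {
      rows <- data.frame(chr = cdf$chr[i], start = cdf$start[i],
                         end = cdf$end[i], kind = "exon")
    }
    rows$circ_id <- cdf$circ_id[i]
    rows$ordinal <- seq_len(nrow(rows))
    rows$strand <- cdf$strand[i]
    feats[[i]] <- rows
  }
  fdf <- do.call(rbind, feats)
  features <- GenomicRanges::GRanges(fdf$chr, IRanges::IRanges(fdf$start, fdf$end),
                                     strand = fdf$strand, kind = fdf$kind,
                                     circ_id = fdf$circ_id, ordinal = fdf$ordinal)
  fid <- feature_ids(features)
  exon_len <- circ_exon_lengths(features)[cdf$circ_id]

  ## 4. expression planting ---------------------------------------------
  set.seed(derive_seed(seed, 4L))
  pops <- cfg$populations
  n_expr <- round(cfg$frac_expressed * nrow(cdf))
  expressed <- sort(sample.int(nrow(cdf), n_expr))
  cdf$expressed <- seq_len(nrow(cdf)) %in% expressed
  cdf$label <- NA_character_
  cdf$label[cdf$expressed] <- sample(names(cfg$trajectory_mix), n_expr,
                                     replace = TRUE, prob = cfg$trajectory_mix)
  base_count <- 9L * sample(10:28, nrow(cdf), replace = TRUE)
  mult <- function(ch) switch(ch, U = cfg$fc_up_planted, D = cfg$fc_down_planted, F = 1)
  pop_counts <- matrix(0L, nrow(cdf), length(pops),
                       dimnames = list(cdf$circ_id, pops))
  for (i in which(cdf$expressed)) {
    l1 <- substr(cdf$label[i], 1, 1); l2 <- substr(cdf$label[i], 2, 2)
    m <- c(1, mult(l1), mult(l1) * mult(l2))
    pop_counts[i, ] <- as.integer(round(base_count[i] * m))
  }
  # allocate circ-level counts to exon features by largest remainder
  exp_counts <- matrix(0L, length(features), length(pops),
                       dimnames = list(fid, pops))
  for (i in seq_len(nrow(cdf))) {
    sel <- which(features$circ_id == cdf$circ_id[i] & features$kind == "exon")
    w <- GenomicRanges::width(features)[sel]
    for (p in seq_along(pops)) {
      tot <- pop_counts[i, p]
      raw <- tot * w / sum(w)
      fl <- floor(raw)
      rem <- tot - sum(fl)
      if (rem > 0) {
        add <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
        fl[add] <- fl[add] + 1L
      }
      exp_counts[sel, p] <- as.integer(fl)
    }
  }
  true_rpkm <- sweep(pop_counts / (cfg$library_size * 1e-6), 1,
                     exon_len * 1e-3, "/")
  # validated circRNAs: genic-exonic, expressed, with introns (all intron
  # counts are zero -> the derived threshold bounds the intron noise floor)
  with_intron <- unique(features$circ_id[features$kind == "intron"])
  validated <- head(cdf$circ_id[cdf$expressed & cdf$circ_id %in% with_intron], 5)

  ## 5. miRNAs and seed planting ----------------------------------------
  set.seed(derive_seed(seed, 5L))
  mirnas <- generate_mirnas(cfg$n_mirnas, cfg$mirna_length)
  eligible <- cdf$circ_id[cdf$expressed & exon_len >= 200]
  n_orf <- min(cfg$n_orf_circs, max(0L, length(eligible) - cfg$n_seed_circs))
  picks <- sample(eligible, cfg$n_seed_circs + n_orf)
  seed_circs <- picks[seq_len(cfg$n_seed_circs)]
  orf_circs <- picks[cfg$n_seed_circs + seq_len(n_orf)]
  circs_gr <- GenomicRanges::GRanges(cdf$chr, IRanges::IRanges(cdf$start, cdf$end),
                                     strand = cdf$strand, circ_id = cdf$circ_id,
                                     circ_class = cdf$class, gene_id = cdf$gene)
  seed_truth <- list()
  for (si in seq_along(seed_circs)) {
    cid <- seed_circs[si]
    cf <- features[features$circ_id == cid & features$kind == "exon"]
    cf <- cf[order(GenomicRanges::start(cf))]
    strand <- as.character(GenomicRanges::strand(cf))[1]
    seq0 <- mature_seq_from_char(genome, cf, strand)
    L <- nchar(seq0)
    n_m <- sample(1:2, 1)
    mids <- sample(names(mirnas), n_m)
    plan <- data.frame(mirna_id = mids,
                       category = sample(c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                                         n_m, replace = TRUE),
                       n = sample(1:3, n_m, replace = TRUE))
    junction_site <- si == 1L  # one circRNA gets a junction-spanning 8mer
    if (junction_site) plan$category[1] <- "8mer"
    seq1 <- scrub_seed_sites(seq0, mirnas)
    pos_used <- integer(0)
    for (r in seq_len(nrow(plan))) {
      n_here <- plan$n[r]
      positions <- NULL
      if (junction_site && r == 1L) {
        positions <- c(L - 2L, if (n_here > 1)
          pick_site_positions(L, n_here - 1L, avoid = c(pos_used, L - 2L)))
      } else {
        positions <- pick_site_positions(L, n_here, avoid = pos_used)
      }
      seq1 <- plant_seed_sites(seq1, mirnas[[plan$mirna_id[r]]], n_here,
                               category = plan$category[r], positions = positions,
                               verify = FALSE)
      pos_used <- c(pos_used, positions)
    }
    # verification pass with the scanner itself; scrub accidental extras
    for (round in 1:6) {
      ok <- TRUE
      for (r in seq_len(nrow(plan))) {
        hits <- scan_seeds(seq1, mirnas[[plan$mirna_id[r]]], with_scores = FALSE)
        if (sum(hits$category == plan$category[r]) != plan$n[r] ||
            nrow(hits) != plan$n[r]) ok <- FALSE
      }
      if (ok) break
      if (round == 6) stop("could not plant seed sites without extras", call. = FALSE)
      seq1 <- scrub_seed_sites(seq1, mirnas, keep_pos = pos_used)
    }
    genome <- write_mature_seq(genome, cf, strand, seq1)
    plan$circ_id <- cid
    seed_truth[[si]] <- plan
  }
  seed_truth <- do.call(rbind, seed_truth)

  ## 6. ORF planting -----------------------------------------------------
  set.seed(derive_seed(seed, 6L))
  codon_usage <- synthetic_codon_usage()
  w_tab <- relative_adaptiveness(codon_usage)
  cdf$orf_planted <- cdf$circ_id %in% orf_circs
  for (cid in orf_circs) {
    cf <- features[features$circ_id == cid & features$kind == "exon"]
    cf <- cf[order(GenomicRanges::start(cf))]
    strand <- as.character(GenomicRanges::strand(cf))[1]
    seq0 <- mature_seq_from_char(genome, cf, strand)
    n_cod <- sample(cfg$orf_n_codons[1]:cfg$orf_n_codons[2], 1)
    orf <- paste0("ATG", paste(sample_biased_codons(n_cod - 2L, w_tab), collapse = ""), "TAA")
    if (nchar(orf) + 6L > nchar(seq0)) next
    at <- sample.int(nchar(seq0) - nchar(orf) - 3L, 1)
    substr(seq0, at, at + nchar(orf) - 1L) <- orf
    genome <- write_mature_seq(genome, cf, strand, seq0)
  }

  ## 7. reads -------------------------------------------------------------
  set.seed(derive_seed(seed, 7L))
  samples <- paste(rep(pops, each = cfg$n_replicates), 1:cfg$n_replicates, sep = "_")
  sample_pops <- rep(pops, each = cfg$n_replicates)
  reads_by_sample <- vector("list", length(samples))
  names(reads_by_sample) <- samples
  realized_counts <- matrix(0L, length(features), length(samples),
                            dimnames = list(fid, samples))
  fw <- GenomicRanges::width(features)
  fchr <- as.character(GenomicRanges::seqnames(features))
  fst <- GenomicRanges::start(features)
  fstr <- as.character(GenomicRanges::strand(features))
  for (j in seq_along(samples)) {
    mu <- exp_counts[, sample_pops[j]]
    n_ij <- switch(cfg$noise,
      none = mu,
      poisson = rpois(length(mu), mu),
      nb = ifelse(mu > 0, rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion), 0L))
    n_ij <- as.integer(n_ij)
    realized_counts[, j] <- n_ij
    tot <- sum(n_ij)
    if (tot > cfg$library_size) {
      stop("infeasible config: planted reads exceed the library size", call. = FALSE)
    }
    idx <- rep(seq_along(n_ij), n_ij)
    rl <- pmin(cfg$read_length, fw[idx])
    st <- fst[idx] + floor(runif(length(idx)) * (fw[idx] - rl + 1L))
    # background reads pad the library to its exact nominal size
    n_bg <- cfg$library_size - tot
    bg_chr <- sample(names(sq), n_bg, replace = TRUE)
    bg_block_start <- GenomicRanges::start(bg_blocks)[match(bg_chr, as.character(GenomicRanges::seqnames(bg_blocks)))]
    bg_st <- bg_block_start + sample.int(bg_width - cfg$read_length, n_bg, replace = TRUE) - 1L
    reads_by_sample[[j]] <- GenomicRanges::GRanges(
      c(fchr[idx], bg_chr),
      IRanges::IRanges(start = c(st, bg_st), width = c(rl, rep(cfg$read_length, n_bg))),
      strand = c(fstr[idx], rep("+", n_bg)))
  }
  library_sizes <- setNames(rep(cfg$library_size, length(samples)), samples)

  ## 8. conservation track ------------------------------------------------
  expr_feats <- features[features$circ_id %in% cdf$circ_id[cdf$expressed] &
                         features$kind == "exon"]
  flank_list <- suppressWarnings(do.call(c, lapply(which(cdf$expressed), function(i)
    flanks(circs_gr[i], 200, sq))))
  conserved <- c(GenomicRanges::granges(expr_feats), GenomicRanges::granges(flank_list))
  elev <- c(rep(cfg$cons_elevation, length(expr_feats)),
            rep(cfg$cons_flank_elevation, length(flank_list)))
  mask <- GenomicRanges::GRanges(names(sq), IRanges::IRanges(1L, 200L))
  track <- generate_conservation_track(sq, conserved, elevation = elev,
                                       base_level = cfg$cons_base,
                                       noise_sd = cfg$cons_noise_sd,
                                       seed = derive_seed(seed, 8L), mask = mask)

  ## 9. linear expression, isoform table, exon fold changes ---------------
  set.seed(derive_seed(seed, 9L))
  genic <- !is.na(cdf$gene)
  lin <- matrix(2^runif(sum(genic) * length(pops), -2, 6), sum(genic), length(pops),
                dimnames = list(cdf$gene[genic], pops))
  # correlation is planted over the pairs that enter the comparison:
  # expressed genic circRNAs, one point per circRNA and population
  eg <- which(cdf$expressed & genic)
  x <- log2(true_rpkm[eg, , drop = FALSE] + 1e-3)
  xs <- (x - mean(x)) / stats::sd(x)
  z <- matrix(rnorm(length(x)), nrow(x))
  ys <- cfg$linear_target_r * xs + sqrt(1 - cfg$linear_target_r^2) * z
  lin[match(cdf$gene[eg], rownames(lin)), ] <-
    pmax(0, 2^(ys * stats::sd(x) + mean(x)) - 1e-3)
  # isoform RPKM: both isoforms of alternatively spliced genes expressed
  txs <- unique(annotation$exons$transcript_id)
  iso_gene <- setNames(sub("_t[12]$", "", txs), txs)
  iso_rpkm <- matrix(2^runif(length(txs) * length(pops), -2, 8),
                     length(txs), length(pops), dimnames = list(txs, pops))
  as_gene_ids <- names(as_skip)
  both <- iso_gene %in% as_gene_ids
  iso_rpkm[both, ] <- 2^runif(sum(both) * length(pops), 3, 8)  # > threshold
  # shared-exon fold changes and planted concordance
  expr_genic <- which(cdf$expressed & genic)
  exon_fc <- matrix(1, length(expr_genic), 2,
                    dimnames = list(cdf$circ_id[expr_genic], c("t1", "t2")))
  circ_fc_planted <- t(vapply(expr_genic, function(i) {
    l1 <- substr(cdf$label[i], 1, 1); l2 <- substr(cdf$label[i], 2, 2)
    c(mult(l1), mult(l2))
  }, numeric(2)))
  concord <- ifelse(cdf$label[expr_genic] == "FF", "mixed", "same")
  opp <- head(which(concord == "same"), cfg$n_opposite_pairs)
  concord[opp] <- "opposite"
  exon_fc[] <- circ_fc_planted
  exon_fc[opp, ] <- 1 / circ_fc_planted[opp, ]
  exon_fc[concord == "mixed", ] <- 1
  names(concord) <- cdf$circ_id[expr_genic]
  # alternative-splicing truth, from planting bookkeeping
  thr <- cfg$expression_threshold
  hosted <- cdf$expressed & !is.na(cdf$gene) & cdf$gene %in% as_gene_ids
  sharing <- vapply(seq_len(nrow(cdf)), function(i) {
    if (!hosted[i] || cdf$class[i] != "genic_exonic") return(FALSE)
    g <- cdf$gene[i]
    t1_all <- all(iso_rpkm[paste0(g, "_t1"), ] > thr)
    t1_all || any(cdf$ex_from[i]:cdf$ex_to[i] != as_skip[[g]])
  }, logical(1))
  as_truth <- list(n_as_genes = length(as_gene_ids),
                   n_circ_in_as_genes = sum(hosted),
                   frac_circ_in_as_genes = sum(hosted) / sum(cdf$expressed),
                   n_circ_sharing_exon = sum(sharing))

  ## 10. truth manifest ----------------------------------------------------
  truth <- list(
    seed = seed,
    library_sizes = library_sizes,
    circs = data.frame(
      circ_id = cdf$circ_id, chrom = cdf$chr, start = cdf$start, end = cdf$end,
      strand = cdf$strand, circ_class = cdf$class, gene_id = cdf$gene,
      n_exons = vapply(cdf$circ_id, function(id)
        sum(features$circ_id == id & features$kind == "exon"), integer(1)),
      exon_length = unname(exon_len),
      expressed = cdf$expressed, label = cdf$label,
      orf_planted = cdf$orf_planted,
      cons_elevation = ifelse(cdf$expressed, cfg$cons_elevation, 0)
    ),
    rpkm = true_rpkm,
    pop_counts = pop_counts,
    feature_expected_counts = exp_counts,
    realized_counts = realized_counts,
    features = fdf,
    validated_circ_ids = validated,
    seed_sites = seed_truth,
    concordance = concord,
    exon_fc = exon_fc,
    linear_target_r = cfg$linear_target_r,
    as_genes = as_gene_ids,
    alt_splicing = as_truth,
    funnel = c(putative = nrow(cdf), expressed = sum(cdf$expressed))
  )

  list(genome = Biostrings::DNAStringSet(genome), annotation = annotation,
       junctions = junctions, reads_by_sample = reads_by_sample,
       library_sizes = library_sizes, sample_populations = sample_pops,
       mirnas = mirnas, codon_usage = codon_usage, track = track,
       linear_rpkm = lin, isoform_rpkm = iso_rpkm, isoform_gene = iso_gene,
       exon_fc = exon_fc, config = cfg, truth = truth)
}

# random mature miRNA library whose 6mer target cores are pairwise distinct
# and non-self-overlapping (no period < 6), so planted sites cannot collide
generate_mirnas <- function(n, len) {
  out <- character(0)
  cores <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stop("could not generate distinct miRNA library", call. = FALSE)
    m <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
    mb <- strsplit(m, "")[[1]]
    core <- paste(rev(COMP_RNA[mb[2:7]]), collapse = "")
    periodic <- any(vapply(1:5, function(p)
      substr(core, 1, 6 - p) == substr(core, p + 1, 6), logical(1)))
    # also forbid 5-base shifted agreement with existing cores, so one
    # miRNA's core can never arise inside another's planted 8-nt window
    shifted <- any(vapply(cores, function(cc)
      substr(core, 2, 6) == substr(cc, 1, 5) || substr(core, 1, 5) == substr(cc, 2, 6),
      logical(1)))
    if (core %in% cores || periodic || shifted) next
    out <- c(out, m)
    cores <- c(cores, core)
  }
  setNames(out, sprintf("syn-miR-%d", seq_len(n)))
}

# mature sequence of a circRNA from a character-vector genome
mature_seq_from_char <- function(genome, exon_features, strand) {
  pieces <- vapply(seq_along(exon_features), function(i)
    substr(genome[[as.character(GenomicRanges::seqnames(exon_features))[i]]],
           GenomicRanges::start(exon_features)[i], GenomicRanges::end(exon_features)[i]),
    character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

# write an edited mature sequence back into the genome (inverse of the above)
write_mature_seq <- function(genome, exon_features, strand, new_seq) {
  g <- if (strand == "-") revcomp(new_seq) else new_seq
  w <- GenomicRanges::width(exon_features)
  stopifnot(nchar(g) == sum(w))
  offs <- cumsum(c(0L, head(w, -1)))
  for (i in seq_along(exon_features)) {
    chr <- as.character(GenomicRanges::seqnames(exon_features))[i]
    piece <- substr(g, offs[i] + 1L, offs[i] + w[i])
    substr(genome[[chr]], GenomicRanges::start(exon_features)[i],
           GenomicRanges::end(exon_features)[i]) <- piece
  }
  genome
}

# non-overlapping planting positions (0-based core starts kept 1-based here),
# spaced >= 16 nt apart and away from the junction region
pick_site_positions <- function(L, n, avoid = integer(0), spacing = 16L) {
  if (n == 0L) return(integer(0))
  cand <- seq(10L, L - 12L, by = spacing)
  if (length(avoid)) {
    cand <- cand[vapply(cand, function(p) all(abs(p - avoid) >= spacing), logical(1))]
  }
  if (length(cand) < n) stop("cannot place seed sites without overlap", call. = FALSE)
  sort(sample(cand, n))
}

#' Plant miRNA seed sites into a sequence
#'
#' Writes `n` non-overlapping sites of the requested Bartel category into the
#' sequence (an 8-nt window per site: the base opposite miRNA position 8, the
#' 6mer core complementary to miRNA positions 2-7, and the base opposite
#' position 1). Flanking bases are chosen so the site has exactly the
#' requested category and not a higher one. With `verify = TRUE` the edited
#' sequence is re-scanned with [scan_seeds()] and an error is raised unless
#' exactly `n` sites of the category (and no others for this miRNA) are
#' found.
#'
#' @param sequence target sequence
#' @param mirna_seq miRNA sequence 5'->3'
#' @param n number of sites (0 returns the sequence unchanged)
#' @param category one of `8mer`, `7mer-m8`, `7mer-A1`, `6mer`
#' @param positions optional 1-based core start positions (may wrap the
#'   junction modulo the sequence length); chosen automatically if `NULL`
#' @param verify re-scan and error on accidental extra sites
#' @return the edited sequence (character)
#' @export
plant_seed_sites <- function(sequence, mirna_seq, n, category = "8mer",
                             positions = NULL, verify = TRUE) {
  if (n == 0L) return(sequence)
  s <- strsplit(dna2rna(sequence), "")[[1]]
  m <- strsplit(dna2rna(mirna_seq), "")[[1]]
  L <- length(s)
  if (is.null(positions)) positions <- pick_site_positions(L, n)
  stopifnot(length(positions) == n)
  core <- rev(COMP_RNA[m[2:7]])
  comp_m8 <- COMP_RNA[[m[8]]]
  not_m8 <- setdiff(c("A", "C", "G", "U"), comp_m8)[1]
  for (p in positions) {
    at <- function(q, b) {
      q <- ((q - 1L) %% L) + 1L
      s[q] <<- b
    }
    at(p - 1L, if (category %in% c("8mer", "7mer-m8")) comp_m8 else not_m8)
    for (k in 0:5) at(p + k, core[k + 1L])
    at(p + 6L, if (category %in% c("8mer", "7mer-A1")) "A"
       else setdiff(c("G", "C", "U"), comp_m8)[1])
  }
  out <- paste(s, collapse = "")
  was_dna <- !grepl("U", toupper(sequence))
  if (was_dna) out <- rna2dna(out)
  if (verify) {
    hits <- scan_seeds(out, mirna_seq, with_scores = FALSE)
    if (nrow(hits) != n || sum(hits$category == category) != n) {
      stop("cannot place seed sites without creating extras", call. = FALSE)
    }
  }
  out
}

# remove accidental seed cores (any library miRNA) from a sequence,
# leaving the 8-nt windows around kept core positions untouched
scrub_seed_sites <- function(sequence, mirnas, keep_pos = integer(0), max_iter = 25L) {
  s <- strsplit(dna2rna(sequence), "")[[1]]
  L <- length(s)
  keep_bases <- unique(unlist(lapply(keep_pos, function(p)
    ((p - 2L):(p + 6L) - 1L) %% L + 1L)))
  cycle <- c(A = "C", C = "G", G = "U", U = "A")
  for (it in seq_len(max_iter)) {
    txt <- paste(s, collapse = "")
    dirty <- FALSE
    for (mi in seq_along(mirnas)) {
      hits <- scan_seeds(txt, mirnas[[mi]], with_scores = FALSE)
      for (p0 in hits$start) {
        p <- p0 + 1L
        if (p %in% keep_pos) next
        span <- ((p:(p + 5L)) - 1L) %% L + 1L
        mutable <- setdiff(span, keep_bases)
        if (!length(mutable)) next
        q <- mutable[ceiling(length(mutable) / 2)]
        s[q] <- cycle[[s[q]]]
        dirty <- TRUE
      }
      if (dirty) break
    }
    if (!dirty) break
  }
  out <- paste(s, collapse = "")
  if (!grepl("U", toupper(sequence))) out <- rna2dna(out)
  out
}

#' Generate a synthetic per-base conservation track
#'
#' Per-base score = `base_level` + `elevation` over the conserved intervals
#' + Gaussian noise; masked intervals carry no score.
#'
#' @param seqlengths named chromosome lengths
#' @param conserved `GRanges` of intervals carrying elevated scores
#' @param elevation scalar or per-interval vector of score elevations
#' @param base_level background score level
#' @param noise_sd Gaussian noise standard deviation (0 for a noiseless track)
#' @param seed integer seed
#' @param mask optional `GRanges` of positions left uncovered (`NA`)
#' @return `cons_track`
#' @export
generate_conservation_track <- function(seqlengths, conserved = NULL,
                                        elevation = 0.5, base_level = 0,
                                        noise_sd = 0.2, seed = 1, mask = NULL) {
  set.seed(derive_seed(seed, 21L))
  if (!is.null(conserved)) {
    if (length(elevation) == 1L) elevation <- rep(elevation, length(conserved))
    stopifnot(length(elevation) == length(conserved))
    over <- GenomicRanges::end(conserved) >
      seqlengths[as.character(GenomicRanges::seqnames(conserved))]
    if (any(over) || any(GenomicRanges::start(conserved) < 1L)) {
      stop("conserved interval outside the genome", call. = FALSE)
    }
  }
  scores <- lapply(names(seqlengths), function(chr) {
    n <- seqlengths[[chr]]
    v <- rep(base_level, n)
    if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
    v
  })
  names(scores) <- names(seqlengths)
  if (!is.null(conserved)) {
    for (i in seq_along(conserved)) {
      chr <- as.character(GenomicRanges::seqnames(conserved))[i]
      idx <- GenomicRanges::start(conserved)[i]:GenomicRanges::end(conserved)[i]
      scores[[chr]][idx] <- scores[[chr]][idx] + elevation[i]
    }
  }
  if (!is.null(mask)) {
    for (i in seq_along(mask)) {
      chr <- as.character(GenomicRanges::seqnames(mask))[i]
      if (!chr %in% names(scores)) next
      idx <- max(1L, GenomicRanges::start(mask)[i]):min(seqlengths[[chr]], GenomicRanges::end(mask)[i])
      scores[[chr]][idx] <- NA_real_
    }
  }
  structure(list(scores = scores, seqlengths = seqlengths), class = "cons_track")
}

# codon usage with a reproducible bias: within each synonymous family the
# lexicographically first codon is favoured 4:1
synthetic_codon_usage <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- sort(names(code)[code != "*"])
  aa <- code[sense]
  usage <- numeric(length(sense))
  names(usage) <- sense
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    wts <- c(4, rep(1, length(fam) - 1L))
    usage[fam] <- wts / sum(wts)
  }
  usage * 1000 / sum(usage)
}

# sample sense codons with probability proportional to relative adaptiveness
sample_biased_codons <- function(n, w, bias = 3) {
  probs <- w^bias
  sample(names(w), n, replace = TRUE, prob = probs)
}

#' Jointly simulate correlated circular and linear RPKM vectors
#'
#' Bivariate log-normal pairs with a configurable Pearson correlation on the
#' log2 scale, used both by the full generator and on its own to check
#' correlation recovery.
#'
#' @param n number of pairs
#' @param target_r target Pearson correlation of the log2 values
#' @param seed integer seed
#' @param meanlog2,sdlog2 location and scale of the log2-RPKM distribution
#' @return data.frame with `circ_rpkm`, `linear_rpkm`
#' @export
simulate_correlated_rpkm <- function(n, target_r = 0.8, seed = 1,
                                     meanlog2 = 4, sdlog2 = 2) {
  set.seed(derive_seed(seed, 31L))
  x <- rnorm(n)
  y <- target_r * x + sqrt(1 - target_r^2) * rnorm(n)
  data.frame(circ_rpkm = 2^(meanlog2 + sdlog2 * x),
             linear_rpkm = 2^(meanlog2 + sdlog2 * y))
}
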