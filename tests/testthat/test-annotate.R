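test_that("junctions are classified into the four classes by the boundary rule", {
  ann <- toy_annotation()
  cls <- function(j) {
    c <- suppressWarnings(classify_junctions(j, ann))
    list(class = c$circ_class, gene = c$gene_id)
  }
  # both ends on exon boundaries of the same-strand gene
  expect_equal(cls(toy_junction(101, 400))$class, "genic_exonic")
  expect_equal(cls(toy_junction(101, 400))$gene, "geneA")
  # single-exon span
  expect_equal(cls(toy_junction(301, 400))$class, "genic_exonic")
  # ends mid-exon on the same strand
  expect_equal(cls(toy_junction(150, 350))$class, "genic_other")
  expect_equal(cls(toy_junction(150, 350))$gene, "geneA")
  # one matching boundary only is not exon-bounded
  expect_equal(cls(toy_junction(101, 350))$class, "genic_other")
  # opposite strand only
  expect_equal(cls(toy_junction(2010, 2090, strand = "+"))$class, "antisense")
  # no gene overlap
  expect_equal(cls(toy_junction(1000, 1500))$class, "intergenic")
})

test_that("junctions on chromosomes absent from the annotation are intergenic with a warning", {
  ann <- toy_annotation()
  expect_warning(res <- classify_junctions(toy_junction(10, 50, chrom = "chrX"), ann),
                 "absent")
  expect_equal(res$circ_class, "intergenic")
})

test_that("multi-gene ambiguity resolves by boundary count then gene id", {
  # two same-strand genes overlapping; only gene "aa" matches both boundaries
  ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 300, 120, 300), c(200, 400, 200, 380)),
    strand = "+",
    gene_id = c("zz", "zz", "aa", "aa"),
    transcript_id = c("tz", "tz", "ta", "ta"))
  ann <- build_annotation(ex)
  got <- classify_junctions(toy_junction(120, 380), ann)
  expect_equal(got$circ_class, "genic_exonic")
  expect_equal(got$gene_id, "aa")
  # exact tie (both genes match both boundaries): lexicographically smaller id
  ex2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 300, 100, 300), c(200, 400, 200, 400)),
    strand = "+",
    gene_id = c("zz", "zz", "aa", "aa"),
    transcript_id = c("tz", "tz", "ta", "ta"))
  got2 <- classify_junctions(toy_junction(100, 400), build_annotation(ex2))
  expect_equal(got2$gene_id, "aa")
})

test_that("boundary matching uses the union of exons across transcripts", {
  # the span's boundaries come from two different transcripts of one gene
  ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 500, 300), c(200, 600, 400)),
    strand = "+", gene_id = "g1",
    transcript_id = c("t1", "t1", "t2"))
  ann <- build_annotation(ex)
  got <- classify_junctions(toy_junction(100, 400), ann)
  expect_equal(got$circ_class, "genic_exonic")
  feats <- decompose_features(got, ann)
  expect_equal(sum(feats$kind == "exon"), 2L)  # union blocks 100-200, 300-400
})

test_that("decomposition alternates exons and introns that tile the span", {
  ann <- toy_annotation()
  circ <- classify_junctions(toy_junction(101, 400), ann)
  feats <- decompose_features(circ, ann)
  expect_equal(feats$kind, c("exon", "intron", "exon"))
  expect_equal(feats$ordinal, 1:3)
  expect_equal(sum(GenomicRanges::width(feats)), GenomicRanges::width(circ))
  # single exon: no introns
  circ1 <- classify_junctions(toy_junction(301, 400), ann)
  expect_equal(decompose_features(circ1, ann)$kind, "exon")
  # non-genic-exonic circRNAs are one exon feature covering the span
  circ2 <- classify_junctions(toy_junction(1000, 1399), ann)
  f2 <- decompose_features(circ2, ann)
  expect_equal(f2$kind, "exon")
  expect_equal(GenomicRanges::width(f2), 400L)
})

test_that("mature sequences concatenate exons and respect strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTTAACCGGTT"))
  mk <- function(start, end, strand) {
    circs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(min(start), max(end)),
                                    strand = strand, circ_id = "c1",
                                    circ_class = "genic_exonic", gene_id = "g")
    feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                    strand = strand, kind = "exon",
                                    circ_id = "c1", ordinal = seq_along(start))
    as.character(reconstruct_sequences(circs, feats, genome))
  }
  expect_equal(unname(mk(1, 4, "+")), "AACC")
  expect_equal(unname(mk(1, 4, "-")), "GGTT")  # revcomp of AACC
  # two exons concatenate in genomic order on the plus strand
  expect_equal(unname(mk(c(1, 5), c(2, 6), "+")), "AAGG")
  # and in transcription order (reverse complement) on the minus strand
  expect_equal(unname(mk(c(1, 5), c(2, 6), "-")), "CCTT")
  # introns are excluded from the mature sequence
  circs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 8), strand = "+",
                                  circ_id = "c1", circ_class = "genic_exonic",
                                  gene_id = "g")
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 3, 7), c(2, 6, 8)),
                                  strand = "+", kind = c("exon", "intron", "exon"),
                                  circ_id = "c1", ordinal = 1:3)
  expect_equal(unname(as.character(reconstruct_sequences(circs, feats, genome))), "AATT")
})

test_that("features beyond the chromosome end are an error", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  circs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), strand = "+",
                                  circ_id = "c1", circ_class = "intergenic")
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), strand = "+",
                                  kind = "exon", circ_id = "c1", ordinal = 1L)
  expect_error(reconstruct_sequences(circs, feats, genome), "beyond")
})

test_that("catalog overlap is reciprocal and supports single-nucleotide mode", {
  circs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 1000, 5000),
                                                           width = c(100, 100, 400)),
                                  circ_id = c("a", "b", "c"))
  catalog <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 1099, 5000),
                                                             width = c(100, 50, 50)))
  # identical intervals: known at f = 1
  r <- catalog_overlap(circs, catalog, min_frac = 1)
  expect_true(r$known[r$circ_id == "a"])
  expect_equal(r$overlap_level[r$circ_id == "a"], "1")
  # 1-bp overlap: novel at f = 0.5, known in single-nucleotide mode
  expect_false(r$known[r$circ_id == "b"])
  r1 <- catalog_overlap(circs, catalog, single_nt = TRUE)
  expect_true(r1$known[r1$circ_id == "b"])
  expect_equal(r$overlap_level[r$circ_id == "b"], "single_nt")
  # reciprocity: 50/50 for the catalog entry but 50/400 for the circRNA
  r2 <- catalog_overlap(circs, catalog, min_frac = 0.5)
  expect_false(r2$known[r2$circ_id == "c"])
  expect_equal(r2$best_reciprocal[r2$circ_id == "c"], 50 / 400)
})

test_that("classification on the synthetic bundle recovers every planted class", {
  b <- default_bundle()
  r <- default_run()
  tr <- b$truth$circs
  expect_identical(r$annotate$circs$circ_id, tr$circ_id)
  expect_equal(r$annotate$circs$circ_class, tr$circ_class)
  expect_equal(r$annotate$circs$gene_id, ifelse(is.na(tr$gene_id), NA, tr$gene_id))
  # exact feature decomposition, and feature lengths tile genic-exonic spans
  f <- r$annotate$features
  key <- paste(f$circ_id, f$kind, f$ordinal, GenomicRanges::start(f), GenomicRanges::end(f))
  tf <- b$truth$features
  expect_setequal(key, paste(tf$circ_id, tf$kind, tf$ordinal, tf$start, tf$end))
  ge <- tr$circ_id[tr$circ_class == "genic_exonic"]
  span_w <- setNames(tr$end - tr$start + 1L, tr$circ_id)
  tiled <- tapply(GenomicRanges::width(f)[f$circ_id %in% ge],
                  f$circ_id[f$circ_id %in% ge], sum)
  expect_equal(as.vector(tiled[ge]), as.vector(span_w[ge]))
})
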