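test_that("rpkm matches its closed form and rejects degenerate inputs", {
  expect_equal(rpkm(10, 1e6, 1000), 10)
  expect_equal(rpkm(0, 12345, 777), 0)
  expect_equal(rpkm(7, 2e6, 500), 7)  # 7 / (2 * 0.5)
  expect_error(rpkm(1, 0, 100), "library")
  expect_error(rpkm(1, 1e6, 0), "length")
})

test_that("rpkm is invariant under joint scaling of counts and library size", {
  set.seed(1)
  counts <- matrix(rpois(30, 20), 10, 3)
  libs <- c(1e5, 2e5, 3e5)
  lens <- sample(100:2000, 10)
  r1 <- rpkm_matrix(counts, libs, lens)
  r2 <- rpkm_matrix(counts * 7, libs * 7, lens)
  expect_equal(r1, r2)
})

test_that("feature counting is strand-aware and multi-feature reads count in each", {
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 201), c(200, 300)),
                                  strand = "+", kind = c("exon", "intron"),
                                  circ_id = "c1", ordinal = 1:2)
  reads <- list(
    s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(110, 190, 150), width = 20),
                                strand = c("+", "+", "-")))
  m <- count_features(reads, feats)
  expect_equal(m["c1_exon1", "s1"], 2L)    # in-exon read + boundary read
  expect_equal(m["c1_intron2", "s1"], 1L)  # boundary read counts there too
  # wrong-strand read counted nowhere; empty read set gives a zero matrix
  m0 <- count_features(list(s1 = GenomicRanges::GRanges()), feats)
  expect_true(all(m0 == 0))
  # unknown chromosomes are skipped and tallied
  mx <- count_features(list(s1 = GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 50),
                                                        strand = "+")), feats)
  expect_equal(unname(attr(mx, "skipped")["s1"]), 1L)
})

test_that("population means average replicates arithmetically", {
  m <- matrix(c(1, 2, 3, 5, 7, 9), nrow = 1)
  colnames(m) <- paste0("s", 1:6)
  pm <- population_means(m, rep(c("A", "B"), each = 3))
  expect_equal(unname(pm[1, ]), c(2, 7))
})

test_that("the expression threshold is the highest validated-intron RPKM", {
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101, 201), width = 100),
                                  strand = "+", kind = c("exon", "intron", "intron"),
                                  circ_id = "c1", ordinal = 1:3)
  pop <- matrix(c(10, 0.2, 3.5, 12, 1.1, 0.7), ncol = 2,
                dimnames = list(feature_ids(feats), c("A", "B")))
  expect_equal(derive_threshold("c1", feats, pop), 3.5)
  # single intron with zero RPKM
  pop0 <- pop; pop0[2:3, ] <- 0
  expect_equal(derive_threshold("c1", feats, pop0), 0)
  # no validation set: the published default
  expect_equal(derive_threshold(NULL), 3.5)
  # validated set without introns is an error pointing to the default
  expect_error(derive_threshold("c1", feats[1], pop[1, , drop = FALSE]), "default")
})

test_that("expression calls use strict inequality and exon features only", {
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101, 201, 301), width = 100),
                                  strand = "+",
                                  kind = c("exon", "intron", "exon", "exon"),
                                  circ_id = c("c1", "c1", "c1", "c2"), ordinal = c(1, 2, 3, 1))
  pop <- matrix(c(3.5, 10, 1, 2), ncol = 1, dimnames = list(feature_ids(feats), "A"))
  got <- call_expressed(feats, pop, threshold = 3.5)
  # exon at exactly the threshold is not expressed (strict >)
  expect_false(got$feature_expressed[["c1_exon1"]])
  # an expressed intron does not qualify its circRNA
  expect_true(got$feature_expressed[["c1_intron2"]])
  expect_false("c2" %in% got$expressed_circ_ids)
  expect_false("c1" %in% got$expressed_circ_ids)
  # one expressed exon among several suffices
  pop2 <- pop; pop2["c1_exon3", ] <- 4
  expect_true("c1" %in% call_expressed(feats, pop2, 3.5)$expressed_circ_ids)
})

test_that("meta-feature counts sum exon features per circRNA", {
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101, 201, 301), width = 100),
                                  strand = "+",
                                  kind = c("exon", "intron", "exon", "exon"),
                                  circ_id = c("c1", "c1", "c1", "c2"), ordinal = c(1, 2, 3, 1))
  counts <- matrix(c(3, 100, 4, 7), ncol = 1, dimnames = list(feature_ids(feats), "s1"))
  meta <- meta_feature_counts(counts, feats)
  expect_equal(meta["c1", "s1"], 7)   # 3 + 4; the intron's 100 is excluded
  expect_equal(meta["c2", "s1"], 7)
  zero <- meta_feature_counts(counts * 0, feats)
  expect_true(all(zero == 0))
})

test_that("noiseless counts reproduce planted RPKM and the expressed set exactly", {
  b <- noiseless_bundle()
  r <- noiseless_run()
  meta <- meta_feature_counts(r$quantify$counts, r$annotate$features)
  lens <- circ_exon_lengths(r$annotate$features)[rownames(meta)]
  crpkm <- population_means(rpkm_matrix(meta, b$library_sizes, lens),
                            b$sample_populations)
  tr <- b$truth$rpkm[rownames(crpkm), colnames(crpkm)]
  expect_equal(crpkm, tr, tolerance = 1e-12)
  expect_setequal(r$quantify$expressed_circ_ids,
                  b$truth$circs$circ_id[b$truth$circs$expressed])
})

test_that("expressed-set recall and precision exceed 0.95 under count noise", {
  b <- default_bundle()
  r <- default_run()
  truth <- b$truth$circs$circ_id[b$truth$circs$expressed]
  pred <- r$quantify$expressed_circ_ids
  expect_gte(mean(truth %in% pred), 0.95)
  expect_gte(mean(pred %in% truth), 0.95)
})
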