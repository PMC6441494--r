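make_track <- function(values, chrom = "chr1") {
  structure(list(scores = setNames(list(values), chrom),
                 seqlengths = setNames(length(values), chrom)),
            class = "cons_track")
}

test_that("region means are masked-aware averages over covered bases", {
  tr <- make_track(rep(0.5, 100))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 40))
  expect_equal(region_mean(gr, tr), 0.5)
  tr2 <- make_track(c(rep(1, 50), rep(0, 50)))
  expect_equal(region_mean(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)), tr2), 0.5)
  # only covered bases enter the mean
  v <- rep(NA_real_, 20); v[1:10] <- 2
  tr3 <- make_track(v)
  expect_equal(region_mean(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 20)), tr3), 2)
  # fully masked region: NA
  expect_true(is.na(region_mean(GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20)), tr3)))
  # multi-interval union
  expect_equal(region_mean(GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(5, 15))), tr2), 1)
})

test_that("flanks are strand-aware and clipped at chromosome ends", {
  circ <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1500), strand = "+")
  fl <- flanks(circ, 200, c(chr1 = 10000L))
  up <- fl[fl$side == "upstream"]
  dn <- fl[fl$side == "downstream"]
  expect_equal(c(GenomicRanges::start(up), GenomicRanges::end(up)), c(801, 1000))
  expect_equal(c(GenomicRanges::start(dn), GenomicRanges::end(dn)), c(1501, 1700))
  # minus strand swaps the sides
  GenomicRanges::strand(circ) <- "-"
  flm <- flanks(circ, 200, c(chr1 = 10000L))
  expect_equal(GenomicRanges::start(flm[flm$side == "downstream"]), 801L)
  expect_equal(GenomicRanges::start(flm[flm$side == "upstream"]), 1501L)
  # clipping at the chromosome start records the realized width
  circ2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 400), strand = "+")
  fl2 <- flanks(circ2, 200, c(chr1 = 500L))
  expect_equal(fl2$realized_width[fl2$side == "upstream"], 50L)
  expect_equal(GenomicRanges::end(fl2[fl2$side == "downstream"]), 500L)
})

test_that("matched shuffles respect the class-specific reference and length", {
  ann <- toy_annotation()
  sq <- c(chr1 = 10000L)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 380), strand = "+")
  exonic <- GenomicRanges::reduce(ann$exons, ignore.strand = TRUE)
  set.seed(2)
  for (i in 1:20) {
    s <- shuffle_matched(region, "genic_exonic", FALSE, ann, sq)
    expect_equal(GenomicRanges::width(s), 80L)
    expect_true(length(GenomicRanges::findOverlaps(s, exonic, type = "within")) == 1L)
  }
  # genic flanks shuffle within the intronic reference
  genic <- GenomicRanges::reduce(ann$genes, ignore.strand = TRUE)
  intronic <- GenomicRanges::setdiff(genic, exonic)
  fl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 90), strand = "+")
  for (i in 1:10) {
    s <- shuffle_matched(fl, "genic_exonic", TRUE, ann, sq)
    expect_true(length(GenomicRanges::findOverlaps(s, intronic, type = "within")) == 1L)
  }
  # determinism under a fixed seed
  set.seed(7); a <- shuffle_matched(region, "intergenic", FALSE, ann, sq)
  set.seed(7); b <- shuffle_matched(region, "intergenic", FALSE, ann, sq)
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  # infeasible length names the problem
  big <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000), strand = "+")
  expect_error(shuffle_matched(big, "genic_exonic", FALSE, ann, sq), "host")
})

test_that("the group comparison handles identical and swapped groups", {
  same <- rep(0.4, 10)
  r <- compare_conservation(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  set.seed(8)
  a <- rnorm(30, 1); b <- rnorm(30, 0)
  r1 <- compare_conservation(a, b)
  r2 <- compare_conservation(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("a planted elevation of 0.5 is detected at p < 0.01", {
  sq <- c(chr1 = 120000L)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(1000, by = 1000, length.out = 50), width = 200))
  tr <- generate_conservation_track(sq, regions, elevation = 0.5,
                                    base_level = 0, noise_sd = 0.2, seed = 3)
  real <- vapply(seq_along(regions), function(i) region_mean(regions[i], tr), numeric(1))
  set.seed(33)
  shuf <- vapply(1:50, function(i) {
    st <- sample(60000:110000, 1)
    region_mean(GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = 200)), tr)
  }, numeric(1))
  res <- compare_conservation(real, shuf)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_real - res$mean_shuffled, 0.3)
})

test_that("with no planted elevation the test rejects at the nominal rate", {
  sq <- c(chr1 = 30000L)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(100, by = 290, length.out = 50), width = 100))
  rejections <- 0L
  for (s in 1:200) {
    tr <- generate_conservation_track(sq, conserved = NULL, base_level = 0.1,
                                      noise_sd = 0.2, seed = s)
    real <- vapply(seq_along(regions), function(i) region_mean(regions[i], tr), numeric(1))
    set.seed(s + 4000L)
    shuf <- vapply(1:50, function(i) {
      st <- sample.int(30000L - 100L, 1)
      region_mean(GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = 100)), tr)
    }, numeric(1))
    if (compare_conservation(real, shuf)$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / 200, 0.08)
})

test_that("bundle conservation separates real regions from shuffles", {
  r <- default_run()
  expect_lt(r$conserve$tests$body$p_value, 0.01)
  expect_lt(r$conserve$tests$flank$p_value, 0.01)
  expect_gt(r$conserve$tests$body$mean_real, r$conserve$tests$body$mean_shuffled)
})
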