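test_that("ORF finding honours ATG starts, minimum length, and nesting", {
  w <- relative_adaptiveness(biased_usage())
  set.seed(11)
  sense_codons <- setdiff(names(w), c("ATG"))
  body <- paste(sample(sense_codons, 48, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")  # 50 codons = 150 nt including the stop
  seq <- paste0("CCCCC", orf, "CCCCC")
  got <- find_orfs(seq, min_len = 150)
  expect_equal(nrow(got), 1L)
  expect_equal(got$length, 150L)
  expect_equal(got$start, 5L)
  expect_false(got$open_ended)
  expect_equal(got$orf_seq, orf)
  # one codon shorter fails the threshold
  expect_equal(nrow(find_orfs(paste0("CCCCC", "ATG", substr(body, 4, nchar(body)), "TAA"),
                              min_len = 150)), 0L)
  # no ATG anywhere: nothing
  expect_equal(nrow(find_orfs(strrep("C", 300), min_len = 150)), 0L)
})

test_that("in-frame internal ATGs do not create nested ORFs", {
  set.seed(12)
  pool <- setdiff(names(relative_adaptiveness(biased_usage())),
                  c("ATG", "TAA", "TAG", "TGA"))
  body1 <- paste(sample(pool, 30, replace = TRUE), collapse = "")
  body2 <- paste(sample(pool, 30, replace = TRUE), collapse = "")
  seq <- paste0("ATG", body1, "ATG", body2, "TAA")
  got <- find_orfs(seq, min_len = 30)
  same_frame <- got[got$frame == 0L, ]
  expect_equal(nrow(same_frame), 1L)  # only the 5'-most ATG is reported
  expect_equal(same_frame$start, 0L)
})

test_that("the search is restricted to the given strand", {
  set.seed(13)
  pool <- setdiff(names(relative_adaptiveness(biased_usage())),
                  c("ATG", "TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(pool, 60, replace = TRUE), collapse = ""), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  fwd <- find_orfs(orf, min_len = 150)
  rev <- find_orfs(rc, min_len = 150)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 0L)
})

test_that("circular mode finds junction-spanning ORFs once", {
  set.seed(14)
  pool <- setdiff(names(relative_adaptiveness(biased_usage())),
                  c("ATG", "TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(pool, 58, replace = TRUE), collapse = ""), "TAA")
  # split the ORF across the junction
  seq <- paste0(substr(orf, 101, nchar(orf)), strrep("C", 30), substr(orf, 1, 100))
  lin <- find_orfs(seq, min_len = 150)
  circ <- find_orfs(seq, min_len = 150, circular_mode = TRUE)
  expect_equal(nrow(lin), 0L)
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$length, 180L)
})

test_that("relative adaptiveness is the within-family ratio to the best codon", {
  wu <- relative_adaptiveness(uniform_usage())
  expect_true(all(abs(wu - 1) < 1e-12))
  u <- uniform_usage()
  # lysine family AAA/AAG set to 30/10
  u["AAA"] <- 30; u["AAG"] <- 10
  w <- relative_adaptiveness(u)
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3)
  expect_equal(unname(w["ATG"]), 1)  # Met is a single-codon family
  expect_equal(unname(w["TGG"]), 1)  # Trp likewise
})

test_that("CAI is the geometric mean of w, excluding stop codons", {
  w <- relative_adaptiveness(biased_usage())
  expect_equal(cai("ATGTGG", w), 1)  # Met + Trp
  # two codons with w = {1, 0.25} give sqrt(0.25)
  u <- uniform_usage(); u["AAA"] <- 40; u["AAG"] <- 10
  w2 <- relative_adaptiveness(u)
  expect_equal(cai("AAAAAG", w2), 0.5)
  # a trailing stop codon does not enter the mean
  expect_equal(cai("AAAAAGTAA", w2), 0.5)
  expect_error(cai("AAAA", w), "divisible")
})

test_that("CAI matches a direct-product oracle to 1e-12 on random ORFs", {
  w <- relative_adaptiveness(biased_usage())
  set.seed(21)
  for (i in 1:250) {
    n <- sample(10:120, 1)
    cod <- sample(names(w), n, replace = TRUE)
    expect_equal(cai(paste(cod, collapse = ""), w), prod(w[cod])^(1 / n),
                 tolerance = 1e-12)
  }
})

test_that("eCAI is exactly 1 under uniform usage and monotone in confidence", {
  wu <- relative_adaptiveness(uniform_usage())
  set.seed(31)
  pool <- replicate(15, random_orf(60, wu))
  e1 <- ecai(pool, wu, n_null = 60, n_runs = 2, seed = 5)
  expect_equal(e1$ecai, 1)
  # with a biased table the null is non-degenerate and quantiles are ordered
  wb <- relative_adaptiveness(biased_usage())
  e95 <- ecai(pool, wb, n_null = 120, n_runs = 1, seed = 5, confidence = 0.95)
  e99 <- ecai(pool, wb, n_null = 120, n_runs = 1, seed = 5, confidence = 0.99)
  expect_gte(e99$ecai, e95$ecai)
  expect_error(ecai(strrep("A", 90), wb), "degenerate")
})

test_that("shuffled controls are length-matched and seed-deterministic", {
  set.seed(41)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")))
  tx <- replicate(5, paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""))
  lens <- c(150, 300, 450)
  c1 <- shuffled_controls(genome, tx, lens, seed = 9)
  expect_equal(nchar(c1$genomic), lens)
  expect_equal(nchar(c1$transcriptomic), lens)
  c2 <- shuffled_controls(genome, tx, lens, seed = 9)
  expect_identical(c1, c2)
  expect_error(shuffled_controls(genome, tx, 10000, seed = 1), "window")
})

test_that("the 2x2 chi-squared statistic matches its closed form", {
  expect_equal(chi2_2x2(50, 50, 50, 50)$statistic, 0)
  expect_equal(chi2_2x2(30, 10, 10, 30)$statistic, 20)
  expect_equal(chi2_2x2(30, 10, 10, 30)$p_value,
               pchisq(20, 1, lower.tail = FALSE))
  # invariant under transposition
  expect_equal(chi2_2x2(12, 34, 5, 6)$statistic, chi2_2x2(12, 5, 34, 6)$statistic)
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("circRNAs with planted codon-biased ORFs are all recovered", {
  b <- default_bundle()
  r <- default_run()
  planted <- b$truth$circs$circ_id[b$truth$circs$orf_planted]
  found <- unique(r$orfcai$circ_orfs$seq_id)
  expect_true(all(planted %in% found))
  # the planted ORF is drawn from optimal codons, so each planted circRNA's
  # best ORF clears the eCAI gate (shorter accidental ORFs need not)
  best <- tapply(r$orfcai$circ_orfs$cai, r$orfcai$circ_orfs$seq_id, max)
  expect_true(all(best[planted] > r$orfcai$ecai))
})

test_that("codon-biased ORF pools separate from uniform controls by chi-squared", {
  wb <- relative_adaptiveness(biased_usage())
  set.seed(51)
  biased_pool <- replicate(250, paste(
    sample(names(wb), 60, replace = TRUE, prob = wb^3), collapse = ""))
  uniform_pool <- replicate(250, random_orf(60, wb))
  thr <- ecai(uniform_pool, wb, n_null = 300, n_runs = 2, seed = 6)$ecai
  a <- sum(vapply(biased_pool, cai, numeric(1), w = wb) > thr)
  c_ <- sum(vapply(uniform_pool, cai, numeric(1), w = wb) > thr)
  test <- chi2_2x2(a, 250 - a, c_, 250 - c_)
  expect_lt(test$p_value, 0.001)
})
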