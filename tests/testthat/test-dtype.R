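test_that("k-mer counting pools reads with overlaps and respects boundaries", {
  kc <- kmer_counts(read_set("ACGT"), 2)
  expect_equal(unname(kc$counts[c("AC", "CG", "GT")]), c(1, 1, 1))
  expect_equal(sum(kc$counts), 3)
  expect_equal(kmer_counts(read_set("AAAA"), 2)$counts[["AA"]], 3)
  # never spanning read boundaries: "AC","CA" yields no "CC"
  expect_equal(kmer_counts(read_set(c("AC", "CA")), 2)$counts[["CC"]], 0)
  expect_equal(kmer_counts(read_set("ACGT"), 4, merge_revcomp = TRUE)$counts[["ACGT"]], 1)
  expect_error(kmer_counts(read_set("ACG"), 5), "k must")
})

test_that("reverse-complement merging adds pair counts onto canonical words", {
  kc <- kmer_counts(read_set("AACC"), 2, merge_revcomp = TRUE)
  # GG's count folds into CC; TT's into AA
  expect_equal(kc$counts[["AA"]], 1)
  expect_equal(kc$counts[["CC"]], 1)
  expect_false("GG" %in% names(kc$counts))
})

test_that("D2 is the inner product and obeys Cauchy-Schwarz", {
  a <- kmer_counts(read_set("ACGT"), 2)
  expect_equal(d2(a, a), 3)               # 1*1 over {AC, CG, GT}
  b <- kmer_counts(read_set("AAAA"), 2)
  expect_equal(d2(a, b), 0)               # disjoint word sets
  expect_equal(d2(a, a), sum(a$counts^2))
  set.seed(8)
  for (i in 1:20) {
    x <- kmer_counts(read_set(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                    collapse = "")), 3)
    y <- kmer_counts(read_set(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                    collapse = "")), 3)
    expect_lte(d2(x, y)^2, d2(x, x) * d2(y, y) + 1e-9)
  }
  expect_error(d2(a, kmer_counts(read_set("ACGT"), 3)), "lengths differ")
})

test_that("centered statistics follow their closed forms", {
  uni <- markov_model(rep(0.25, 4), order = 0)
  # counts exactly at expectation: every 2-mer once in ACGTA...: construct
  # a synthetic count vector at its expectation so every centered term is 0
  a <- kmer_counts(read_set("ACGT"), 2)
  a$counts[] <- a$positions * 0.25^2
  expect_equal(d2star(a, a, uni, uni), 0)
  expect_equal(d2s(a, a, uni, uni), 0)

  # single deviating word with centered value c on both sides: term c/sqrt(2)
  b <- a
  b$counts[] <- b$positions * 0.25^2
  b$counts[["AC"]] <- b$counts[["AC"]] + 2
  expect_equal(d2s(b, b, uni, uni), 2 / sqrt(2))

  # toy pair: direct evaluation of the printed formulas
  r1 <- read_set("ACGT"); r2 <- read_set("ACGG")
  x <- kmer_counts(r1, 2); y <- kmer_counts(r2, 2)
  words <- names(x$counts)
  p <- rep(1 / 16, length(words))
  xt <- x$counts - 3 * p
  yt <- y$counts - 3 * p
  expect_equal(d2star(x, y, uni, uni), sum(xt * yt / sqrt(3 * p * 3 * p)))
  den <- sqrt(xt^2 + yt^2)
  expect_equal(d2s(x, y, uni, uni),
               sum(ifelse(den > 0, xt * yt / den, 0)))
})

test_that("dissimilarities are bounded, symmetric and zero at self", {
  set.seed(9)
  reads <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), character(1))
  r1 <- read_set(reads[1:5], "a"); r2 <- read_set(reads[6:10], "b")
  for (s in c("d2", "d2s", "d2star")) {
    expect_equal(dtype_dissimilarity(r1, r1, s, k = 3), 0)
    v12 <- dtype_dissimilarity(r1, r2, s, k = 3)
    expect_identical(v12, dtype_dissimilarity(r2, r1, s, k = 3))
    expect_gte(v12, 0); expect_lte(v12, 1)
  }
  # disjoint k-mer content without merging: maximal d2 dissimilarity 0.5
  expect_equal(dtype_dissimilarity(read_set("AAAA"), read_set("CCCC"), "d2",
                                   k = 2, merge_revcomp = FALSE), 0.5)
})
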