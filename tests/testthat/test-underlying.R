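test_that("the priority rule orders by length, rarity, first occurrence, word", {
  uni <- markov_model(rep(0.25, 4), order = 0)
  # length dominates
  ip <- irredundant_common_patterns(read_set("AACGTA"), read_set("ACGTAC"),
                                    transforms = "F")
  po <- priority_order(ip, uni)
  expect_equal(nchar(po[1]), max(nchar(ip$words)))
  expect_false(is.unsorted(rev(nchar(po))))

  # equal length: rarer word first under a GC-rich model ("AT" beats "CG"
  # even though "CG" occurs earlier in the concatenation)
  gc <- markov_model(c(1/6, 1/3, 1/3, 1/6), order = 0)
  ip <- irredundant_common_patterns(read_set(c("CG", "AT")),
                                    read_set(c("CG", "AT")),
                                    transforms = "F")
  two <- priority_order(ip, gc)
  two <- two[nchar(two) == 2]
  expect_equal(two, c("AT", "CG"))
  # under the uniform model the pair is tied in probability and falls back
  # to the first occurrence, which favors "CG"
  two <- priority_order(ip, uni)
  two <- two[nchar(two) == 2]
  expect_equal(two, c("CG", "AT"))
})

test_that("greedy extraction on the spec'd toy instance keeps the long pattern", {
  uni <- markov_model(rep(0.25, 4), order = 0)
  r1 <- read_set("ACGTT"); r2 <- read_set(c("ACGAA", "CGTTC"))
  ip <- irredundant_common_patterns(r1, r2, transforms = "F")
  u <- extract_underlying(ip, uni)
  expect_true("CGTT" %in% u$patterns$word)
  expect_false("ACG" %in% u$patterns$word)  # its only R1 occurrence is tied
  # matches the literal Definition-2 oracle
  or <- oracle_underlying(r1, r2, uni, "F")
  expect_equal(sort(u$patterns$word), sort(or$patterns$word))
})

test_that("a read compared against itself yields the read as sole underlying pattern", {
  uni <- markov_model(rep(0.25, 4), order = 0)
  ip <- irredundant_common_patterns(read_set("ACGT", "a"),
                                    read_set("ACGT", "b"), transforms = "F")
  u <- extract_underlying(ip, uni)
  expect_equal(u$patterns$word, "ACGT")
  expect_equal(u$patterns$untied1, 1L)
  expect_equal(u$patterns$untied2, 1L)
})

test_that("extraction matches the literal oracle and the compiled engine", {
  set.seed(202)
  for (rep in 1:25) {
    inst <- random_instance()
    m <- fit_markov(inst$r1, order = 1, pseudocount = 1)
    for (tr in list("F", c("F", "R", "C", "RC"))) {
      ip <- irredundant_common_patterns(inst$r1, inst$r2, tr)
      if (!length(ip$words)) next
      u <- extract_underlying(ip, m)
      or <- oracle_underlying(inst$r1, inst$r2, m, tr)
      expect_equal(u$patterns[order(u$patterns$word),
                              c("word", "untied1", "untied2", "occ1", "occ2")],
                   or$patterns[order(or$patterns$word),
                               c("word", "untied1", "untied2", "occ1", "occ2")],
                   ignore_attr = TRUE)
      # fast one-shot engine agrees with the R-level greedy pass
      pd <- under2:::.pattern_docs(inst$r1, inst$r2, tr)
      eng <- under2:::underlying_cpp(pd$docs, pd$table$set, m$initial,
                                     m$transition, TRUE)
      o <- order(eng$word)
      expect_equal(eng$word[o], sort(u$patterns$word))
      expect_equal(eng$untied1[o],
                   u$patterns$untied1[order(u$patterns$word)])
      expect_equal(eng$untied2[o],
                   u$patterns$untied2[order(u$patterns$word)])
    }
  }
})

test_that("claimed untied occurrences are pairwise disjoint", {
  set.seed(303)
  for (rep in 1:20) {
    inst <- random_instance()
    m <- fit_markov(inst$r1)
    ip <- irredundant_common_patterns(inst$r1, inst$r2, "F")
    if (!length(ip$words)) next
    u <- extract_underlying(ip, m)
    if (!nrow(u$untied)) next
    by_doc <- split(u$untied, u$untied$doc)
    for (oc in by_doc) {
      cells <- unlist(mapply(function(o, l) o:(o + l - 1L),
                             oc$offset, oc$length, SIMPLIFY = FALSE))
      expect_false(anyDuplicated(cells) > 0)
    }
  }
})

test_that("no rejected pattern could still be added (Definition-2 maximality audit)", {
  set.seed(404)
  for (rep in 1:20) {
    inst <- random_instance()
    m <- fit_markov(inst$r1)
    or <- oracle_underlying(inst$r1, inst$r2, m, "F")
    if (is.null(or$patterns)) next
    ir <- or$ir
    rejected <- setdiff(ir$words, or$patterns$word)
    for (w in rejected) {
      oc <- ir$occurrences[ir$occurrences$word == w, ]
      free_sets <- unique(oc$set[vapply(seq_len(nrow(oc)), function(r) {
        cells <- (oc$offset[r] + 1L):(oc$offset[r] + nchar(w))
        !any(or$gamma[[oc$doc[r]]][cells])
      }, logical(1))])
      expect_lt(length(free_sets), 2L)
    }
  }
})
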