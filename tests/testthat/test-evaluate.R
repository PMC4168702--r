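# Brute-force Robinson-Foulds oracle: enumerate non-trivial bipartitions of
# an unrooted tree by collecting, for every internal edge, the tip set on the
# child side, canonicalized as the lexicographically smaller side.
biparts <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  internal <- tree$edge[tree$edge[, 2] > ntip, 2]
  out <- character(0)
  for (v in internal) {
    side <- sort(tips_below(v))
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

rf_oracle <- function(t1, t2) {
  b1 <- biparts(t1); b2 <- biparts(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

test_that("PPV separates, collapses and shares ties as defined", {
  expect_equal(ppv(c(0.1, 0.2), c(0.3, 0.4)), 1)          # perfect separation
  expect_equal(ppv(rep(1, 10), rep(1, 10)), 0.5)          # all tied: no power
  expect_equal(ppv(c(5, 6), c(1, 2), orientation = "similarity"), 1)
  expect_equal(ppv(c(0.3, 0.4), c(0.1, 0.2)), 0)
  # tie group straddling the cut contributes proportionally: sorted values
  # 0.1(P) | 0.5,0.5,0.5 (P,P,N) | 0.9(N), cut = 2, so the tie group fills
  # one cut slot with share 2/3 positive -> PPV = (1 + 2/3) / 2
  expect_equal(ppv(c(0.1, 0.5, 0.5), c(0.5, 0.9)), (1 + 2 / 3) / 2)
  expect_error(ppv(numeric(0), 1), "non-empty")
})

test_that("PPV is invariant under strictly monotone transforms of the scores", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(15); n <- runif(15) + 0.2
    v1 <- ppv(p, n)
    expect_gte(v1, 0); expect_lte(v1, 1)
    expect_equal(ppv(exp(3 * p), exp(3 * n)), v1)
    expect_equal(ppv(-1 / (1 + p), -1 / (1 + n)), v1)
  }
})

test_that("pairwise matrices are symmetric with zero diagonal and recomputable", {
  set.seed(42)
  g <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  cfg <- simulation_config(N = 600, gamma = 2, beta = 60)
  sets <- list(sample_reads(g, cfg, "a"), sample_reads(g, cfg, "b"),
               sample_reads(g, cfg, "c"))
  m <- pairwise_matrix(sets, "under2")
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m["a", "b"], under2(sets[[1]], sets[[2]])$under2)

  dup <- pairwise_matrix(list(sets[[1]],
                              read_set(sets[[1]]$reads, "copy"),
                              sets[[2]]), "under2")
  expect_equal(dup["a", "copy"], 0)

  md <- pairwise_matrix(sets, "d2", k = 3)
  expect_equal(md["a", "c"], dtype_dissimilarity(sets[[1]], sets[[3]], "d2", k = 3))
})

test_that("NJ inverts additive matrices and UPGMA inverts ultrametric ones", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  m <- ape::cophenetic.phylo(tr)
  m <- m[order(rownames(m)), order(colnames(m))]
  nj_t <- nj_tree(m)
  expect_equal(rf_oracle(nj_t, tr), 0)
  expect_equal(robinson_foulds(nj_t, tr), 0L)
  # branch lengths recovered: cophenetic distances match within 1e-9
  cm <- ape::cophenetic.phylo(nj_t)[rownames(m), colnames(m)]
  expect_equal(cm, m, tolerance = 1e-9)

  ultra <- ape::read.tree(
    text = "(((a:1,b:1):2,(c:2,d:2):1):1,(e:2.5,f:2.5):1.5);")
  um <- ape::cophenetic.phylo(ultra)
  up <- upgma_tree(um)
  expect_equal(ape::cophenetic.phylo(up)[rownames(um), colnames(um)], um,
               tolerance = 1e-9)
  expect_equal(robinson_foulds(up, ultra), 0L)

  bad <- um; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
})

test_that("Robinson-Foulds matches brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t1), 0L)
  expect_equal(robinson_foulds(t1, t2), 2L)   # 2n - 6 for n = 4

  set.seed(43)
  for (i in 1:20) {
    x <- ape::rtree(8); y <- ape::rtree(8)
    expect_equal(robinson_foulds(x, y), rf_oracle(x, y))
    expect_equal(robinson_foulds(x, y), robinson_foulds(y, x))
    expect_lte(robinson_foulds(x, y), 2 * 8 - 6)
  }
  y <- ape::rtree(8)
  y$tip.label[1] <- "zzz"
  expect_error(robinson_foulds(ape::rtree(8), y), "leaf")
})
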