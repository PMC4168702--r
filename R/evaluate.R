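#' Positive predictive value of a score separation
#'
#' Merges the within-positive-set and within-negative-set pair scores,
#' orients them so that "better" means more similar, and reports the
#' fraction of the top half (best \eqn{\lfloor n/2 \rfloor} entries) that
#' are positive pairs.  A PPV of 1 means perfect separation of positive
#' from negative pairs; 0.5 means no statistical power.  Tied values
#' straddling the cut contribute proportionally (midrank sharing), so the
#' result does not depend on an arbitrary ordering of ties.
#'
#' @param positive_scores,negative_scores Numeric vectors of within-set
#'   pair scores.
#' @param orientation \code{"dissimilarity"} (smaller is more similar, the
#'   default — Under2 and the bounded d-type transforms) or
#'   \code{"similarity"}.
#' @return PPV in \eqn{[0, 1]}.
#' @export
#' @examples
#' ppv(c(0.1, 0.2), c(0.3, 0.4))   # 1: positives perfectly separated
ppv <- function(positive_scores, negative_scores,
                orientation = c("dissimilarity", "similarity")) {
  orientation <- match.arg(orientation)
  if (!length(positive_scores) || !length(negative_scores))
    stop("both score lists must be non-empty")
  x <- c(positive_scores, negative_scores)
  if (any(!is.finite(x))) {
    # infinite dissimilarities (no shared signal) rank worst
    worst <- if (orientation == "dissimilarity") Inf else -Inf
    x[!is.finite(x)] <- worst
  }
  if (orientation == "similarity") x <- -x
  pos <- c(rep(TRUE, length(positive_scores)),
           rep(FALSE, length(negative_scores)))
  n <- length(x)
  cut <- n %/% 2L
  o <- order(x)
  x <- x[o]; pos <- pos[o]
  share <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    in_cut <- max(0L, min(j, cut) - i + 1L)
    if (in_cut > 0L)
      share <- share + sum(pos[i:j]) * in_cut / (j - i + 1L)
    i <- j + 1L
  }
  share / cut
}

# All within-list pairwise scores for one statistic.
.pair_scores <- function(readsets, stat, k = 5L, transforms = c("F", "R", "C", "RC")) {
  n <- length(readsets)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out <- c(out, .dissimilarity_of(readsets[[i]], readsets[[j]], stat, k,
                                    transforms))
  }
  out
}

.dissimilarity_of <- function(a, b, stat, k, transforms) {
  if (stat == "under2") {
    under2(a, b, transforms = transforms)$under2
  } else {
    dtype_dissimilarity(a, b, stat = stat, k = k)
  }
}

#' PPV benchmark of statistics on a simulated experiment
#'
#' Scores all within-positive and within-negative read-set pairs with each
#' requested statistic and computes the PPV of the merged ranking.  All
#' statistics are used in their dissimilarity orientation.
#'
#' @param experiment Result of [build_experiment()].
#' @param stats Character vector among \code{"under2"}, \code{"d2"},
#'   \code{"d2s"}, \code{"d2star"}.
#' @param k Word length for the d-type statistics (default 5).
#' @param transforms Transform strings searched by Under2.
#' @return Named numeric vector of PPVs.
#' @export
benchmark_ppv <- function(experiment, stats = c("under2", "d2", "d2s", "d2star"),
                          k = 5L, transforms = c("F", "R", "C", "RC")) {
  stats <- match.arg(stats, several.ok = TRUE)
  vapply(stats, function(s) {
    ps <- .pair_scores(experiment$positives, s, k, transforms)
    ns <- .pair_scores(experiment$negatives, s, k, transforms)
    ppv(ps, ns, orientation = "dissimilarity")
  }, numeric(1))
}

#' Pairwise dissimilarity matrix of read sets
#'
#' @param readsets List of two or more [read_set()] objects with unique
#'   labels.
#' @param stat One of \code{"under2"}, \code{"d2"}, \code{"d2s"},
#'   \code{"d2star"}.
#' @param k Word length for the d-type statistics.
#' @param transforms Transform strings searched by Under2.
#' @return Labelled symmetric numeric matrix with zero diagonal.
#' @export
pairwise_matrix <- function(readsets, stat = c("under2", "d2", "d2s", "d2star"),
                            k = 5L, transforms = c("F", "R", "C", "RC")) {
  stat <- match.arg(stat)
  n <- length(readsets)
  if (n < 2L) stop("need at least 2 read sets")
  labels <- vapply(readsets, function(r) r$label, character(1))
  if (anyDuplicated(labels)) stop("read-set labels must be unique")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- .dissimilarity_of(readsets[[i]], readsets[[j]], stat, k, transforms)
    m[i, j] <- v
    m[j, i] <- v
  }
  m
}

#' Distance-based tree reconstruction
#'
#' [nj_tree()] runs Saitou–Nei neighbor joining (unrooted);
#' [upgma_tree()] runs average-linkage agglomeration (rooted,
#' ultrametric).  Both delegate to the standard implementations
#' (\pkg{ape}, \code{stats::hclust}).
#'
#' @param m Labelled symmetric dissimilarity matrix (zero diagonal).
#' @return An \code{ape::phylo} tree.
#' @export
nj_tree <- function(m) {
  .check_dist_matrix(m)
  if (nrow(m) < 3L) stop("neighbor joining needs n >= 3")
  ape::nj(m)
}

#' @rdname nj_tree
#' @export
upgma_tree <- function(m) {
  .check_dist_matrix(m)
  if (nrow(m) < 3L) stop("UPGMA needs n >= 3")
  ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
}

#' Robinson–Foulds distance between two trees
#'
#' The size of the symmetric difference of the non-trivial bipartition
#' sets of the two trees on the same leaves.  Rooted trees are unrooted
#' before comparison.  The distance is 0 iff the trees are isomorphic and
#' at most \eqn{2n - 6} for two unrooted binary trees on \eqn{n} leaves.
#'
#' @param t1,t2 \code{ape::phylo} trees with identical leaf label sets,
#'   \eqn{n \ge 3}.
#' @return Integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf label sets")
  if (length(t1$tip.label) < 3L) stop("Robinson-Foulds needs n >= 3 leaves")
  unroot_ <- function(t) if (ape::is.rooted(t)) ape::unroot(t) else t
  as.integer(phangorn::RF.dist(unroot_(t1), unroot_(t2), check.labels = TRUE))
}
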