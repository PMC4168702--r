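#' k-mer occurrence counts of a read set
#'
#' Counts overlapping occurrences of all words of length \code{k}, pooled
#' over reads and never spanning read boundaries.  Windows containing
#' \code{N} are skipped.  With \code{merge_revcomp} each word's count is
#' added to its reverse-complement canonical form (the lexicographically
#' smaller of the pair), which accounts for the two strands of the genome
#' the reads were sampled from.
#'
#' @param rs A [read_set()].
#' @param k Word length, \code{1 <= k <= min(read length)} and \code{k <= 12}.
#' @param merge_revcomp Merge reverse-complement word pairs (default FALSE).
#' @return Object of class \code{kmer_counts}: list with \code{k},
#'   \code{counts} (named vector over the word universe), \code{positions}
#'   (total word start positions, \eqn{\sum_r (len_r - k + 1)}) and
#'   \code{merged}.
#' @export
#' @examples
#' kmer_counts(read_set("ACGT"), 2)$counts[c("AC", "CG", "GT")]
kmer_counts <- function(rs, k, merge_revcomp = FALSE) {
  stopifnot(inherits(rs, "read_set"))
  k <- as.integer(k)
  if (k < 1L || k > min(nchar(rs$reads)))
    stop("k must satisfy 1 <= k <= min read length")
  if (k > 12L) stop("k > 12 is not supported")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(rs$reads), width = k, simplify.as = "collapsed")
  positions <- sum(pmax(0L, nchar(rs$reads) - k + 1L))
  if (merge_revcomp) {
    words <- names(counts)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words)))
    canonical <- ifelse(words <= rc, words, rc)
    counts <- vapply(split(counts, canonical), sum, numeric(1))
  }
  structure(list(k = k, counts = counts, positions = positions,
                 merged = merge_revcomp),
            class = "kmer_counts")
}

.check_pair <- function(a, b) {
  stopifnot(inherits(a, "kmer_counts"), inherits(b, "kmer_counts"))
  if (a$k != b$k) stop("word lengths differ: ", a$k, " vs ", b$k)
  if (!identical(a$merged, b$merged))
    stop("count vectors differ in reverse-complement merging")
  if (!identical(names(a$counts), names(b$counts)))
    stop("count vectors are over different word universes")
  invisible(NULL)
}

#' D2 statistic: inner product of k-mer count vectors
#'
#' @param a,b [kmer_counts()] objects with equal \code{k}.
#' @return \eqn{\sum_w A_w B_w}.
#' @export
d2 <- function(a, b) {
  .check_pair(a, b)
  sum(a$counts * b$counts)
}

# Null probability of each word of a count vector's universe; with merged
# reverse-complement universes the probability of a canonical word is the
# sum over the word and its (distinct) reverse complement.
.null_probs <- function(m, kc) {
  words <- names(kc$counts)
  p <- word_probability(m, words)
  if (kc$merged) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words)))
    pal <- rc == words
    p[!pal] <- p[!pal] + word_probability(m, rc[!pal])
  }
  p
}

#' Centered D2 statistics (D2* and D2S)
#'
#' Both statistics center the counts at their null expectation,
#' \eqn{\tilde A_w = A_w - m_A p_w} with \eqn{m_A} the number of word start
#' positions, and standardize the inner product:
#' \eqn{D2^* = \sum_w \tilde A_w \tilde B_w / \sqrt{m_A p^A_w \, m_B p^B_w}}
#' and
#' \eqn{D2S = \sum_w \tilde A_w \tilde B_w / \sqrt{\tilde A_w^2 + \tilde B_w^2}}
#' (terms with \eqn{\tilde A_w = \tilde B_w = 0} contribute 0).
#'
#' @param a,b [kmer_counts()] objects with equal \code{k}.
#' @param null_a,null_b [markov_model()] null models for each set.
#' @return The statistic value.
#' @export
d2star <- function(a, b, null_a, null_b) {
  .check_pair(a, b)
  pa <- .null_probs(null_a, a)
  pb <- .null_probs(null_b, b)
  at <- a$counts - a$positions * pa
  bt <- b$counts - b$positions * pb
  sum(at * bt / sqrt(a$positions * pa * b$positions * pb))
}

#' @rdname d2star
#' @export
d2s <- function(a, b, null_a, null_b) {
  .check_pair(a, b)
  at <- a$counts - a$positions * .null_probs(null_a, a)
  bt <- b$counts - b$positions * .null_probs(null_b, b)
  den <- sqrt(at^2 + bt^2)
  terms <- ifelse(den > 0, at * bt / den, 0)
  sum(terms)
}

#' Bounded k-mer dissimilarity between two read sets
#'
#' Computes the requested D2-family statistic on pooled k-mer counts
#' (reverse-complement merging on by default, to account for double
#' strands; null models fitted order-0 on each set) and converts it to a
#' dissimilarity in \eqn{[0, 1]}: \eqn{d = \frac12 (1 - S / \nu)} where
#' \eqn{\nu} is the geometric mean of the self-inner-products for d2 and the
#' analogous self-normalizer for the centered statistics, so that identical
#' inputs give 0.
#'
#' @param r1,r2 [read_set()] objects.
#' @param stat One of \code{"d2"}, \code{"d2s"}, \code{"d2star"}.
#' @param k Word length (default 5).
#' @param merge_revcomp Merge reverse-complement pairs (default TRUE).
#' @param markov_order Order of the null models for the centered statistics
#'   (default 0).
#' @param pseudocount Smoothing for the null fit.
#' @return Dissimilarity in \eqn{[0, 1]}.
#' @export
dtype_dissimilarity <- function(r1, r2, stat = c("d2", "d2s", "d2star"),
                                k = 5L, merge_revcomp = TRUE,
                                markov_order = 0L, pseudocount = 1) {
  stat <- match.arg(stat)
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  a <- kmer_counts(r1, k, merge_revcomp)
  b <- kmer_counts(r2, k, merge_revcomp)
  if (sum(a$counts) == 0 || sum(b$counts) == 0)
    stop("degenerate all-zero k-mer count vector")
  if (stat == "d2") {
    s <- d2(a, b)
    nu <- sqrt(d2(a, a) * d2(b, b))
    if (nu == 0) stop("degenerate all-zero k-mer count vector")
    return(0.5 * (1 - s / nu))
  }
  na <- fit_markov(r1, order = markov_order, pseudocount = pseudocount)
  nb <- fit_markov(r2, order = markov_order, pseudocount = pseudocount)
  pa <- .null_probs(na, a)
  pb <- .null_probs(nb, b)
  at <- a$counts - a$positions * pa
  bt <- b$counts - b$positions * pb
  if (stat == "d2star") {
    s <- sum(at * bt / sqrt(a$positions * pa * b$positions * pb))
    nu <- sqrt(sum(at^2 / (a$positions * pa)) * sum(bt^2 / (b$positions * pb)))
  } else {
    den <- sqrt(at^2 + bt^2)
    s <- sum(ifelse(den > 0, at * bt / den, 0))
    nu <- sqrt(sum(ifelse(den > 0, at^2 / den, 0)) *
               sum(ifelse(den > 0, bt^2 / den, 0)))
  }
  if (nu == 0) stop("degenerate centered count vectors")
  0.5 * (1 - s / nu)
}
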