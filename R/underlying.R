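# Pattern priority and greedy underlying-pattern selection (location-vector
# algorithm).  The compiled engine used by under2() implements the same
# procedure; this R implementation works from an explicit irredundant set and
# doubles as a readable reference path.

# Global 0-based position of each occurrence in the canonical concatenation
# order (set 1 blocks F,R,C,RC then set 2), used by the priority rule.
.global_positions <- function(ip) {
  gstart <- cumsum(c(0L, ip$doc_lengths))[seq_along(ip$doc_lengths)]
  gstart[ip$occurrences$doc] + ip$occurrences$offset
}

#' Rank irredundant patterns by the pattern priority rule
#'
#' Priority orders patterns for greedy selection: longer patterns first;
#' among equal lengths, the pattern less likely to appear under the null
#' model (smaller \eqn{p_w}) first; then the pattern whose first occurrence
#' appears earlier in the canonical concatenation of the reads; finally the
#' lexicographically smaller word (a tie-break that makes the order strict).
#'
#' @param ip An [irredundant_common_patterns()] result.
#' @param m A [markov_model()] supplying the word probabilities.
#' @return The pattern words, ordered by decreasing priority.  The
#'   permutation of pattern indices is attached as attribute \code{"order"}.
#' @export
priority_order <- function(ip, m) {
  stopifnot(inherits(ip, "irredundant_patterns"), inherits(m, "markov_model"))
  if (!length(ip$words)) return(character(0))
  lpw <- .word_logprob(m, ip$words)
  gpos <- .global_positions(ip)
  first <- vapply(split(gpos, ip$occurrences$pattern), min, numeric(1))
  first <- first[as.character(seq_along(ip$words))]
  ord <- order(-ip$length, lpw, first, ip$words)
  structure(ip$words[ord], order = ord)
}

#' Extract the underlying patterns by the greedy location-vector pass
#'
#' Walks the irredundant patterns in priority order over a location vector
#' spanning every position of both read sets (including enabled transform
#' strings).  An occurrence is *untied* when none of its cells is already
#' claimed; claims are made progressively in position order, so accepted
#' claims are pairwise disjoint even between overlapping occurrences of the
#' same word.  A pattern is accepted when it retains at least one untied
#' occurrence in each read set, in which case all its untied occurrences
#' claim their cells; rejected patterns claim nothing.
#'
#' @param ip An [irredundant_common_patterns()] result.
#' @param m A [markov_model()] supplying the priority probabilities.
#' @return An object of class \code{underlying_patterns}: a list with
#'   \code{patterns} (data frame with \code{word}, \code{length},
#'   \code{untied1}, \code{untied2}, \code{occ1}, \code{occ2}, \code{pw})
#'   and \code{untied} (data frame of the claimed occurrences).
#' @export
extract_underlying <- function(ip, m) {
  stopifnot(inherits(ip, "irredundant_patterns"), inherits(m, "markov_model"))
  if (!length(ip$words)) stop("the irredundant set is empty")
  ord <- attr(priority_order(ip, m), "order")
  pw <- word_probability(m, ip$words)
  gamma <- lapply(ip$doc_lengths, function(L) rep(FALSE, L))
  occ_by_pat <- split(seq_len(nrow(ip$occurrences)), ip$occurrences$pattern)
  acc <- list()
  untied_rows <- integer(0)
  for (idx in ord) {
    rows <- occ_by_pat[[as.character(idx)]]
    oc <- ip$occurrences[rows, , drop = FALSE]
    o <- order(oc$doc, oc$offset)
    rows <- rows[o]; oc <- oc[o, , drop = FALSE]
    k <- ip$length[idx]
    claimed <- integer(0)
    u1 <- 0L; u2 <- 0L
    for (r in seq_len(nrow(oc))) {
      d <- oc$doc[r]
      cells <- (oc$offset[r] + 1L):(oc$offset[r] + k)
      if (any(gamma[[d]][cells])) next
      gamma[[d]][cells] <- TRUE
      claimed <- c(claimed, r)
      if (oc$set[r] == 1L) u1 <- u1 + 1L else u2 <- u2 + 1L
    }
    if (u1 >= 1L && u2 >= 1L) {
      acc[[length(acc) + 1L]] <- data.frame(
        word = ip$words[idx], length = k, untied1 = u1, untied2 = u2,
        occ1 = ip$occ1[idx], occ2 = ip$occ2[idx], pw = pw[idx],
        stringsAsFactors = FALSE)
      untied_rows <- c(untied_rows, rows[claimed])
    } else {
      for (r in claimed) {
        d <- oc$doc[r]
        gamma[[d]][(oc$offset[r] + 1L):(oc$offset[r] + k)] <- FALSE
      }
    }
  }
  patterns <- if (length(acc)) do.call(rbind, acc) else
    data.frame(word = character(0), length = integer(0), untied1 = integer(0),
               untied2 = integer(0), occ1 = integer(0), occ2 = integer(0),
               pw = numeric(0), stringsAsFactors = FALSE)
  untied <- ip$occurrences[sort(untied_rows),
                           c("word", "set", "read", "transform", "doc",
                             "offset", "length")]
  rownames(untied) <- NULL
  structure(list(patterns = patterns, untied = untied,
                 transforms = ip$transforms, labels = ip$labels),
            class = "underlying_patterns")
}

#' @export
print.underlying_patterns <- function(x, ...) {
  cat("underlying_patterns: ", nrow(x$patterns), " patterns between '",
      x$labels[1], "' and '", x$labels[2], "'\n", sep = "")
  invisible(x)
}
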