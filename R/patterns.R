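#' Brute-force enumeration of common patterns between two read sets
#'
#' Test oracle: enumerates every substring of every (transformed) read of
#' one set that also occurs somewhere in the other set, deduplicated by
#' word, with complete occurrence lists.  A word is *common* when it occurs
#' at least once in each read set (possibly on a transform string when
#' transforms are enabled).  Substrings containing \code{N} never match.
#'
#' Intended for small instances only; the scale guard directs larger inputs
#' to the indexed path of [irredundant_common_patterns()].
#'
#' @param r1,r2 [read_set()] objects.
#' @param transforms Subset of \code{c("F", "R", "C", "RC")}.
#' @return A list with \code{words} (sorted character vector) and
#'   \code{occurrences}, a data frame with columns \code{word}, \code{set},
#'   \code{read}, \code{transform}, \code{offset} (0-based), \code{length}.
#' @export
common_patterns_bruteforce <- function(r1, r2, transforms = c("F", "R", "C", "RC")) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  pd <- .pattern_docs(r1, r2, transforms)
  if (sum(nchar(pd$docs)) > 2000L)
    stop("inputs exceed the brute-force scale guard (2000 symbols); ",
         "use irredundant_common_patterns()")
  subs <- lapply(seq_along(pd$docs), function(d) {
    doc <- pd$docs[d]
    L <- nchar(doc)
    starts <- rep(seq_len(L), times = L:1)
    lens <- unlist(lapply(seq_len(L), function(s) seq_len(L - s + 1L)))
    words <- substring(doc, starts, starts + lens - 1L)
    keep <- !grepl("N", words, fixed = TRUE)
    data.frame(word = words[keep], doc = d, offset = starts[keep] - 1L,
               length = lens[keep], stringsAsFactors = FALSE)
  })
  subs <- do.call(rbind, subs)
  subs$set <- pd$table$set[subs$doc]
  shared <- intersect(unique(subs$word[subs$set == 1L]),
                      unique(subs$word[subs$set == 2L]))
  occ <- subs[subs$word %in% shared, , drop = FALSE]
  occ$read <- pd$table$read[occ$doc]
  occ$transform <- pd$table$transform[occ$doc]
  occ <- occ[order(occ$word, occ$doc, occ$offset),
             c("word", "set", "read", "transform", "offset", "length")]
  rownames(occ) <- NULL
  list(words = sort(shared), occurrences = occ)
}

#' Irredundant common patterns of two read sets
#'
#' A common pattern is *irredundant* when at least one of its occurrences
#' (in either set, on any enabled transform string) is not completely
#' contained, on the same read and transform, inside an occurrence of a
#' longer common pattern.  Extraction runs on a generalized suffix array
#' with LCP support over all reads of both sets (transform strings appended
#' as further documents), so it scales far beyond the brute-force oracle.
#'
#' The number of irredundant common patterns is bounded by
#' \eqn{|R_1| + |R_2|}, the summed sequence lengths.
#'
#' @param r1,r2 [read_set()] objects.
#' @param transforms Subset of \code{c("F", "R", "C", "RC")}; the default
#'   enables all four.
#' @return An object of class \code{irredundant_patterns}: a list with
#'   \code{words}, \code{length}, \code{occ1}, \code{occ2} (total occurrence
#'   counts per set over the enabled transforms), and \code{occurrences}
#'   (data frame with \code{pattern}, \code{word}, \code{set}, \code{read},
#'   \code{transform}, \code{offset}, \code{length}).
#' @export
#' @examples
#' r1 <- read_set("ACGT", "a"); r2 <- read_set("ACGT", "b")
#' irredundant_common_patterns(r1, r2, transforms = "F")$words   # "ACGT"
irredundant_common_patterns <- function(r1, r2,
                                        transforms = c("F", "R", "C", "RC")) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  if (length(r1$reads) < 1L || length(r2$reads) < 1L)
    stop("both read sets must be non-empty")
  pd <- .pattern_docs(r1, r2, transforms)
  res <- irredundant_cpp(pd$docs, pd$table$set)
  occ <- data.frame(
    pattern = res$occ_pattern,
    word = res$word[res$occ_pattern],
    set = res$occ_set,
    read = pd$table$read[res$occ_doc],
    transform = pd$table$transform[res$occ_doc],
    doc = res$occ_doc,
    offset = res$occ_offset,
    length = res$length[res$occ_pattern],
    stringsAsFactors = FALSE)
  structure(list(words = as.character(res$word),
                 length = as.integer(res$length),
                 occ1 = as.integer(res$occ1),
                 occ2 = as.integer(res$occ2),
                 occurrences = occ,
                 doc_table = pd$table,
                 doc_lengths = nchar(pd$docs),
                 transforms = pd$transforms,
                 labels = c(r1$label, r2$label)),
            class = "irredundant_patterns")
}

#' @export
print.irredundant_patterns <- function(x, ...) {
  cat("irredundant_patterns: ", length(x$words), " patterns between '",
      x$labels[1], "' and '", x$labels[2], "' (transforms ",
      paste(x$transforms, collapse = ","), ")\n", sep = "")
  invisible(x)
}
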