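#' Construct a read set
#'
#' A read set is a labelled collection of reads over \code{A, C, G, T}
#' (positions holding \code{N} are allowed but never match any pattern).
#' It is the unit of comparison for every statistic in the package.
#'
#' @param reads Character vector of reads (length >= 1, each non-empty).
#'   Case-insensitive; normalized to upper case.
#' @param label Text label for the set.
#' @param beta Nominal read length.  Defaults to the common read length when
#'   all reads have equal length, otherwise the rounded mean length.
#' @return An object of class \code{read_set} with fields \code{reads},
#'   \code{label}, \code{beta}.
#' @export
#' @examples
#' rs <- read_set(c("ACGTT", "TTGCA"), label = "toy")
#' total_length(rs)
read_set <- function(reads, label = "readset", beta = NULL) {
  if (!is.character(reads) || length(reads) < 1L)
    stop("reads must be a non-empty character vector")
  reads <- toupper(reads)
  if (any(nchar(reads) < 1L)) stop("every read must be non-empty")
  if (any(grepl("[^ACGTN]", reads)))
    stop("reads contain symbols outside {A,C,G,T,N}")
  lens <- nchar(reads)
  if (is.null(beta)) {
    beta <- if (length(unique(lens)) == 1L) lens[1] else as.integer(round(mean(lens)))
  }
  out <- structure(list(reads = unname(reads), label = as.character(label),
                        beta = as.integer(beta)),
                   class = "read_set")
  # per-set memo for transform strings and fitted background models; an
  # environment so the cache survives copies (read sets are immutable)
  attr(out, "cache") <- new.env(parent = emptyenv())
  out
}

.rs_cache <- function(rs, key, compute) {
  env <- attr(rs, "cache")
  if (is.null(env)) return(compute())
  if (is.null(env[[key]])) env[[key]] <- compute()
  env[[key]]
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set '", x$label, "': ", length(x$reads), " reads, total ",
      total_length(x), " bp (beta = ", x$beta, ")\n", sep = "")
  invisible(x)
}

#' Total forward length of a read set
#'
#' The summed length of the reads (the quantity \eqn{|R| = M \beta} when all
#' reads have the nominal length), used as the normalizing length in the
#' Under2 score and its logarithmic terms.
#'
#' @param rs A [read_set()].
#' @return Integer total length.
#' @export
total_length <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  sum(nchar(rs$reads))
}

.TRANSFORMS <- c("F", "R", "C", "RC")

.revcomp1 <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Sequence transforms of a read
#'
#' Returns the forward read together with its reverse, complement, and
#' reverse-complement.  These transforms let pattern occurrences account for
#' the double-stranded nature of DNA and for inverted segments.
#'
#' @param read A single read over \code{A, C, G, T}.
#' @return Named character vector with entries \code{F}, \code{R}, \code{C},
#'   \code{RC}, all of the same length as \code{read}.
#' @export
#' @examples
#' transforms_of("AC")   # F "AC", R "CA", C "TG", RC "GT"
transforms_of <- function(read) {
  if (!is.character(read) || length(read) != 1L) stop("read must be a single string")
  read <- toupper(read)
  if (grepl("[^ACGT]", read)) stop("read contains symbols outside {A,C,G,T}")
  comp <- chartr("ACGT", "TGCA", read)
  rev_ <- paste(rev(strsplit(read, "", fixed = TRUE)[[1]]), collapse = "")
  c(F = read,
    R = rev_,
    C = comp,
    RC = paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Vectorized transform strings for all reads of a set (N allowed; kept as N).
.transform_strings <- function(reads, transform) {
  switch(transform,
    F = reads,
    C = chartr("ACGTN", "TGCAN", reads),
    R = as.character(Biostrings::reverse(Biostrings::DNAStringSet(reads))),
    RC = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads))),
    stop("unknown transform: ", transform))
}

.check_transforms <- function(transforms) {
  transforms <- unique(match.arg(transforms, .TRANSFORMS, several.ok = TRUE))
  if (length(transforms) < 1L) stop("at least one transform required")
  transforms
}

# Documents (one string per read x transform) for one or two read sets, in
# the package's canonical concatenation order: set 1 F-block (reads in
# order), then R, C, RC blocks, then the same for set 2.  Global positions
# used for pattern priority follow this order.
.pattern_docs <- function(r1, r2 = NULL, transforms = .TRANSFORMS) {
  transforms <- .check_transforms(transforms)
  sets <- if (is.null(r2)) list(r1) else list(r1, r2)
  docs <- character(0)
  tab <- list()
  for (s in seq_along(sets)) {
    rs <- sets[[s]]
    reads <- rs$reads
    for (tr in transforms) {
      docs <- c(docs, .rs_cache(rs, paste0("transform_", tr), function()
        .transform_strings(reads, tr)))
      tab[[length(tab) + 1L]] <- data.frame(
        set = s, transform = tr, read = seq_along(reads),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tab)
  tab$doc <- seq_len(nrow(tab))
  list(docs = docs, table = tab, transforms = transforms)
}

#' Enumerate occurrences of a word in a read set
#'
#' Reports every (possibly overlapping) exact match of \code{word} in each
#' requested transform string of each read.  Offsets are 0-based and
#' half-open: an occurrence at offset \code{l} covers positions
#' \code{[l, l + nchar(word))} of the transform string.
#'
#' @param word Word over \code{A, C, G, T}.
#' @param rs A [read_set()].
#' @param transforms Subset of \code{c("F", "R", "C", "RC")}.
#' @return Data frame with columns \code{read} (1-based read index),
#'   \code{transform}, \code{offset} (0-based), \code{length}.
#' @export
#' @examples
#' occurrences("AC", read_set("ACAC"), transforms = "F")
occurrences <- function(word, rs, transforms = .TRANSFORMS) {
  stopifnot(inherits(rs, "read_set"))
  if (!is.character(word) || length(word) != 1L || nchar(word) < 1L)
    stop("word must be a single non-empty string")
  word <- toupper(word)
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}")
  transforms <- .check_transforms(transforms)
  out <- list()
  for (tr in transforms) {
    strs <- .transform_strings(rs$reads, tr)
    hits <- Biostrings::startIndex(
      Biostrings::vmatchPattern(word, Biostrings::DNAStringSet(strs),
                                fixed = TRUE))
    for (i in seq_along(hits)) {
      st <- hits[[i]]
      if (length(st))
        out[[length(out) + 1L]] <- data.frame(
          read = i, transform = tr, offset = st - 1L,
          length = nchar(word), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(read = integer(0), transform = character(0),
                      offset = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
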