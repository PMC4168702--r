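#' Read sequences from a FASTA or FASTQ file
#'
#' Parses a (possibly gzipped) FASTA or FASTQ file into a data frame of
#' sequence records.  FASTQ quality strings are parsed and discarded: all
#' downstream statistics in this package are quality-agnostic.  Sequences are
#' case-normalized to upper case and restricted to the alphabet
#' \code{A, C, G, T, N}; any other symbol is an error.
#'
#' @param path Path to the input file.
#' @param format Either \code{"fasta"} or \code{"fastq"}.
#' @return A data frame with character columns \code{id} and \code{seq}, one
#'   row per record, in file order.  Record ids are truncated at the first
#'   whitespace.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgt"), fa)
#' read_sequences(fa)
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(xs) == 0L) stop("no sequence records in ", path)
  ids <- sub("\\s.*$", "", names(xs))
  seqs <- toupper(as.character(xs))
  if (any(!nzchar(ids))) stop("empty record id in ", path)
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record ", ids[which(bad)[1]], " contains symbols outside {A,C,G,T,N}")
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param records Data frame with columns \code{id} and \code{seq}, as
#'   returned by [read_sequences()].
#' @param path Output path.
#' @param format Either \code{"fasta"} or \code{"fastq"}; FASTQ is written
#'   with constant placeholder qualities (`I`) since qualities are not used.
#' @return Invisibly, \code{path}.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", records$id), records$seq))
  } else {
    quals <- vapply(nchar(records$seq),
                    function(n) strrep("I", n), character(1))
    lines <- as.vector(rbind(paste0("@", records$id), records$seq, "+", quals))
  }
  writeLines(lines, path)
  invisible(path)
}

.check_dist_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("distance matrix must be numeric")
  n <- nrow(m)
  if (n < 2L || ncol(m) != n) stop("distance matrix must be square, n >= 2")
  labels <- rownames(m)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
    stop("distance matrix needs unique non-empty row labels")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  if (max(abs(diag(m))) > 1e-9) stop("distance matrix diagonal is not zero")
  invisible(m)
}

#' Write a square PHYLIP distance matrix
#'
#' Classic square PHYLIP dialect: the first line holds the number of taxa;
#' each following row holds the taxon name padded or truncated to 10
#' characters, then the full row of distances.  Labels that collide after
#' truncation to 10 characters are an error.
#'
#' @param m Labelled symmetric numeric matrix with zero diagonal.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_phylip_matrix <- function(m, path) {
  .check_dist_matrix(m)
  labels <- substr(rownames(m), 1L, 10L)
  if (anyDuplicated(labels))
    stop("labels collide after truncation to 10 characters: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(formatC(labels[i], width = -10L),
           paste(sprintf("%.6f", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(as.character(nrow(m)), rows), path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to a file written in the dialect of
#'   [write_phylip_matrix()].
#' @return Labelled symmetric numeric matrix.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("truncated PHYLIP matrix file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2L) stop("invalid taxon count on line 1")
  if (length(lines) < n + 1L) stop("expected ", n, " matrix rows")
  labels <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    labels[i] <- trimws(substr(row, 1L, 10L))
    vals <- as.numeric(strsplit(trimws(substring(row, 11L)), "\\s+")[[1]])
    if (length(vals) != n) stop("row ", i, " has ", length(vals),
                                " values, expected ", n)
    m[i, ] <- vals
  }
  dimnames(m) <- list(labels, labels)
  .check_dist_matrix(m)
  m
}

#' Read or write a Newick tree
#'
#' Thin wrappers over \pkg{ape}'s Newick parser and serializer, used for
#' reference taxonomies and reconstructed trees.
#'
#' @param path Path to a Newick file.
#' @return [read_newick()] returns an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("failed to parse Newick file: ", path)
  tr
}

#' @rdname read_newick
#' @param tree An \code{ape::phylo} tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
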