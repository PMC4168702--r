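#' Construct a Markov background model
#'
#' Order-0 (i.i.d.) or order-1 Markov chain over \code{A, C, G, T}, used as
#' the null model for word probabilities and expected occurrence counts.
#'
#' @param initial Numeric vector of 4 initial probabilities, named or in
#'   \code{A, C, G, T} order; must sum to 1.
#' @param transition 4x4 row-stochastic transition matrix (order 1).  For an
#'   order-0 model this may be omitted.
#' @param order 0 or 1.
#' @param trained_on Text label recording provenance.
#' @return An object of class \code{markov_model}.
#' @export
#' @examples
#' m <- markov_model(rep(0.25, 4), order = 0)
#' word_probability(m, "ACG")   # 4^-3
markov_model <- function(initial, transition = NULL, order = 1L,
                         trained_on = "user") {
  order <- as.integer(order)
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  bases <- c("A", "C", "G", "T")
  initial <- as.numeric(initial)
  if (length(initial) != 4L || any(initial < 0))
    stop("initial must be 4 non-negative probabilities")
  if (abs(sum(initial) - 1) > 1e-12) stop("initial probabilities must sum to 1")
  names(initial) <- bases
  if (is.null(transition)) {
    # order-0 models are represented with constant transition rows so the
    # chain-product word probability applies uniformly at both orders
    transition <- matrix(initial, 4L, 4L, byrow = TRUE)
  }
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(4L, 4L)) || any(transition < 0))
    stop("transition must be a non-negative 4x4 matrix")
  if (max(abs(rowSums(transition) - 1)) > 1e-12)
    stop("transition rows must sum to 1")
  dimnames(transition) <- list(bases, bases)
  structure(list(order = order, initial = initial, transition = transition,
                 trained_on = as.character(trained_on)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("markov_model (order ", x$order, ", trained on ", x$trained_on, ")\n",
      sep = "")
  cat("initial:", paste(sprintf("%s=%.4f", names(x$initial), x$initial),
                        collapse = " "), "\n")
  if (x$order == 1L) {
    cat("transition:\n")
    print(round(x$transition, 4))
  }
  invisible(x)
}

#' Fit a Markov background model to a read set
#'
#' Order 0: smoothed symbol frequencies.  Order 1: smoothed adjacent-pair
#' frequencies counted within reads (never across read boundaries), with the
#' initial distribution taken as the empirical symbol frequencies.  Positions
#' holding \code{N} contribute neither symbol nor pair counts.
#'
#' @param rs A [read_set()].
#' @param order 0 or 1 (default 1, the model used by the Under2 score).
#' @param pseudocount Added to every count cell before normalization
#'   (default 1); keeps all probabilities strictly positive, which is
#'   required because word probabilities appear in denominators.
#' @return A [markov_model()].
#' @export
fit_markov <- function(rs, order = 1L, pseudocount = 1) {
  stopifnot(inherits(rs, "read_set"))
  order <- as.integer(order)
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (total_length(rs) < 2L) stop("need at least 2 symbols to fit a model")
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(rs$reads, "", fixed = TRUE)
  all_chars <- unlist(chars, use.names = FALSE)
  sym <- table(factor(all_chars[all_chars %in% bases], levels = bases))
  initial <- (as.numeric(sym) + pseudocount)
  if (sum(initial) == 0) stop("no ACGT symbols in read set")
  initial <- initial / sum(initial)
  if (order == 0L)
    return(markov_model(initial, order = 0L, trained_on = rs$label))
  a <- unlist(lapply(chars, function(v) v[-length(v)]), use.names = FALSE)
  b <- unlist(lapply(chars, function(v) v[-1L]), use.names = FALSE)
  keep <- a %in% bases & b %in% bases
  pair <- table(factor(a[keep], levels = bases), factor(b[keep], levels = bases))
  trans <- matrix(as.numeric(pair), 4L, 4L) + pseudocount
  # a context never observed (possible only with pseudocount 0) gets a
  # uniform row, so the matrix stays row-stochastic
  empty <- rowSums(trans) == 0
  trans[empty, ] <- 0.25
  trans <- trans / rowSums(trans)
  markov_model(initial, trans, order = 1L, trained_on = rs$label)
}

#' Probability of a word under a Markov model
#'
#' Order 0: the product of base probabilities.  Order 1: the initial
#' probability of the first base times the chain of transition
#' probabilities.
#'
#' @param m A [markov_model()].
#' @param w Word(s) over \code{A, C, G, T}; vectorized.
#' @return Numeric vector of probabilities in (0, 1].
#' @export
word_probability <- function(m, w) {
  exp(.word_logprob(m, w))
}

# Log word probability accumulated left to right (one term per position), so
# equal-probability ties are resolved identically to the compiled engine.
.word_logprob <- function(m, w) {
  stopifnot(inherits(m, "markov_model"))
  if (any(nchar(w) < 1L)) stop("words must be non-empty")
  if (any(grepl("[^ACGT]", toupper(w)))) stop("words must be over {A,C,G,T}")
  lpi <- log(m$initial)
  lA <- log(m$transition)
  vapply(toupper(w), function(word) {
    codes <- match(strsplit(word, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    p <- lpi[codes[1]]
    if (length(codes) > 1L)
      for (t in seq_len(length(codes) - 1L)) p <- p + lA[codes[t], codes[t + 1L]]
    unname(p)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Expected occurrence count of a word in a read set
#'
#' Under the null model, a word of length \eqn{|w|} can start at
#' \eqn{\beta - |w| + 1} positions of each of \eqn{M} reads, so its expected
#' occurrence count is \eqn{E[occ_w] = p_w \, M \, (\beta - |w| + 1)}.  When
#' occurrences are also counted on transform strings (reverse, complement,
#' reverse-complement), the number of searched strings scales the count of
#' possible match sites, hence the \code{transform_count} factor.
#'
#' @param m A [markov_model()].
#' @param w A word over \code{A, C, G, T}.
#' @param M Number of reads.
#' @param beta Read length; must satisfy \code{nchar(w) <= beta}.
#' @param transform_count Number of searched strings per read (1 in
#'   forward-only mode, 4 when all transforms are enabled).
#' @return Expected occurrence count (positive real).
#' @export
#' @examples
#' m <- markov_model(rep(0.25, 4), order = 0)
#' expected_occurrences(m, "ACG", M = 10, beta = 10)   # 10 * 8 / 64
expected_occurrences <- function(m, w, M, beta, transform_count = 1L) {
  stopifnot(inherits(m, "markov_model"), M >= 1, beta >= 1,
            transform_count >= 1)
  if (nchar(w) > beta) stop("word longer than the read length")
  word_probability(m, w) * M * transform_count * (beta - nchar(w) + 1)
}

#' Monte-Carlo calibration of the expected occurrence count
#'
#' Simulates independent read sets from a Markov model, counts the (forward,
#' possibly overlapping) occurrences of a fixed word in each set, divides by
#' the closed-form expectation \eqn{E[occ_w] = p_w M (\beta - |w| + 1)}, and
#' averages.  Under the generating model (with a stationary initial
#' distribution for order 1) the expectation of this ratio is exactly 1.
#'
#' @param m A [markov_model()] used both to generate and to compute
#'   \eqn{E[occ_w]}.
#' @param word Word over \code{A, C, G, T} with \code{nchar(word) <= beta}.
#' @param n_sets Number of independent read sets.
#' @param M Reads per set.
#' @param beta Read length.
#' @param chunk Read sets generated per batch (memory/speed trade-off).
#' @return List with \code{mean}, \code{se} (standard error of the mean)
#'   and the per-set \code{ratios}.
#' @export
occurrence_ratio_calibration <- function(m, word, n_sets = 10000L, M = 50L,
                                         beta = 200L, chunk = 200L) {
  stopifnot(inherits(m, "markov_model"), n_sets >= 2L)
  E <- expected_occurrences(m, word, M = M, beta = beta, transform_count = 1L)
  ratios <- numeric(0)
  done <- 0L
  while (done < n_sets) {
    b <- min(chunk, n_sets - done)
    rs <- markov_reads(m, M * b, beta)
    counts <- Biostrings::vcountPattern(
      word, Biostrings::DNAStringSet(rs$reads), fixed = TRUE)
    per_set <- as.numeric(rowsum(counts, rep(seq_len(b), each = M)))
    ratios <- c(ratios, per_set / E)
    done <- done + b
  }
  list(mean = mean(ratios), se = stats::sd(ratios) / sqrt(length(ratios)),
       ratios = ratios)
}

#' Stationary distribution of an order-1 Markov model
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.  Generating reads with the stationary distribution
#' as the initial law makes the closed-form expected occurrence count exact
#' at every read position.
#'
#' @param m A [markov_model()] of order 1.
#' @return Named probability vector over \code{A, C, G, T}.
#' @export
stationary_distribution <- function(m) {
  stopifnot(inherits(m, "markov_model"))
  e <- eigen(t(m$transition))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  stats::setNames(v / sum(v), c("A", "C", "G", "T"))
}
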