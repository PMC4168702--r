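#' Default implantation motifs
#'
#' Five fixed words of lengths 5, 4, 5, 6, 6.  The common-motif (CM) model
#' implants only the first (length 5); the multiple-motif models (SMM, FMM)
#' use all five.  The words themselves are arbitrary documented constants —
#' configuration, not ground truth — and can be replaced through
#' [simulation_config()].
#'
#' @return Character vector of five motifs.
#' @export
default_motifs <- function() {
  c("CTGAG", "ACCT", "TGCAT", "CGATAC", "TAGGCT")
}

#' Configuration for the benchmark simulator
#'
#' Bundles every knob of the synthetic benchmark: background sequence
#' model, motif-implantation correlation model, read sampling, and
#' sequencing error.  Defaults reproduce the standard benchmark
#' conditions: reads of length \eqn{\beta = 200} at coverage
#' \eqn{\gamma = 5}, motif intensity \eqn{\lambda = 0.001}, error-free
#' sequencing.
#'
#' @param N Background sequence length (default 2000).
#' @param lambda Per-position implantation probability \eqn{\lambda}.
#' @param model Correlation model: \code{"NONE"}, \code{"CM"} (one fixed
#'   length-5 motif), \code{"SMM"} (five motifs and their
#'   reverse-complements, 10 equiprobable variants), \code{"FMM"} (adds the
#'   reverses, 15 variants).
#' @param motifs Motif words; CM uses the first.
#' @param background \code{"uniform"} (each base 1/4), \code{"gcrich"}
#'   (\eqn{p_A = p_T = 1/6}, \eqn{p_C = p_G = 1/3}), or
#'   \code{"fasta-window"} (a uniformly chosen length-\code{N} window from
#'   a record of \code{fasta}).
#' @param fasta Path to a FASTA file for \code{background = "fasta-window"}.
#' @param gamma Coverage \eqn{\gamma}; the read count is
#'   \eqn{M = \lceil \gamma N / \beta \rceil}.
#' @param beta Read length \eqn{\beta}.
#' @param error_rate Per-base substitution probability (default 0).
#' @param both_strands Reverse-complement each read with probability 1/2.
#' @param seed Integer seed consumed by [build_experiment()] for fully
#'   deterministic replication.
#' @return Object of class \code{sim_config}.
#' @export
simulation_config <- function(N = 2000L, lambda = 0.001,
                              model = c("CM", "SMM", "FMM", "NONE"),
                              motifs = default_motifs(),
                              background = c("uniform", "gcrich", "fasta-window"),
                              fasta = NULL, gamma = 5, beta = 200L,
                              error_rate = 0, both_strands = FALSE,
                              seed = NULL) {
  model <- match.arg(model)
  background <- match.arg(background)
  N <- as.integer(N); beta <- as.integer(beta)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  if (beta < 1L) stop("beta must be >= 1")
  if (N < beta) stop("background length N must be >= beta")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (model != "NONE") {
    if (length(motifs) < 1L) stop("motifs required for model ", model)
    motifs <- toupper(motifs)
    if (any(grepl("[^ACGT]", motifs))) stop("motifs must be over {A,C,G,T}")
    if (model == "CM" && nchar(motifs[1]) < 1L) stop("CM needs a motif")
  }
  if (background == "fasta-window" && is.null(fasta))
    stop("background 'fasta-window' needs a fasta path")
  structure(list(N = N, lambda = lambda, model = model, motifs = motifs,
                 background = background, fasta = fasta, gamma = gamma,
                 beta = beta, error_rate = error_rate,
                 both_strands = both_strands, seed = seed),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

#' Generate a background sequence
#'
#' Draws from the configured background model: i.i.d. uniform, i.i.d.
#' GC-rich, or a uniformly placed window of a supplied FASTA record (a
#' record is first chosen uniformly among those long enough).  Consumes the
#' current RNG stream; seed upstream (or via [build_experiment()]) for
#' reproducibility.
#'
#' @param cfg A [simulation_config()].
#' @return A single character string of length \code{cfg$N}.
#' @export
generate_background <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$background == "uniform") {
    return(paste(sample(.BASES, cfg$N, replace = TRUE), collapse = ""))
  }
  if (cfg$background == "gcrich") {
    p <- c(1 / 6, 1 / 3, 1 / 3, 1 / 6)
    return(paste(sample(.BASES, cfg$N, replace = TRUE, prob = p), collapse = ""))
  }
  recs <- read_sequences(cfg$fasta, format = "fasta")
  ok <- which(nchar(recs$seq) >= cfg$N)
  if (!length(ok))
    stop("no FASTA record is at least ", cfg$N, " bp long")
  rec <- recs$seq[ok[sample.int(length(ok), 1L)]]
  start <- sample.int(nchar(rec) - cfg$N + 1L, 1L)
  substr(rec, start, start + cfg$N - 1L)
}

# Variant list for the configured correlation model: CM = the first motif;
# SMM = each motif and its reverse-complement (10 variants); FMM = motif,
# reverse-complement and reverse (15 variants).  All variants equiprobable.
.motif_variants <- function(cfg) {
  switch(cfg$model,
    CM = cfg$motifs[1],
    SMM = as.vector(vapply(cfg$motifs, function(m)
      c(m, .revcomp1(m)), character(2))),
    FMM = as.vector(vapply(cfg$motifs, function(m)
      c(m, .revcomp1(m),
        paste(rev(strsplit(m, "", fixed = TRUE)[[1]]), collapse = "")),
      character(3))),
    stop("model NONE has no motifs to implant"))
}

#' Implant motifs into a background sequence
#'
#' Scans the sequence left to right; at each position a motif variant is
#' implanted with probability \eqn{\lambda} by overwriting the next
#' \eqn{|m|} symbols in place (the scan then jumps past the implant, so
#' implanted motifs never overlap); otherwise the scan advances one
#' position.  A variant that does not fit in the remaining suffix is
#' skipped and the scan advances one position.  Output length equals input
#' length.
#'
#' @param seq Background sequence (single string).
#' @param cfg A [simulation_config()] with \code{model != "NONE"}.
#' @return The sequence with motifs implanted.  The implant log (a data
#'   frame with 1-based \code{position} and \code{variant}) is attached as
#'   attribute \code{"implants"}.
#' @export
implant_motifs <- function(seq, cfg) {
  stopifnot(inherits(cfg, "sim_config"), is.character(seq), length(seq) == 1L)
  if (cfg$model == "NONE" || cfg$lambda == 0) return(seq)
  variants <- .motif_variants(cfg)
  vchars <- strsplit(variants, "", fixed = TRUE)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  N <- length(s)
  j <- 1L
  at <- integer(0); what <- integer(0)
  repeat {
    # geometric jump = number of non-implant positions before the next
    # implant; equivalent to a per-position Bernoulli(lambda) scan
    j <- j + stats::rgeom(1L, cfg$lambda)
    if (is.na(j) || j > N) break
    v <- sample.int(length(variants), 1L)
    len <- length(vchars[[v]])
    if (j + len - 1L <= N) {
      s[j:(j + len - 1L)] <- vchars[[v]]
      at <- c(at, j); what <- c(what, v)
      j <- j + len
    } else {
      j <- j + 1L
    }
  }
  out <- paste(s, collapse = "")
  attr(out, "implants") <- data.frame(position = at, variant = variants[what],
                                      stringsAsFactors = FALSE)
  out
}

#' Sample reads uniformly from a sequence
#'
#' Draws \eqn{M = \lceil \gamma N / \beta \rceil} reads of length
#' \eqn{\beta} with uniformly random start positions (so the expected
#' per-position depth is \eqn{\gamma}), optionally reverse-complementing
#' each read with probability 1/2 and applying per-base substitution errors.
#'
#' @param seq Source sequence (single string, length \code{>= beta}).
#' @param cfg A [simulation_config()].
#' @param label Label for the returned read set.
#' @return A [read_set()].
#' @export
sample_reads <- function(seq, cfg, label = "sample") {
  stopifnot(inherits(cfg, "sim_config"), is.character(seq), length(seq) == 1L)
  N <- nchar(seq)
  beta <- cfg$beta
  if (N < beta) stop("sequence shorter than the read length")
  M <- as.integer(ceiling(cfg$gamma * N / beta))
  starts <- sample.int(N - beta + 1L, M, replace = TRUE)
  reads <- substring(seq, starts, starts + beta - 1L)
  if (cfg$both_strands) {
    flip <- stats::runif(M) < 0.5
    if (any(flip)) reads[flip] <- vapply(reads[flip], .revcomp1, character(1),
                                         USE.NAMES = FALSE)
  }
  if (cfg$error_rate > 0) {
    hits <- which(stats::runif(M * beta) < cfg$error_rate)
    for (h in hits) {
      ri <- (h - 1L) %/% beta + 1L
      pos <- (h - 1L) %% beta + 1L
      cur <- substr(reads[ri], pos, pos)
      sub <- sample(setdiff(.BASES, cur), 1L)
      substr(reads[ri], pos, pos) <- sub
    }
  }
  read_set(reads, label = label, beta = beta)
}

#' Simulate reads from a Markov chain
#'
#' Generates \code{M} independent reads of length \code{beta} from a
#' [markov_model()]: first base from the model's initial distribution, then
#' chain transitions.  Used for expectation-calibration experiments, where
#' an initial distribution equal to [stationary_distribution()] of the
#' transition matrix makes the closed-form expected occurrence count exact.
#'
#' @param m A [markov_model()].
#' @param M Number of reads.
#' @param beta Read length.
#' @param label Label for the read set.
#' @return A [read_set()].
#' @export
markov_reads <- function(m, M, beta, label = "markov") {
  stopifnot(inherits(m, "markov_model"), M >= 1, beta >= 1)
  M <- as.integer(M); beta <- as.integer(beta)
  cum <- t(apply(m$transition, 1L, cumsum))
  mat <- matrix(0L, M, beta)
  mat[, 1L] <- sample.int(4L, M, replace = TRUE, prob = m$initial)
  if (beta > 1L) for (j in 2:beta) {
    u <- stats::runif(M)
    prev <- mat[, j - 1L]
    mat[, j] <- 1L + (u > cum[prev, 1L]) + (u > cum[prev, 2L]) +
      (u > cum[prev, 3L])
  }
  chars <- matrix(.BASES[mat], M, beta)
  reads <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  read_set(reads, label = label, beta = beta)
}

#' Build a positive/negative benchmark experiment
#'
#' Generates \code{n_neg} independent background sequences (negatives) and
#' \code{n_pos} backgrounds with motifs implanted (positives), and
#' sequences each into a read set.  Sub-seeds for every sequence are
#' derived deterministically from \code{cfg$seed}, so the same
#' configuration reproduces bit-identical read sets.
#'
#' @param cfg A [simulation_config()].
#' @param n_pos,n_neg Numbers of positive and negative sequences
#'   (default 20 + 20).
#' @return A list with \code{positives} and \code{negatives} (lists of
#'   [read_set()]) and \code{config}.
#' @export
build_experiment <- function(cfg, n_pos = 20L, n_neg = 20L) {
  stopifnot(inherits(cfg, "sim_config"), n_pos >= 2L, n_neg >= 2L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, n_pos + n_neg)
  make_one <- function(seed, positive, label) {
    set.seed(seed)
    bg <- generate_background(cfg)
    if (positive) bg <- implant_motifs(bg, cfg)
    sample_reads(bg, cfg, label = label)
  }
  positives <- lapply(seq_len(n_pos), function(i)
    make_one(seeds[i], TRUE, sprintf("pos_%02d", i)))
  negatives <- lapply(seq_len(n_neg), function(i)
    make_one(seeds[n_pos + i], FALSE, sprintf("neg_%02d", i)))
  list(positives = positives, negatives = negatives, config = cfg)
}

#' Simulate a family of genomes along a phylogeny
#'
#' Evolves a uniform i.i.d. root sequence down an \code{ape::phylo} tree:
#' along each edge every base is substituted, with probability equal to the
#' edge length (interpreted as a per-base substitution probability), by a
#' uniformly chosen different base.  The tip sequences provide genomes with
#' a known generating topology for end-to-end phylogeny benchmarks.
#'
#' @param tree An \code{ape::phylo} tree with edge lengths in \eqn{[0, 1)}.
#' @param N Genome (root sequence) length.
#' @return Named character vector of tip genomes.
#' @export
simulate_genome_family <- function(tree, N) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0 | tree$edge.length >= 1))
    stop("edge lengths must be substitution probabilities in [0, 1)")
  N <- as.integer(N)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample(.BASES, N, replace = TRUE)
  # preorder edge traversal so parents are simulated before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  edges <- tr$edge
  elen <- tr$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    s <- seqs[[parent]]
    hit <- which(stats::runif(N) < elen[e])
    if (length(hit)) {
      cur <- s[hit]
      s[hit] <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L),
                       character(1), USE.NAMES = FALSE)
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}
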