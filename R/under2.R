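#' Under2 dissimilarity between read sets
#'
#' The Under2 statistic compares two read sets through their underlying
#' common patterns: variable-length words shared by the two sets, filtered
#' for redundancy and greedily assigned to non-overlapping (untied)
#' occurrences, so every read position contributes at most once.  Each
#' selected pattern contributes its untied positions weighted by the ratio
#' of its observed to expected occurrence count under a first-order Markov
#' background fitted on the scored set:
#' \deqn{Score(R_1, R_2) = \frac{1}{|R_1|} \sum_{w \in U} |w| \,
#'   untied_w^1 \, \frac{occ_w}{E[occ_w]}}
#' with \eqn{E[occ_w] = p_w M (\beta - |w| + 1)} (scaled by the number of
#' enabled transform strings).  The directional statistic is
#' \deqn{Under^2(R_1, R_2) = \log_4 |R_2| / Score(R_1, R_2) - \log_4 |R_1|}
#' and the symmetric dissimilarity is the average of the two directions.
#'
#' @param r1,r2 [read_set()] objects.
#' @param transforms Subset of \code{c("F", "R", "C", "RC")}; all four by
#'   default, so patterns are also matched on reverses, complements and
#'   reverse-complements.
#' @param markov_order Order of the background model fitted to the scored
#'   set (default 1).
#' @param pseudocount Smoothing count for the background fit (default 1).
#' @param model_scope \code{"r1"} fits the background on the set whose
#'   positions are being scored (default); \code{"pooled"} fits one model on
#'   both sets.
#' @return For [under2()], a list of class \code{under2_comparison} with
#'   \code{score_12}, \code{score_21}, \code{under2_12}, \code{under2_21},
#'   the symmetric \code{under2}, and a \code{diagnostics} list (pattern
#'   counts and mean underlying-pattern lengths per direction).
#' @seealso [irredundant_common_patterns()], [extract_underlying()]
#' @export
#' @examples
#' set.seed(1)
#' g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
#' cfg <- simulation_config(N = 2000, gamma = 2, beta = 100)
#' ra <- sample_reads(g, cfg, label = "a")
#' rb <- sample_reads(g, cfg, label = "b")
#' under2(ra, rb)$under2
under2 <- function(r1, r2, transforms = c("F", "R", "C", "RC"),
                   markov_order = 1L, pseudocount = 1,
                   model_scope = c("r1", "pooled")) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  model_scope <- match.arg(model_scope)
  if (identical(sort(r1$reads), sort(r2$reads))) {
    # self-comparison: the statistic is exactly zero by construction
    out <- list(score_12 = NA_real_, score_21 = NA_real_,
                under2_12 = 0, under2_21 = 0, under2 = 0,
                diagnostics = list(self = TRUE))
    class(out) <- "under2_comparison"
    return(out)
  }
  d12 <- .under2_direction(r1, r2, transforms, markov_order, pseudocount,
                           model_scope)
  d21 <- .under2_direction(r2, r1, transforms, markov_order, pseudocount,
                           model_scope)
  u12 <- .under2_from_score(d12$score, total_length(r1), total_length(r2))
  u21 <- .under2_from_score(d21$score, total_length(r2), total_length(r1))
  out <- list(score_12 = d12$score, score_21 = d21$score,
              under2_12 = u12, under2_21 = u21,
              under2 = (u12 + u21) / 2,
              diagnostics = list(
                self = FALSE,
                n_patterns = c(d12$n_patterns, d21$n_patterns),
                n_irredundant = c(d12$n_irredundant, d21$n_irredundant),
                mean_length = c(d12$mean_length, d21$mean_length)))
  class(out) <- "under2_comparison"
  out
}

#' @export
print.under2_comparison <- function(x, ...) {
  cat("under2 comparison\n")
  if (isTRUE(x$diagnostics$self)) {
    cat("  identical read sets: under2 = 0\n")
  } else {
    cat(sprintf("  score 1->2: %.6g   score 2->1: %.6g\n",
                x$score_12, x$score_21))
    cat(sprintf("  under2 1->2: %.6g  under2 2->1: %.6g\n",
                x$under2_12, x$under2_21))
    cat(sprintf("  symmetric under2: %.6g\n", x$under2))
  }
  invisible(x)
}

# One direction of the statistic via the compiled engine: fit the background,
# extract the underlying patterns, and evaluate the score sum.
.under2_direction <- function(r1, r2, transforms, markov_order, pseudocount,
                              model_scope) {
  model <- if (model_scope == "r1") {
    .rs_cache(r1, sprintf("markov_%d_%g", markov_order, pseudocount),
              function() fit_markov(r1, order = markov_order,
                                    pseudocount = pseudocount))
  } else {
    fit_markov(read_set(c(r1$reads, r2$reads), label = "pooled"),
               order = markov_order, pseudocount = pseudocount)
  }
  pd <- .pattern_docs(r1, r2, transforms)
  res <- underlying_cpp(pd$docs, pd$table$set, model$initial,
                        model$transition, FALSE)
  len1 <- nchar(r1$reads)
  sc <- .score_sum(res$length, res$untied1, res$occ1, res$pw,
                   length(pd$transforms), len1)
  list(score = sc,
       n_patterns = length(res$length),
       n_irredundant = res$n_irredundant,
       mean_length = if (length(res$length)) mean(res$length) else NA_real_)
}

# Score(R1,R2) = (1/|R1|) * sum |w| * untied^1_w * occ_w / E[occ_w], with
# E[occ_w] = p_w * transform_count * sum_r max(0, len_r - |w| + 1); the
# possible-positions sum generalizes M * (beta - |w| + 1) to reads of
# unequal length.
.score_sum <- function(len, untied1, occ1, pw, transform_count, read_lens) {
  if (!length(len)) return(0)
  uk <- sort(unique(len))
  poss <- vapply(uk, function(k) sum(pmax(0L, read_lens - k + 1L)), numeric(1))
  E <- pw * transform_count * poss[match(len, uk)]
  sum(len * untied1 * occ1 / E) / sum(read_lens)
}

.under2_from_score <- function(score, len1, len2) {
  if (score <= 0) {
    warning("no shared signal between the read sets; Under2 is infinite")
    return(Inf)
  }
  log(len2, base = 4) / score - log(len1, base = 4)
}

#' Directional Under2 statistic
#'
#' \eqn{Under^2(R_1, R_2) = \log_4 |R_2| / Score(R_1, R_2) - \log_4 |R_1|},
#' where \eqn{|R|} is the total forward length of a read set.  The
#' centering term makes the statistic zero for identical inputs.
#'
#' @inheritParams under2
#' @return A single numeric value (\code{Inf} with a warning when the sets
#'   share no patterns at all).
#' @export
under2_asym <- function(r1, r2, transforms = c("F", "R", "C", "RC"),
                        markov_order = 1L, pseudocount = 1,
                        model_scope = c("r1", "pooled")) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  model_scope <- match.arg(model_scope)
  d <- .under2_direction(r1, r2, transforms, markov_order, pseudocount,
                         model_scope)
  .under2_from_score(d$score, total_length(r1), total_length(r2))
}

#' Under2 score of one direction
#'
#' Evaluates \eqn{Score(R_1, R_2)} either from scratch (fitting the model
#' and extracting the underlying patterns internally) or from an explicit
#' [extract_underlying()] result and [markov_model()], which lets the score
#' be cross-checked against an independently derived underlying set.
#'
#' @inheritParams under2
#' @param underlying Optional \code{underlying_patterns} object extracted
#'   from \code{(r1, r2)}.
#' @param model Optional [markov_model()]; required when \code{underlying}
#'   is given, otherwise fitted on \code{r1}.
#' @return The score (non-negative real).
#' @export
under2_score <- function(r1, r2, underlying = NULL, model = NULL,
                         transforms = c("F", "R", "C", "RC"),
                         markov_order = 1L, pseudocount = 1) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  if (is.null(underlying)) {
    d <- .under2_direction(r1, r2, transforms, markov_order, pseudocount,
                           model_scope = "r1")
    return(d$score)
  }
  stopifnot(inherits(underlying, "underlying_patterns"))
  if (is.null(model)) stop("model is required when underlying is supplied")
  p <- underlying$patterns
  .score_sum(p$length, p$untied1, p$occ1, word_probability(model, p$word),
             length(underlying$transforms), nchar(r1$reads))
}
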