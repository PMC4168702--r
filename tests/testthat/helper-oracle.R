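# Literal brute-force oracle for irredundant / underlying common patterns,
# written directly from the definitions and independent of the package's
# suffix-array engine.  Intended for tiny instances only.

.o_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}
.o_rev <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# Documents in the canonical order: set 1 blocks F,R,C,RC (reads in order),
# then set 2.  Returns data.frame(doc, set, transform, read, string, gstart).
oracle_docs <- function(r1, r2, transforms) {
  rows <- list()
  for (s in 1:2) {
    reads <- (if (s == 1) r1 else r2)$reads
    for (tr in transforms) {
      strs <- switch(tr,
        F = reads,
        R = vapply(reads, .o_rev, character(1), USE.NAMES = FALSE),
        C = chartr("ACGTN", "TGCAN", reads),
        RC = vapply(reads, .o_revcomp, character(1), USE.NAMES = FALSE))
      for (i in seq_along(strs))
        rows[[length(rows) + 1L]] <- data.frame(
          set = s, transform = tr, read = i, string = strs[i],
          stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$doc <- seq_len(nrow(df))
  df$gstart <- cumsum(c(0L, nchar(df$string)))[seq_len(nrow(df))]
  df
}

# All substrings (word, doc, offset 0-based, length) of every document;
# substrings containing N are excluded (N matches nothing).
oracle_substrings <- function(docs) {
  out <- lapply(seq_len(nrow(docs)), function(d) {
    str <- docs$string[d]
    L <- nchar(str)
    starts <- rep(seq_len(L), times = L:1)
    lens <- unlist(lapply(seq_len(L), function(s) seq_len(L - s + 1L)))
    words <- substring(str, starts, starts + lens - 1L)
    keep <- !grepl("N", words, fixed = TRUE)
    data.frame(word = words[keep], doc = d, offset = starts[keep] - 1L,
               length = lens[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Definition 1, literally: a common pattern is irredundant iff at least one
# of its occurrences is not contained (same document) in an occurrence of a
# longer common pattern.
oracle_irredundant <- function(r1, r2, transforms = "F") {
  docs <- oracle_docs(r1, r2, transforms)
  subs <- oracle_substrings(docs)
  subs$set <- docs$set[subs$doc]
  shared <- intersect(unique(subs$word[subs$set == 1]),
                      unique(subs$word[subs$set == 2]))
  occ <- subs[subs$word %in% shared, , drop = FALSE]
  keep <- character(0)
  for (d in unique(occ$doc)) {
    oc <- occ[occ$doc == d, , drop = FALSE]
    s <- oc$offset; e <- oc$offset + oc$length; L <- oc$length
    contained <- outer(s, s, ">=") & outer(e, e, "<=") & outer(L, L, "<")
    keep <- c(keep, oc$word[!apply(contained, 1L, any)])
  }
  words <- sort(unique(keep))
  occ <- occ[occ$word %in% words, , drop = FALSE]
  occ <- occ[order(occ$word, occ$doc, occ$offset), , drop = FALSE]
  rownames(occ) <- NULL
  list(words = words, occurrences = occ, docs = docs)
}

.o_logprob <- function(m, w) {
  lpi <- log(m$initial); lA <- log(m$transition)
  codes <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
  p <- lpi[codes[1]]
  if (length(codes) > 1L)
    for (t in seq_len(length(codes) - 1L)) p <- p + lA[codes[t], codes[t + 1L]]
  unname(p)
}

# Definition 2 via the greedy location-vector algorithm, literally: rank by
# the priority rule, then accept a pattern iff it has at least one untied
# occurrence per set, claiming cells progressively in position order.
oracle_underlying <- function(r1, r2, m, transforms = "F") {
  ir <- oracle_irredundant(r1, r2, transforms)
  if (!length(ir$words)) return(list(patterns = NULL, ir = ir))
  occ <- ir$occurrences
  lens <- nchar(ir$words)
  lpw <- vapply(ir$words, function(w) .o_logprob(m, w), numeric(1))
  gpos <- ir$docs$gstart[occ$doc] + occ$offset
  first <- vapply(ir$words, function(w) min(gpos[occ$word == w]), numeric(1))
  ord <- order(-lens, lpw, first, ir$words)
  gamma <- lapply(nchar(ir$docs$string), function(L) rep(FALSE, L))
  res <- list()
  for (idx in ord) {
    w <- ir$words[idx]; k <- lens[idx]
    oc <- occ[occ$word == w, , drop = FALSE]
    oc <- oc[order(oc$doc, oc$offset), , drop = FALSE]
    claimed <- list(); u <- c(0L, 0L)
    for (r in seq_len(nrow(oc))) {
      cells <- (oc$offset[r] + 1L):(oc$offset[r] + k)
      d <- oc$doc[r]
      if (any(gamma[[d]][cells])) next
      gamma[[d]][cells] <- TRUE
      claimed[[length(claimed) + 1L]] <- c(d, oc$offset[r])
      u[oc$set[r]] <- u[oc$set[r]] + 1L
    }
    if (all(u >= 1L)) {
      res[[length(res) + 1L]] <- data.frame(
        word = w, length = k, untied1 = u[1], untied2 = u[2],
        occ1 = sum(oc$set == 1), occ2 = sum(oc$set == 2),
        stringsAsFactors = FALSE)
    } else {
      for (cl in claimed)
        gamma[[cl[1]]][(cl[2] + 1L):(cl[2] + k)] <- FALSE
    }
  }
  pats <- if (length(res)) do.call(rbind, res) else NULL
  list(patterns = pats, ir = ir, gamma = gamma)
}

# Random small instance: 2-10 reads of length 8-30 per set, occasionally with
# a planted shared word (to exercise long shared patterns) or an N.
random_instance <- function(plant = TRUE) {
  mk <- function(planted) {
    n <- sample(2:10, 1)
    reads <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(8:30, 1), TRUE),
            collapse = ""), character(1))
    if (!is.null(planted)) {
      i <- sample(n, 1)
      if (nchar(reads[i]) >= nchar(planted)) {
        at <- sample(nchar(reads[i]) - nchar(planted) + 1L, 1)
        substr(reads[i], at, at + nchar(planted) - 1L) <- planted
      }
    }
    reads
  }
  planted <- if (plant && runif(1) < 0.6)
    paste(sample(c("A", "C", "G", "T"), sample(5:12, 1), TRUE), collapse = "")
  else NULL
  r1 <- mk(planted)
  r2 <- mk(planted)
  if (runif(1) < 0.15) {  # sprinkle an N
    i <- sample(length(r1), 1)
    p <- sample(nchar(r1[i]), 1)
    substr(r1[i], p, p) <- "N"
  }
  list(r1 = read_set(r1, "r1"), r2 = read_set(r2, "r2"))
}
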