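# Independent brute-force oracles used to check the package's algorithms.
# These deliberately re-derive results by naive enumeration and share no
# code with the implementation.

# ---- C-value oracle -------------------------------------------------------

# Exhaustive substring counting + literal formula over a corpus given as a
# list of token vectors (content tokens only).
oracle_cvalue <- function(runs, max_len = 6L) {
  freq <- list()
  for (run in runs) {
    n <- length(run)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):min(n, i + max_len - 1L)) {
        key <- paste(run[i:j], collapse = " ")
        freq[[key]] <- (if (is.null(freq[[key]])) 0L else freq[[key]]) + 1L
      }
    }
  }
  surfaces <- names(freq)
  res <- data.frame(surface = surfaces, stringsAsFactors = FALSE)
  res$length <- lengths(strsplit(surfaces, " ", fixed = TRUE))
  res$freq <- unlist(freq, use.names = FALSE)
  res$cvalue <- NA_real_
  for (i in seq_along(surfaces)) {
    a <- surfaces[i]
    containing <- surfaces[vapply(surfaces, function(b) {
      b != a && grepl(paste0(" ", a, " "), paste0(" ", b, " "), fixed = TRUE)
    }, logical(1))]
    if (length(containing) == 0L) {
      res$cvalue[i] <- log2(res$length[i]) * res$freq[i]
    } else {
      tfreq <- sum(res$freq[match(containing, surfaces)])
      res$cvalue[i] <- log2(res$length[i]) *
        (res$freq[i] - tfreq / length(containing))
    }
  }
  res
}

# ---- span containment antichain oracle ------------------------------------

# keep span i iff no other span strictly contains it (pairwise check)
oracle_antichain <- function(spans) {
  spans <- spans[!duplicated(spans[, c("start", "end")]), , drop = FALSE]
  keep <- rep(TRUE, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    for (j in seq_len(nrow(spans))) {
      if (i == j) next
      inside <- spans$start[j] <= spans$start[i] && spans$end[j] >= spans$end[i]
      strict <- spans$start[j] < spans$start[i] || spans$end[j] > spans$end[i]
      if (inside && strict) keep[i] <- FALSE
    }
  }
  spans[keep, , drop = FALSE]
}

# ---- bipartite span-matching oracle ---------------------------------------

# maximum one-to-one matching by exhaustive assignment (<= 5 a side)
oracle_match_counts <- function(pred, gold, relaxed = FALSE) {
  compatible <- function(p, g) {
    if (pred$characteristic[p] != gold$characteristic[g]) return(FALSE)
    if (relaxed) {
      gold$start[g] < pred$end[p] && gold$end[g] > pred$start[p]
    } else {
      pred$start[p] == gold$start[g] && pred$end[p] == gold$end[g]
    }
  }
  np <- nrow(pred); ng <- nrow(gold)
  best <- 0L
  assign_next <- function(p, used, count) {
    if (p > np) { best <<- max(best, count); return(invisible()) }
    assign_next(p + 1L, used, count)          # leave p unmatched
    for (g in seq_len(ng)) {
      if (!used[g] && compatible(p, g)) {
        used[g] <- TRUE
        assign_next(p + 1L, used, count + 1L)
        used[g] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, max(ng, 1L)), 0L)
  c(tp = best, fp = np - best, fn = ng - best)
}

# ---- rule matching oracle -------------------------------------------------

# Brute-force matcher over a token stream with single-token tags and rules
# made of DICT_CLASS / LITERAL / REGEX constituents: enumerates every start
# position, every ordering of the capture-block constituents (order inside
# the bracket is unordered by design, tried identity first) and every
# on/off combination of the optional constituents, then applies the
# leftmost-longest, non-overlapping policy.
oracle_match_rule <- function(cons, capture, tokens, tag_class) {
  n <- length(tokens)
  perm_list <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  block <- capture[1]:capture[2]
  orderings <- lapply(perm_list(block), function(p) {
    ord <- seq_along(cons)
    ord[block] <- p
    ord
  })
  consumes <- function(con, pos) {
    if (pos > n) return(FALSE)
    switch(con$kind,
      DICT_CLASS = identical(tag_class[pos], con$payload),
      LITERAL = tolower(tokens[pos]) == tolower(con$payload),
      REGEX = grepl(paste0("^(?:", con$payload, ")$"), tolower(tokens[pos]),
                    perl = TRUE, ignore.case = TRUE))
  }
  match_at <- function(start) {
    found <- NULL
    for (ord in orderings) {
      ocons <- cons[ord]
      oopt <- which(vapply(ocons, function(c) isTRUE(c$optional), logical(1)))
      ocombos <- if (length(oopt)) {
        g <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(oopt))))
        g[, rev(seq_len(ncol(g))), drop = FALSE]
      } else {
        matrix(logical(), nrow = 1, ncol = 0)
      }
      for (ci in seq_len(nrow(ocombos))) {
        on <- rep(TRUE, length(ocons))
        if (length(oopt)) on[oopt] <- unlist(ocombos[ci, ])
        pos <- start
        cap_lo <- NA; cap_hi <- NA
        ok <- TRUE
        for (k in seq_along(ocons)) {
          if (!on[k]) next
          if (!consumes(ocons[[k]], pos)) { ok <- FALSE; break }
          if (k >= capture[1] && k <= capture[2]) {
            if (is.na(cap_lo)) cap_lo <- pos
            cap_hi <- pos + 1L
          }
          pos <- pos + 1L
        }
        if (ok && !is.na(cap_lo)) {
          if (is.null(found) || pos > found$end ||
              (pos == found$end &&
                 (cap_hi - cap_lo) > (found$cap_hi - found$cap_lo))) {
            found <- list(end = pos, cap_lo = cap_lo, cap_hi = cap_hi)
          }
        }
      }
    }
    found
  }
  out <- list()
  pos <- 1L
  while (pos <= n) {
    hit <- match_at(pos)
    if (is.null(hit)) { pos <- pos + 1L; next }
    out[[length(out) + 1L]] <- c(hit$cap_lo, hit$cap_hi)
    pos <- max(hit$end, pos + 1L)
  }
  out
}
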