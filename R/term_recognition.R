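# C-value automatic term recognition: multi-word candidate extraction and
# termhood scoring, feeding the biomedical-term gazetteer.

#' Extract multi-word candidate terms from a corpus
#'
#' Candidates are contiguous token sequences of length >= 2 inside maximal
#' runs of content tokens (a closed-class function-word list and
#' punctuation delimit runs; this token-shape filter approximates the
#' linguistic noun-phrase filter of the C-value method without a POS
#' tagger). Every substring subsequence of length >= 2 of a run is emitted
#' with its own corpus frequency, counting nested occurrences. Surfaces are
#' case-folded; with `merge_variants = TRUE` hyphens are normalised to
#' spaces and a trivial final-token plural is stripped, merging simple
#' orthographic variants.
#'
#' @param corpus `epi_corpus`, list of `epi_document`, or character vector
#'   of texts.
#' @param lex `epi_lexicon` supplying the function-word list.
#' @param max_len Longest candidate (in tokens) considered.
#' @param merge_variants Merge case/hyphen/plural variants.
#' @return Data frame `surface`, `length`, `freq` (one row per candidate).
#' @export
extract_candidates <- function(corpus, lex = load_lexicon(), max_len = 6L,
                               merge_variants = TRUE) {
  texts <- corpus_texts(corpus)
  counts <- new.env(parent = emptyenv())
  for (text in texts) {
    if (merge_variants) text <- gsub("-", " ", text, fixed = TRUE)
    toks <- epi_tokenize(text)
    content <- grepl("^[A-Za-z0-9]", toks$text) & !(toks$lower %in% lex$functionwords)
    # split content runs at sentence boundaries too
    run_id <- cumsum(!content | c(TRUE, diff(toks$sentence) != 0))
    for (run in split(which(content), run_id[content])) {
      n <- length(run)
      if (n < 2L) next
      words <- toks$lower[run]
      if (merge_variants) words <- normalize_tokens(words)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):min(n, i + max_len - 1L)) {
          key <- paste(words[i:j], collapse = " ")
          counts[[key]] <- get0(key, envir = counts, ifnotfound = 0L) + 1L
        }
      }
    }
  }
  surfaces <- ls(counts)
  if (length(surfaces) == 0L) {
    return(data.frame(surface = character(), length = integer(),
                      freq = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(surface = surfaces,
                    length = lengths(strsplit(surfaces, " ", fixed = TRUE)),
                    freq = vapply(surfaces, function(s) counts[[s]], integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$surface), , drop = FALSE]
}

corpus_texts <- function(corpus) {
  if (inherits(corpus, "epi_corpus")) corpus <- corpus$documents
  if (is.character(corpus)) return(corpus)
  vapply(corpus, function(d) {
    if (inherits(d, "epi_document")) d$abstract else as.character(d)
  }, character(1))
}

normalize_tokens <- function(words) {
  # trivial plural stripping: final -s (not -ss/-us/-is) on tokens > 3 chars
  vapply(words, function(w) {
    if (nchar(w) > 3L && grepl("[a-z]s$", w) && !grepl("(ss|us|is)$", w)) {
      sub("s$", "", w)
    } else w
  }, character(1), USE.NAMES = FALSE)
}

#' Score term candidates with the C-value measure
#'
#' For a candidate string a of token length |a| and corpus frequency f(a):
#' non-nested candidates score `log2(|a|) * f(a)`; candidates nested in at
#' least one longer candidate score
#' `log2(|a|) * (f(a) - mean containing frequency)`, i.e.
#' `log2(|a|) * (f(a) - nest_freq / nest_count)` where `nest_count` is the
#' number of distinct longer candidates containing a and `nest_freq` the sum
#' of their frequencies. Nesting is computed within the candidate set by
#' whole-token substring containment.
#'
#' @param candidates Data frame from [extract_candidates()] (`surface`,
#'   `length`, `freq`).
#' @return The candidates with `nest_freq`, `nest_count` and `cvalue`
#'   columns, sorted by descending C-value (ties: freq desc, surface asc).
#' @export
cvalue <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$nest_freq <- integer()
    candidates$nest_count <- integer()
    candidates$cvalue <- numeric()
    return(candidates)
  }
  stopifnot(all(candidates$length >= 2L), all(candidates$freq >= 1L))
  nest_freq <- integer(n)
  nest_count <- integer(n)
  padded <- paste0(" ", candidates$surface, " ")
  for (i in seq_len(n)) {
    longer <- which(candidates$length > candidates$length[i])
    if (length(longer) == 0L) next
    hit <- grepl(padded[i], padded[longer], fixed = TRUE)
    nest_count[i] <- sum(hit)
    nest_freq[i] <- sum(candidates$freq[longer][hit])
  }
  if (any(nest_count == 0L & nest_freq > 0L)) {
    stop("internal consistency error: nested frequency without nesting terms",
         call. = FALSE)
  }
  disc <- ifelse(nest_count > 0L, nest_freq / nest_count, 0)
  candidates$nest_freq <- nest_freq
  candidates$nest_count <- nest_count
  candidates$cvalue <- log2(candidates$length) * (candidates$freq - disc)
  ord <- order(-candidates$cvalue, -candidates$freq, candidates$surface)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a gazetteer extension from scored candidates
#'
#' Candidates at or above the C-value threshold, with stop-word-only
#' candidates removed, ready to merge into the biomedical-term gazetteer via
#' `load_lexicon(extra_terms = ...)`.
#'
#' @param scored Output of [cvalue()].
#' @param lex `epi_lexicon` for stop-word filtering.
#' @param threshold Minimum C-value for admission (the method itself fixes
#'   no threshold; 1.0 admits any non-fully-nested bigram seen twice).
#' @return Character vector of terms.
#' @export
cvalue_gazetteer <- function(scored, lex = load_lexicon(), threshold = 1.0) {
  filter_stopwords(scored$surface[scored$cvalue >= threshold], lex)
}

#' Write a scored term table
#'
#' TSV `surface<TAB>freq<TAB>cvalue` in score order.
#'
#' @param scored Output of [cvalue()].
#' @param path Output path.
#' @export
write_term_table <- function(scored, path) {
  utils::write.table(scored[, c("surface", "freq", "cvalue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
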