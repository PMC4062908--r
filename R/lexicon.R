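# Semantic-class dictionaries, document tagging, stop-word filtering and the
# human-study (species) gate.

#' Load the semantic-class dictionaries and gazetteers
#'
#' Reads one term file per semantic class from `dir` (UTF-8, one term per
#' line, `#` comments), plus the supporting resources expected alongside it:
#' `biomedical_terms.txt` (multi-word concept gazetteer feeding the
#' `MULTIPLE_TERM` tag), `stopwords.txt`, `functionwords.txt` and
#' `species.tsv` (`surface<TAB>human|non_human`). The shipped resource
#' directory reconstructs the fourteen original dictionaries from the
#' published rule examples; it is deliberately editable so users can extend
#' classes or plug in their own gazetteers (e.g. a UMLS export).
#'
#' @param dir Directory containing `dicts/` plus the supporting files.
#'   Defaults to the bundled reconstruction.
#' @param extra_terms Optional character vector of additional biomedical
#'   terms (e.g. output of [cvalue_gazetteer()]) merged into the gazetteer.
#' @return `epi_lexicon` object with elements `classes` (named list of
#'   character vectors), `biomedical_terms`, `stopwords`, `functionwords`,
#'   `species` (named vector `human`/`non_human` by surface form).
#' @export
load_lexicon <- function(dir = epi_resource(), extra_terms = NULL) {
  if (!dir.exists(dir)) stop("no such lexicon directory: ", dir, call. = FALSE)
  dict_dir <- file.path(dir, "dicts")
  if (!dir.exists(dict_dir)) stop("no 'dicts' directory under ", dir, call. = FALSE)
  files <- sort(list.files(dict_dir, pattern = "\\.txt$", full.names = TRUE))
  cls_names <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(cls_names)) stop("duplicate class file names", call. = FALSE)
  classes <- lapply(files, read_term_file)
  names(classes) <- cls_names
  for (nm in cls_names) {
    if (length(classes[[nm]]) == 0L) {
      warning("dictionary class '", nm, "' is empty", call. = FALSE)
    }
  }
  terms <- read_term_file(file.path(dir, "biomedical_terms.txt"))
  if (!is.null(extra_terms)) {
    terms <- sort(unique(c(terms, tolower(trimws(extra_terms)))))
  }
  species_raw <- utils::read.delim(file.path(dir, "species.tsv"), header = FALSE,
                                   comment.char = "#", stringsAsFactors = FALSE)
  species <- stats::setNames(trimws(species_raw[[2]]), tolower(trimws(species_raw[[1]])))
  structure(list(classes = classes,
                 biomedical_terms = terms,
                 stopwords = read_term_file(file.path(dir, "stopwords.txt")),
                 functionwords = read_term_file(file.path(dir, "functionwords.txt")),
                 species = species),
            class = "epi_lexicon")
}

read_term_file <- function(path) {
  if (!file.exists(path)) stop("missing lexicon file: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  sort(unique(tolower(x[nzchar(x)])))
}

#' @export
print.epi_lexicon <- function(x, ...) {
  cat("<epi_lexicon> ", length(x$classes), " semantic classes, ",
      length(x$biomedical_terms), " gazetteer terms, ",
      length(x$species), " species surface forms\n", sep = "")
  counts <- vapply(x$classes, length, integer(1))
  cat("  classes: ",
      paste(sprintf("%s(%d)", names(counts), counts), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# longest-first alternation regex over a term set with token-boundary guards
term_regex <- function(terms) {
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) return(NULL)
  terms <- terms[order(-nchar(terms), terms)]
  paste0("(?<![A-Za-z0-9])(?:", paste(rx_escape(terms), collapse = "|"),
         ")(?![A-Za-z0-9])")
}

scan_class <- function(text, terms, class_name) {
  rx <- term_regex(terms)
  empty <- data.frame(class_name = character(), start = integer(),
                      end = integer(), surface = character(),
                      stringsAsFactors = FALSE)
  if (is.null(rx)) return(empty)
  m <- gregexpr(rx, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  start <- as.integer(m) - 1L
  data.frame(class_name = class_name, start = start,
             end = start + attr(m, "match.length"),
             surface = regmatches(text, list(m))[[1]],
             stringsAsFactors = FALSE)
}

#' Tag a document with semantic classes
#'
#' Case-insensitive, token-boundary-respecting, leftmost-longest dictionary
#' matching per class; tags of different classes may overlap, tags of the
#' same class never nest. Beyond the dictionary classes, three derived
#' classes are emitted from token shape: `MULTIPLE_TERM` (biomedical-term
#' gazetteer hits), `STATS_NUMBER` (numeric tokens, thousands separators
#' kept) and `PERCENT` (a number immediately followed by `%`).
#'
#' @param doc `epi_document` (or a plain string, for ad-hoc use).
#' @param lex `epi_lexicon`.
#' @param text Override the tagged text (defaults to the abstract).
#' @return Data frame `class_name`, `start`, `end`, `surface` sorted by
#'   start; offsets 0-based half-open into `text`.
#' @export
tag_semantic_classes <- function(doc, lex, text = NULL) {
  if (is.null(text)) {
    text <- if (inherits(doc, "epi_document")) doc$abstract else as.character(doc)
  }
  parts <- lapply(names(lex$classes), function(nm) {
    scan_class(text, lex$classes[[nm]], nm)
  })
  parts <- c(parts, list(scan_class(text, lex$biomedical_terms, "MULTIPLE_TERM")))
  toks <- epi_tokenize(text)
  isnum <- grepl("^[0-9]", toks$text)
  if (any(isnum)) {
    parts <- c(parts, list(data.frame(class_name = "STATS_NUMBER",
                                      start = toks$start[isnum],
                                      end = toks$end[isnum],
                                      surface = toks$text[isnum],
                                      stringsAsFactors = FALSE)))
    # PERCENT: number token directly followed by '%'
    idx <- which(isnum[-length(isnum)] & toks$text[-1] == "%" &
                   toks$end[-length(isnum)] == toks$start[-1])
    if (length(idx)) {
      parts <- c(parts, list(data.frame(class_name = "PERCENT",
                                        start = toks$start[idx],
                                        end = toks$end[idx + 1L],
                                        surface = vapply(idx, function(i)
                                          slice(text, toks$start[i], toks$end[i + 1L]),
                                          character(1)),
                                        stringsAsFactors = FALSE)))
    }
  }
  tags <- do.call(rbind, parts)
  tags <- tags[order(tags$start, -tags$end, tags$class_name), , drop = FALSE]
  rownames(tags) <- NULL
  tags
}

#' Remove stop-word-only candidate terms
#'
#' A candidate is removed iff every one of its tokens is a stop word
#' (single-token stop-word candidates included).
#'
#' @param terms Character vector of candidate terms.
#' @param lex `epi_lexicon` providing the stop-word list.
#' @return The retained candidates.
#' @export
filter_stopwords <- function(terms, lex) {
  keep <- vapply(terms, function(tm) {
    toks <- strsplit(tolower(tm), "[^a-z0-9']+")[[1]]
    toks <- toks[nzchar(toks)]
    length(toks) > 0L && !all(toks %in% lex$stopwords)
  }, logical(1))
  unname(terms[keep])
}

#' Decide whether a document reports a human study
#'
#' Gazetteer-based species gate standing in for a full species tagger: the
#' document is rejected iff at least one non-human species mention is found
#' and no human-population cue (human(s), patient(s), men, women, children,
#' adults, participants, subjects, ...) is present. Evidence spans are
#' returned either way.
#'
#' @param doc `epi_document`.
#' @param lex `epi_lexicon`.
#' @return List with `human_study` (logical) and `evidence` (data frame of
#'   matched species spans with their kind).
#' @export
is_human_study <- function(doc, lex) {
  text <- paste(doc$title, doc$abstract, sep = " \n ")
  hits <- scan_class(text, names(lex$species), "species")
  kind <- unname(lex$species[tolower(hits$surface)])
  evidence <- data.frame(surface = hits$surface, kind = kind,
                         stringsAsFactors = FALSE)
  human <- !(any(kind == "non_human") && !any(kind == "human"))
  list(human_study = human, evidence = evidence)
}
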