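#' Read documents from a MEDLINE/PubMed XML citation set
#'
#' Parses a `PubmedArticleSet` file and returns one document per citation
#' that carries a non-empty abstract. Citations without an abstract are
#' skipped and counted, so corpus bookkeeping (e.g. "23,690 returned,
#' 19,188 processed") is reproducible. Structured abstracts with several
#' `AbstractText` sections are concatenated with single spaces in document
#' order; section labels already present in the text are retained.
#'
#' @param path Path to a PubmedArticleSet XML file.
#' @param drop_non_english Drop citations whose `<Language>` is present and
#'   not `eng` (the corpus query is restricted to English).
#' @return An object of class `epi_corpus`: a list with `documents` (list of
#'   `epi_document`), `n_skipped_no_abstract`, `n_skipped_language`.
#' @export
read_medline_xml <- function(path, drop_non_english = TRUE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  documents <- list()
  skipped_abstract <- 0L
  skipped_language <- 0L
  for (art in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle"))
    lang <- xml2::xml_find_first(art, ".//Language")
    lang <- if (inherits(lang, "xml_missing")) NA_character_ else xml2::xml_text(lang)
    secs <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    abstract <- paste(trimws(xml2::xml_text(secs)), collapse = " ")
    abstract <- trimws(abstract)
    if (!nzchar(abstract)) {
      skipped_abstract <- skipped_abstract + 1L
      next
    }
    if (drop_non_english && !is.na(lang) && tolower(lang) != "eng") {
      skipped_language <- skipped_language + 1L
      next
    }
    if (pmid %in% names(documents)) {
      warning("duplicate PMID ", pmid, ": last occurrence wins", call. = FALSE)
    }
    documents[[pmid]] <- epi_document(pmid, title = title %||% "",
                                      abstract = abstract, language = lang)
  }
  structure(list(documents = unname(documents),
                 n_skipped_no_abstract = skipped_abstract,
                 n_skipped_language = skipped_language),
            class = "epi_corpus")
}

#' Construct a document
#'
#' @param doc_id Citation identifier (PMID string).
#' @param abstract Abstract text; must be non-empty. Character offsets of all
#'   annotations are 0-based half-open code-point offsets into this string.
#' @param title Title text (kept outside the offset space).
#' @param language Optional ISO language code.
#' @return `epi_document` object.
#' @export
epi_document <- function(doc_id, abstract, title = "", language = NA_character_) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.character(abstract) || length(abstract) != 1L || !nzchar(abstract)) {
    stop("a document admitted to the pipeline must have non-empty abstract text",
         call. = FALSE)
  }
  structure(list(doc_id = doc_id, title = title, abstract = abstract,
                 language = language), class = "epi_document")
}

#' @export
print.epi_document <- function(x, ...) {
  cat("<epi_document> ", x$doc_id, "\n", sep = "")
  if (nzchar(x$title)) cat("  title:    ", x$title, "\n", sep = "")
  cat("  abstract: ", nchar(x$abstract), " chars\n", sep = "")
  invisible(x)
}

#' @export
print.epi_corpus <- function(x, ...) {
  cat("<epi_corpus> ", length(x$documents), " documents",
      " (skipped: ", x$n_skipped_no_abstract, " without abstract, ",
      x$n_skipped_language, " non-English)\n", sep = "")
  invisible(x)
}

#' Read plain-text abstracts from a directory
#'
#' One abstract per `<PMID>.txt` file, UTF-8.
#'
#' @param dir Directory containing `.txt` files.
#' @return `epi_corpus` object.
#' @export
read_plaintext <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  skipped <- 0L
  documents <- list()
  for (f in files) {
    text <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    text <- trimws(text)
    if (!nzchar(text)) { skipped <- skipped + 1L; next }
    id <- tools::file_path_sans_ext(basename(f))
    documents[[length(documents) + 1L]] <- epi_document(id, abstract = text)
  }
  structure(list(documents = documents, n_skipped_no_abstract = skipped,
                 n_skipped_language = 0L), class = "epi_corpus")
}

#' Read BRAT-style standoff gold annotations
#'
#' Lines of the form `T<n><TAB><Label> <start> <end><TAB><surface>` with
#' 0-based half-open character offsets into the document's abstract.
#' Annotations whose surface disagrees with the document slice are rejected.
#'
#' @param path `.ann` file path.
#' @param doc The `epi_document` the annotations refer to.
#' @return Data frame with columns `doc_id`, `characteristic`, `start`,
#'   `end`, `surface`.
#' @export
read_standoff <- function(path, doc) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(doc_id = character(), characteristic = character(),
                    start = integer(), end = integer(), surface = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "T")) next   # ignore non-text-bound annotations
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed standoff line ", i, ": ", ln, call. = FALSE)
    head <- strsplit(trimws(parts[2]), "[ ;]+")[[1]]
    label <- head[1]
    chr <- standoff_to_characteristic(label)
    if (is.na(chr)) stop("unknown characteristic label '", label, "' on line ", i, call. = FALSE)
    start <- suppressWarnings(as.integer(head[2]))
    end <- suppressWarnings(as.integer(head[length(head)]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start ||
        end > nchar(doc$abstract)) {
      stop("offset out of range on line ", i, ": ", ln, call. = FALSE)
    }
    surface <- parts[3]
    if (slice(doc$abstract, start, end) != surface) {
      stop("surface mismatch on line ", i, ": annotation text '", surface,
           "' != document slice '", slice(doc$abstract, start, end), "'",
           call. = FALSE)
    }
    out[nrow(out) + 1L, ] <- list(doc$doc_id, chr, start, end, surface)
  }
  out
}

#' Write gold/predicted annotations in BRAT standoff format
#'
#' @param ann Data frame with `characteristic`, `start`, `end`, `surface`.
#' @param path Output `.ann` path.
#' @export
write_standoff <- function(ann, path) {
  lines <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    lines[i] <- sprintf("T%d\t%s %d %d\t%s", i,
                        BRAT_LABELS[[ann$characteristic[i]]],
                        ann$start[i], ann$end[i], ann$surface[i])
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

standoff_to_characteristic <- function(label) {
  key <- gsub("[^a-z]", "", tolower(label))
  hit <- match(key, gsub("[^a-z]", "", tolower(BRAT_LABELS)))
  if (is.na(hit)) hit <- match(key, gsub("[^a-z]", "", CHARACTERISTICS))
  if (is.na(hit)) NA_character_ else CHARACTERISTICS[hit]
}

#' Write document profiles as JSON lines
#'
#' One JSON record per document with unified mentions per characteristic,
#' their offsets and semantic groups.
#'
#' @param profiles List of `epi_profile` objects (see [process_document()]).
#' @param path Output file.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in profiles) {
    rec <- list(doc_id = p$doc_id, human_study = p$human_study,
                skipped_reason = p$skipped_reason,
                mentions = lapply(p$mentions, function(df) {
                  lapply(seq_len(nrow(df)), function(i) {
                    list(start = df$start[i], end = df$end[i],
                         surface = df$surface[i], rule_id = df$rule_id[i],
                         semantic_group = df$semantic_group[i])
                  })
                }))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}

#' Read document profiles written by [write_profiles()]
#'
#' @param path JSON-lines profile file.
#' @return List of `epi_profile` objects.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    mentions <- lapply(CHARACTERISTICS, function(chr) {
      ms <- rec$mentions[[chr]]
      if (is.null(ms) || length(ms) == 0) return(empty_mention_df())
      as_mention_df(data.frame(
        doc_id = rec$doc_id, characteristic = chr,
        start = vapply(ms, function(m) as.integer(m$start), integer(1)),
        end = vapply(ms, function(m) as.integer(m$end), integer(1)),
        surface = vapply(ms, function(m) as.character(m$surface), character(1)),
        rule_id = vapply(ms, function(m) as.character(m$rule_id %||% NA_character_), character(1)),
        semantic_group = vapply(ms, function(m) as.character(m$semantic_group %||% NA_character_), character(1)),
        stringsAsFactors = FALSE))
    })
    names(mentions) <- CHARACTERISTICS
    structure(list(doc_id = rec$doc_id,
                   human_study = isTRUE(rec$human_study),
                   skipped_reason = rec$skipped_reason,
                   mentions = mentions),
              class = "epi_profile")
  })
}
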