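# Per-document orchestration of the four-stage method, document-level
# unification, semantic-group mapping and corpus summarisation.

#' Load all extraction resources
#'
#' Bundles the lexicon, compiled rules, macro table and the term-to-group
#' gazetteer into one object consumed by [process_document()].
#'
#' @param dir Resource directory (defaults to the bundled reconstruction).
#' @param extra_terms Additional biomedical terms for the gazetteer, e.g.
#'   from [cvalue_gazetteer()].
#' @param include_title Also run rules over the title (kept in a separate
#'   offset space; title mentions are flagged `in_title`). The original
#'   method is ambiguous on title handling, so it is a switch.
#' @return `epi_resources` object.
#' @export
load_resources <- function(dir = epi_resource(), extra_terms = NULL,
                           include_title = FALSE) {
  lex <- load_lexicon(dir, extra_terms = extra_terms)
  macros <- read_macros(file.path(dir, "macros.tsv"))
  rules <- read_rules(file.path(dir, "rules"), macros = macros)
  groups_raw <- utils::read.delim(file.path(dir, "semantic_groups.tsv"),
                                  header = FALSE, comment.char = "#",
                                  stringsAsFactors = FALSE)
  groups <- stats::setNames(trimws(groups_raw[[2]]),
                            tolower(trimws(groups_raw[[1]])))
  connectors <- c(",", "/", lex$classes[["multiple-cues"]] %||% c("and", "or"))
  structure(list(lexicon = lex, rules = rules, macros = macros,
                 groups = groups, connectors = connectors,
                 include_title = include_title),
            class = "epi_resources")
}

#' @export
print.epi_resources <- function(x, ...) {
  cat("<epi_resources>\n")
  print(x$lexicon)
  print(x$rules)
  cat("  semantic-group gazetteer: ", length(x$groups), " terms, ",
      length(unique(x$groups)), " groups\n", sep = "")
  invisible(x)
}

#' Unify candidate mentions at document level
#'
#' A mention strictly contained (span-wise) in another mention of the same
#' characteristic is discarded; exact duplicates collapse to one. The
#' result is an antichain under span containment.
#'
#' @param mentions Mention data frame sharing one `doc_id` and one
#'   `characteristic`.
#' @param characteristic Expected characteristic (contract check).
#' @return The surviving mentions, sorted by span.
#' @export
unify_mentions <- function(mentions, characteristic = NULL) {
  if (nrow(mentions) == 0L) return(mentions)
  if (length(unique(mentions$characteristic)) > 1L) {
    stop("unify_mentions called with mixed characteristics", call. = FALSE)
  }
  if (!is.null(characteristic) &&
      mentions$characteristic[1] != characteristic) {
    stop("mentions are '", mentions$characteristic[1], "', expected '",
         characteristic, "'", call. = FALSE)
  }
  if (length(unique(mentions$doc_id)) > 1L) {
    stop("unify_mentions called with mentions from several documents",
         call. = FALSE)
  }
  mentions <- mentions[!duplicated(paste(mentions$start, mentions$end)), ,
                       drop = FALSE]
  n <- nrow(mentions)
  contained <- vapply(seq_len(n), function(i) {
    any(mentions$start <= mentions$start[i] & mentions$end >= mentions$end[i] &
          (mentions$start < mentions$start[i] | mentions$end > mentions$end[i]))
  }, logical(1))
  out <- mentions[!contained, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a mention to a coarse semantic group
#'
#' The longest group-gazetteer entry contained (on token boundaries,
#' case-insensitive) in the mention surface decides the group; ties go to
#' the earlier-starting entry; no entry maps to the fallback `"Other"`.
#' Only exposures, outcomes and covariates carry groups.
#'
#' @param surface Mention surface string (or a mention data frame, in which
#'   case a `semantic_group` column is filled).
#' @param groups Named vector term -> group (lowercase terms).
#' @param characteristic Characteristic of the mention (contract check).
#' @return Group label, or the annotated data frame.
#' @export
map_semantic_group <- function(surface, groups, characteristic = "exposure") {
  if (is.data.frame(surface)) {
    df <- surface
    df$semantic_group <- vapply(seq_len(nrow(df)), function(i)
      map_semantic_group(df$surface[i], groups, df$characteristic[i]),
      character(1))
    return(df)
  }
  if (!characteristic %in% GROUPED_CHARACTERISTICS) {
    stop("semantic groups apply only to exposure/outcome/covariate mentions",
         call. = FALSE)
  }
  hits <- scan_class(surface, names(groups), "g")
  if (nrow(hits) == 0L) return("Other")
  best <- order(-(hits$end - hits$start), hits$start)[1]
  unname(groups[[tolower(hits$surface[best])]])
}

#' Run the full extraction pipeline on one document
#'
#' Species filter, semantic tagging, per-characteristic rule application,
#' document-level unification and semantic-group mapping, in that order.
#' Non-human documents yield an empty profile with
#' `skipped_reason = "non_human"`. Documents with no rule matches yield a
#' profile with empty mention lists, which is normal (the method finds a
#' study design in well under half of real abstracts).
#'
#' @param doc `epi_document`.
#' @param resources `epi_resources` from [load_resources()].
#' @return `epi_profile` object: `doc_id`, `human_study`, `skipped_reason`,
#'   and `mentions`, a list of unified mention data frames keyed by
#'   characteristic.
#' @export
process_document <- function(doc, resources) {
  empty <- stats::setNames(
    lapply(CHARACTERISTICS, function(chr) empty_mention_df()), CHARACTERISTICS)
  species <- is_human_study(doc, resources$lexicon)
  if (!species$human_study) {
    return(structure(list(doc_id = doc$doc_id, human_study = FALSE,
                          skipped_reason = "non_human", mentions = empty),
                     class = "epi_profile"))
  }
  mentions <- extract_from_text(doc, doc$abstract, resources)
  if (isTRUE(resources$include_title) && nzchar(doc$title)) {
    tm <- extract_from_text(doc, doc$title, resources)
    tm$in_title <- rep(TRUE, nrow(tm))
    mentions <- rbind(cbind(mentions, in_title = rep(FALSE, nrow(mentions))), tm)
  }
  per_chr <- lapply(CHARACTERISTICS, function(chr) {
    m <- mentions[mentions$characteristic == chr, , drop = FALSE]
    if (nrow(m) == 0L) return(empty_mention_df())
    if ("in_title" %in% names(m)) {
      # title and abstract live in separate offset spaces: unify separately
      parts <- lapply(split(m, m$in_title), unify_mentions,
                      characteristic = chr)
      m <- do.call(rbind, parts)
    } else {
      m <- unify_mentions(m, chr)
    }
    if (chr %in% GROUPED_CHARACTERISTICS) {
      m <- map_semantic_group(m, resources$groups)
    }
    as_mention_df(m)
  })
  names(per_chr) <- CHARACTERISTICS
  structure(list(doc_id = doc$doc_id, human_study = TRUE,
                 skipped_reason = NULL, mentions = per_chr),
            class = "epi_profile")
}

extract_from_text <- function(doc, text, resources) {
  tags <- tag_semantic_classes(doc, resources$lexicon, text = text)
  ctx <- prepare_match_ctx(doc, tags, text = text,
                           connectors = resources$connectors)
  apply_ruleset(resources$rules, doc, tags, macros = resources$macros,
                ctx = ctx)
}

#' @export
print.epi_profile <- function(x, ...) {
  cat("<epi_profile> ", x$doc_id,
      if (!x$human_study) paste0("  [skipped: ", x$skipped_reason, "]"), "\n",
      sep = "")
  for (chr in CHARACTERISTICS) {
    m <- x$mentions[[chr]]
    if (nrow(m) == 0L) next
    cat("  ", chr, ": ",
        paste(sprintf("\"%s\"", m$surface), collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Process a corpus of documents
#'
#' @param corpus `epi_corpus` or list of `epi_document`.
#' @param resources `epi_resources`.
#' @return List of `epi_profile`.
#' @export
process_corpus <- function(corpus, resources = load_resources()) {
  docs <- if (inherits(corpus, "epi_corpus")) corpus$documents else corpus
  lapply(docs, process_document, resources = resources)
}

#' Summarise extracted mentions over a corpus
#'
#' Per characteristic, frequency tables of case-folded unified mention
#' surfaces (mention occurrences, not unique documents) and, for exposures,
#' outcomes and covariates, of assigned semantic groups. Shares are
#' `100 * count / total` for that characteristic, rounded to one decimal.
#'
#' @param profiles List of `epi_profile`.
#' @return `epi_summary`: list with `mentions` and `groups`, each a list of
#'   data frames (`key`, `count`, `share`) keyed by characteristic, plus
#'   `totals`.
#' @export
summarize_corpus <- function(profiles) {
  mention_tab <- list()
  group_tab <- list()
  totals <- stats::setNames(integer(length(CHARACTERISTICS)), CHARACTERISTICS)
  for (chr in CHARACTERISTICS) {
    surfaces <- unlist(lapply(profiles, function(p)
      tolower(p$mentions[[chr]]$surface)), use.names = FALSE)
    totals[[chr]] <- length(surfaces)
    mention_tab[[chr]] <- frequency_table(surfaces)
    if (chr %in% GROUPED_CHARACTERISTICS) {
      grp <- unlist(lapply(profiles, function(p)
        p$mentions[[chr]]$semantic_group), use.names = FALSE)
      group_tab[[chr]] <- frequency_table(grp, case_fold = FALSE)
    }
  }
  structure(list(mentions = mention_tab, groups = group_tab, totals = totals),
            class = "epi_summary")
}

#' Tabulate counts and shares
#'
#' @param keys Character vector of observations (one per mention).
#' @param case_fold Lowercase keys before counting.
#' @return Data frame `key`, `count`, `share` sorted by descending count;
#'   `share = 100 * count / length(keys)` rounded to one decimal.
#' @export
frequency_table <- function(keys, case_fold = TRUE) {
  if (length(keys) == 0L) {
    return(data.frame(key = character(), count = integer(), share = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (case_fold) keys <- tolower(keys)
  tab <- table(keys)
  out <- data.frame(key = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$share <- round(100 * out$count / sum(out$count), 1)
  out <- out[order(-out$count, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.epi_summary <- function(x, top = 5L, ...) {
  cat("<epi_summary> mention totals:\n")
  for (chr in CHARACTERISTICS) {
    cat(sprintf("  %-12s %6d\n", chr, x$totals[[chr]]))
  }
  for (chr in CHARACTERISTICS) {
    tab <- x$mentions[[chr]]
    if (nrow(tab) == 0L) next
    cat("  top ", chr, ": ",
        paste(sprintf("%s (%d, %.1f%%)", utils::head(tab$key, top),
                      utils::head(tab$count, top), utils::head(tab$share, top)),
              collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Write per-characteristic frequency tables as TSV
#'
#' One `<characteristic>.tsv` (key, frequency, %) per characteristic plus
#' `<characteristic>_groups.tsv` for grouped characteristics, mirroring the
#' layout of published corpus summaries.
#'
#' @param summary `epi_summary`.
#' @param dir Output directory (created if needed).
#' @export
write_summary_tables <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (chr in names(summary$mentions)) {
    tab <- summary$mentions[[chr]]
    names(tab) <- c(chr, "frequency", "%")
    utils::write.table(tab, file.path(dir, paste0(chr, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (chr in names(summary$groups)) {
    tab <- summary$groups[[chr]]
    names(tab) <- c("semantic_group", "frequency", "%")
    utils::write.table(tab, file.path(dir, paste0(chr, "_groups.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
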