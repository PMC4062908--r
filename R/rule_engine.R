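# The annotation-grammar DSL: parsing rule files and matching compiled
# rules against semantically tagged documents.
#
# A rule is a whitespace-separated sequence of constituents:
#   a(class)     one semantic tag of a dictionary class
#   eq('word')   a frozen lexical anchor (case-insensitive token equality)
#   re('rx')     one token matching a whole-token regular expression
#   @name        a macro: a named sub-pattern from the macro config, or the
#                built-in @multiple (coordinated run of biomedical terms)
# A trailing '?' makes the preceding constituent optional. Exactly one
# contiguous bracketed range [ ... ] marks the capture: the emitted mention
# covers exactly the text consumed by the bracketed constituents.

RULE_TOKEN_RX <- paste0(
  "\\[|\\]|\\?",
  "|a\\(([A-Za-z0-9_-]+)\\)",
  "|eq\\([‘'’]([^‘'’]*)[‘'’]\\)",
  "|re\\([‘'’]([^‘'’]*)[‘'’]\\)",
  "|@([A-Za-z0-9_-]+)")

constituent <- function(kind, payload, optional = FALSE, captured = FALSE) {
  list(kind = kind, payload = payload, optional = optional, captured = captured)
}

#' Parse one extraction rule
#'
#' @param line Rule text, e.g.
#'   `"a(totals) re('(of|on|in)') [@stats a(clusters)]"`. Both straight and
#'   typographic quotes are accepted.
#' @param characteristic One of the six characteristic labels the rule
#'   extracts.
#' @param rule_id Identifier kept as mention provenance.
#' @param macros Macro table from [read_macros()]; used to validate macro
#'   references at parse time (`NULL` skips validation).
#' @return `epi_rule` object with `constituents` and the capture range.
#' @export
parse_rule <- function(line, characteristic, rule_id = "r1", macros = NULL) {
  characteristic <- match.arg(characteristic, CHARACTERISTICS)
  cons <- list()
  cap_open <- FALSE
  cap_ranges <- 0L
  cap_start <- NA_integer_
  cap_end <- NA_integer_
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(line, i, n)
    m <- regexpr(paste0("^(?:", RULE_TOKEN_RX, ")"), rest, perl = TRUE)
    if (m == -1) {
      stop("rule syntax error at column ", i, ": '", substr(rest, 1, 20), "'",
           call. = FALSE)
    }
    tok <- substr(rest, 1L, attr(m, "match.length"))
    i <- i + attr(m, "match.length")
    if (tok == "[") {
      if (cap_open) stop("nested capture bracket at column ", i, call. = FALSE)
      cap_open <- TRUE
      cap_start <- length(cons) + 1L
    } else if (tok == "]") {
      if (!cap_open) stop("unbalanced ']' at column ", i, call. = FALSE)
      cap_open <- FALSE
      cap_end <- length(cons)
      if (cap_end < cap_start) stop("empty capture range", call. = FALSE)
      cap_ranges <- cap_ranges + 1L
    } else if (tok == "?") {
      if (length(cons) == 0L) stop("'?' with no preceding constituent", call. = FALSE)
      cons[[length(cons)]]$optional <- TRUE
    } else if (startsWith(tok, "a(")) {
      cons[[length(cons) + 1L]] <- constituent("DICT_CLASS", gsub("^a\\(|\\)$", "", tok))
    } else if (startsWith(tok, "eq(")) {
      payload <- gsub("^eq\\([‘'’]|[‘'’]\\)$", "", tok)
      if (!nzchar(payload)) stop("empty eq() payload", call. = FALSE)
      con <- constituent("LITERAL", payload)
      con$words <- epi_tokenize(tolower(payload))$lower
      cons[[length(cons) + 1L]] <- con
    } else if (startsWith(tok, "re(")) {
      payload <- gsub("^re\\([‘'’]|[‘'’]\\)$", "", tok)
      ok <- tryCatch({ suppressWarnings(grepl(payload, "x", perl = TRUE)); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop("re() payload does not compile: ", payload, call. = FALSE)
      cons[[length(cons) + 1L]] <- constituent("REGEX", payload)
    } else if (startsWith(tok, "@")) {
      name <- sub("^@", "", tok)
      if (!is.null(macros) && name != "multiple" && is.null(macros[[name]])) {
        stop("unknown macro @", name, call. = FALSE)
      }
      cons[[length(cons) + 1L]] <- constituent("MACRO", name)
    }
  }
  if (cap_open) stop("unbalanced '[' (capture bracket never closed)", call. = FALSE)
  if (cap_ranges != 1L) {
    stop("a rule must contain exactly one capture range, found ", cap_ranges,
         call. = FALSE)
  }
  for (k in cap_start:cap_end) cons[[k]]$captured <- TRUE
  structure(list(rule_id = rule_id, characteristic = characteristic,
                 constituents = cons,
                 capture = c(cap_start, cap_end), source = line),
            class = "epi_rule")
}

#' @export
print.epi_rule <- function(x, ...) {
  cat("<epi_rule> ", x$rule_id, " [", x$characteristic, "]  ", x$source, "\n",
      sep = "")
  invisible(x)
}

#' Read the macro configuration
#'
#' TSV mapping macro name to a mini-pattern in the rule notation (without
#' capture brackets). The literal value `BUILTIN` marks `multiple`, whose
#' coordinated-term semantics cannot be expressed as a fixed sequence.
#'
#' @param path Macro file; defaults to the bundled one.
#' @return Named list: parsed constituent lists, or `"BUILTIN"`.
#' @export
read_macros <- function(path = epi_resource("macros.tsv")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  macros <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    name <- trimws(parts[1])
    body <- trimws(paste(parts[-1], collapse = " "))
    if (identical(body, "BUILTIN")) {
      macros[[name]] <- "BUILTIN"
      next
    }
    # parse with a synthetic capture to satisfy the rule grammar, then drop it
    parsed <- parse_rule(paste0("[", body, "]"), "exposure", rule_id = name)
    cons <- lapply(parsed$constituents, function(cc) { cc$captured <- FALSE; cc })
    for (cc in cons) {
      if (cc$kind == "MACRO") stop("macros may not reference macros: @", name,
                                   call. = FALSE)
    }
    macros[[name]] <- cons
  }
  macros
}

#' Read rule files for all characteristics
#'
#' One `<characteristic>.rules` file per characteristic, one rule per line
#' (`#` comments and blank lines ignored).
#'
#' @param dir Rules directory; defaults to the bundled reconstruction of
#'   the published example rules.
#' @param macros Macro table from [read_macros()].
#' @return `epi_ruleset`: list of `epi_rule`.
#' @export
read_rules <- function(dir = epi_resource("rules"), macros = read_macros()) {
  files <- list.files(dir, pattern = "\\.rules$", full.names = TRUE)
  if (length(files) == 0L) stop("no .rules files in ", dir, call. = FALSE)
  rules <- list()
  for (f in sort(files)) {
    chr <- tools::file_path_sans_ext(basename(f))
    chr <- match.arg(chr, CHARACTERISTICS)
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (k in seq_along(lines)) {
      rules[[length(rules) + 1L]] <-
        parse_rule(lines[k], chr, rule_id = sprintf("%s_%02d", chr, k),
                   macros = macros)
    }
  }
  structure(rules, class = "epi_ruleset")
}

#' @export
print.epi_ruleset <- function(x, ...) {
  chrs <- vapply(x, function(r) r$characteristic, character(1))
  cat("<epi_ruleset> ", length(x), " rules\n", sep = "")
  for (chr in unique(chrs)) {
    cat("  ", chr, ": ", sum(chrs == chr), "\n", sep = "")
  }
  invisible(x)
}

# ---- matching -------------------------------------------------------------

# Build the token/tag matching context for one text.
prepare_match_ctx <- function(doc, tags, text = NULL,
                              connectors = c(",", "/", "and", "or")) {
  if (is.null(text)) {
    text <- if (inherits(doc, "epi_document")) doc$abstract else as.character(doc)
  }
  toks <- epi_tokenize(text)
  # align tags to whole-token ranges; tags that cut through a token are unusable
  first <- match(tags$start, toks$start)
  last <- match(tags$end, toks$end)
  ok <- !is.na(first) & !is.na(last) & first <= last
  tag_tok <- data.frame(class_name = tags$class_name[ok],
                        first = first[ok], last = last[ok],
                        stringsAsFactors = FALSE)
  list(text = text, tokens = toks, tags = tag_tok,
       connectors = tolower(connectors))
}

# token lengths of tags of `class` starting at token `pos` (longest first)
tag_lengths_at <- function(ctx, class, pos, limit) {
  sel <- ctx$tags$class_name == class & ctx$tags$first == pos &
    ctx$tags$last <= limit
  if (!any(sel)) return(integer())
  sort(unique(ctx$tags$last[sel] - pos + 1L), decreasing = TRUE)
}

# all valid stopping lengths of the built-in @multiple at `pos`:
# TERM ( CONNECTOR{1,2} TERM | '(' TERM ')' )*
multiple_lengths <- function(ctx, pos, limit) {
  ends <- integer()
  seen <- integer()
  extend <- function(p) {
    if (p %in% seen) return()
    seen <<- c(seen, p)
    ends <<- c(ends, p)
    # coordinated continuation
    q <- p
    for (k in 1:2) {
      if (q > limit || !(ctx$tokens$lower[q] %in% ctx$connectors)) break
      q <- q + 1L
      for (len in tag_lengths_at(ctx, "MULTIPLE_TERM", q, limit)) {
        extend(q + len)
      }
    }
    # parenthesised continuation: ( TERM )
    if (p <= limit && ctx$tokens$text[p] == "(") {
      for (len in tag_lengths_at(ctx, "MULTIPLE_TERM", p + 1L, limit)) {
        q2 <- p + 1L + len
        if (q2 <= limit && ctx$tokens$text[q2] == ")") extend(q2 + 1L)
      }
    }
  }
  for (len in tag_lengths_at(ctx, "MULTIPLE_TERM", pos, limit)) {
    extend(pos + len)
  }
  sort(unique(ends - pos), decreasing = TRUE)
}

# possible token-consumption lengths of one constituent at `pos`
constituent_lengths <- function(con, ctx, pos, limit, macros) {
  if (pos > limit) return(integer())
  switch(con$kind,
    DICT_CLASS = tag_lengths_at(ctx, con$payload, pos, limit),
    LITERAL = {
      words <- con$words %||% epi_tokenize(tolower(con$payload))$lower
      k <- length(words)
      if (pos + k - 1L <= limit &&
          identical(ctx$tokens$lower[pos:(pos + k - 1L)], words)) k else integer()
    },
    REGEX = {
      if (grepl(paste0("^(?:", con$payload, ")$"), ctx$tokens$lower[pos],
                perl = TRUE, ignore.case = TRUE)) 1L else integer()
    },
    MACRO = {
      if (con$payload == "multiple") {
        multiple_lengths(ctx, pos, limit)
      } else {
        macro_lengths(macros[[con$payload]], ctx, pos, limit, macros)
      }
    },
    stop("unknown constituent kind ", con$kind))
}

# total consumption lengths of a macro body (sequence with optionals)
macro_lengths <- function(cons, ctx, pos, limit, macros) {
  if (is.null(cons)) stop("reference to undefined macro", call. = FALSE)
  frontier <- 0L
  for (con in cons) {
    nxt <- integer()
    for (off in frontier) {
      lens <- constituent_lengths(con, ctx, pos + off, limit, macros)
      if (con$optional) lens <- unique(c(lens, 0L))
      nxt <- c(nxt, off + lens)
    }
    frontier <- unique(nxt)
    if (length(frontier) == 0L) return(integer())
  }
  sort(unique(frontier), decreasing = TRUE)
}

# depth-first enumeration of full matches of a constituent ordering at `pos`.
# Returns a list of candidates: list(end, cap_lo, cap_hi) in token indices.
enumerate_matches <- function(cons, ctx, pos, limit, macros) {
  out <- list()
  dfs <- function(ci, p, cap_lo, cap_hi) {
    if (ci > length(cons)) {
      if (!is.na(cap_lo) && !is.na(cap_hi) && cap_hi > cap_lo) {
        out[[length(out) + 1L]] <<- list(end = p, cap_lo = cap_lo, cap_hi = cap_hi)
      }
      return(invisible())
    }
    con <- cons[[ci]]
    lens <- constituent_lengths(con, ctx, p, limit, macros)
    if (con$optional) lens <- unique(c(lens, 0L))
    for (len in lens) {
      lo <- cap_lo; hi <- cap_hi
      if (con$captured && len > 0L) {
        lo <- min(lo, p, na.rm = TRUE)
        hi <- max(hi, p + len, na.rm = TRUE)
      }
      dfs(ci + 1L, p + len, lo, hi)
    }
  }
  dfs(1L, pos, NA_integer_, NA_integer_)
  out
}

# orderings tried at each start position: the constituent order as written,
# then the other permutations of the capture block (the published rule table
# shows the capture-internal order is display-only, e.g. "[@st a(types)]"
# identifying "cross-sectional study")
capture_orderings <- function(rule) {
  n <- length(rule$constituents)
  lo <- rule$capture[1]; hi <- rule$capture[2]
  block <- lo:hi
  if (length(block) == 1L || length(block) > 4L) return(list(seq_len(n)))
  perms <- permutations(length(block))
  orders <- lapply(seq_len(nrow(perms)), function(i) {
    ord <- seq_len(n)
    ord[block] <- block[perms[i, ]]
    ord
  })
  # identity first
  ident <- vapply(orders, function(o) all(o == seq_len(n)), logical(1))
  c(orders[ident], orders[!ident])
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Match one rule against a tagged document
#'
#' The constituent sequence is matched over the token stream within
#' sentence boundaries. Per starting position the longest overall match
#' wins; matching restarts after each match end, so matches of one rule
#' never overlap. The returned mention covers exactly the text consumed by
#' the capture range.
#'
#' @param rule `epi_rule`.
#' @param doc `epi_document` (or plain string).
#' @param tags Tags from [tag_semantic_classes()] over the same text.
#' @param macros Macro table from [read_macros()].
#' @param ctx Prebuilt matching context (overrides `doc`/`tags`).
#' @return Mention data frame (`doc_id`, `characteristic`, `start`, `end`,
#'   `surface`, `rule_id`).
#' @export
match_rule <- function(rule, doc, tags, macros = read_macros(), ctx = NULL) {
  if (is.null(ctx)) ctx <- prepare_match_ctx(doc, tags)
  doc_id <- if (inherits(doc, "epi_document")) doc$doc_id else "doc"
  orderings <- capture_orderings(rule)
  toks <- ctx$tokens
  res <- list()
  if (nrow(toks) == 0L) {
    return(as_mention_df(NULL)[, 1:6])
  }
  for (sent in unique(toks$sentence)) {
    first <- match(sent, toks$sentence)
    limit <- max(which(toks$sentence == sent))
    pos <- first
    while (pos <= limit) {
      best <- NULL
      for (oi in seq_along(orderings)) {
        cons <- rule$constituents[orderings[[oi]]]
        for (cand in enumerate_matches(cons, ctx, pos, limit, macros)) {
          if (is.null(best) ||
              cand$end > best$end ||
              (cand$end == best$end &&
                 (cand$cap_hi - cand$cap_lo) > (best$cap_hi - best$cap_lo))) {
            best <- cand
          }
        }
      }
      if (is.null(best)) { pos <- pos + 1L; next }
      start <- toks$start[best$cap_lo]
      end <- toks$end[best$cap_hi - 1L]
      res[[length(res) + 1L]] <- data.frame(
        doc_id = doc_id, characteristic = rule$characteristic,
        start = start, end = end,
        surface = slice(ctx$text, start, end),
        rule_id = rule$rule_id, stringsAsFactors = FALSE)
      pos <- max(best$end, pos + 1L)
    }
  }
  if (length(res) == 0L) {
    return(as_mention_df(NULL)[, 1:6])
  }
  do.call(rbind, res)
}

#' Apply a ruleset to a tagged document
#'
#' Union of per-rule matches. Captured covariate lists are split into one
#' mention per conjunct (the published examples bold each conjunct
#' separately). Duplicate spans within a characteristic are collapsed,
#' keeping the first rule id and recording all contributing rules.
#'
#' @inheritParams match_rule
#' @param rules `epi_ruleset` or list of `epi_rule`.
#' @return Mention data frame with `all_rule_ids` provenance column.
#' @export
apply_ruleset <- function(rules, doc, tags, macros = read_macros(), ctx = NULL) {
  if (is.null(ctx)) ctx <- prepare_match_ctx(doc, tags)
  parts <- lapply(rules, function(r) match_rule(r, doc, tags, macros, ctx = ctx))
  m <- do.call(rbind, parts)
  if (is.null(m) || nrow(m) == 0L) return(as_mention_df(NULL))
  m <- split_covariate_conjuncts(m, ctx$text)
  key <- paste(m$characteristic, m$start, m$end)
  m$all_rule_ids <- vapply(key, function(k)
    paste(unique(m$rule_id[key == k]), collapse = ","),
    character(1), USE.NAMES = FALSE)
  m <- m[!duplicated(key), , drop = FALSE]
  m <- m[order(m$characteristic, m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  as_mention_df(m)
}

# split a captured coordinated covariate list into per-conjunct mentions
split_covariate_conjuncts <- function(m, text) {
  out <- list()
  for (i in seq_len(nrow(m))) {
    row <- m[i, , drop = FALSE]
    if (row$characteristic != "covariate") { out[[length(out) + 1L]] <- row; next }
    pieces <- split_span(row$surface, row$start)
    for (p in pieces) {
      r2 <- row
      r2$start <- p$start; r2$end <- p$end
      r2$surface <- slice(text, p$start, p$end)
      out[[length(out) + 1L]] <- r2
    }
  }
  do.call(rbind, out)
}

# split "a, b, and c" into trimmed sub-spans with absolute offsets
split_span <- function(surface, start) {
  seps <- gregexpr(",\\s+and\\s+|,\\s*|\\s+and\\s+", surface, perl = TRUE)[[1]]
  bounds <- c(0L)
  if (seps[1] != -1) {
    for (k in seq_along(seps)) {
      bounds <- c(bounds, as.integer(seps[k]) - 1L,
                  as.integer(seps[k]) - 1L + attr(seps, "match.length")[k])
    }
  }
  bounds <- c(bounds, nchar(surface))
  pieces <- list()
  for (k in seq(1L, length(bounds), by = 2L)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    piece <- substr(surface, lo + 1L, hi)
    # trim whitespace, keeping offsets honest
    lead <- attr(regexpr("^\\s*", piece), "match.length")
    trail <- attr(regexpr("\\s*$", piece), "match.length")
    lo <- lo + lead; hi <- hi - trail
    if (hi > lo) pieces[[length(pieces) + 1L]] <- list(start = start + lo,
                                                       end = start + hi)
  }
  pieces
}
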