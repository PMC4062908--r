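test_that("rule parsing recovers constituent kinds, payloads and capture ranges", {
  r1 <- parse_rule("[@st a(types)]", "study_design")
  expect_length(r1$constituents, 2)
  expect_equal(vapply(r1$constituents, `[[`, character(1), "kind"),
               c("MACRO", "DICT_CLASS"))
  expect_equal(r1$capture, c(1, 2))

  r2 <- parse_rule("a(totals) re('(of|on|in)') [@stats a(clusters)]",
                   "population")
  expect_length(r2$constituents, 4)
  expect_equal(vapply(r2$constituents, `[[`, character(1), "kind"),
               c("DICT_CLASS", "REGEX", "MACRO", "DICT_CLASS"))
  expect_equal(vapply(r2$constituents, `[[`, character(1), "payload"),
               c("totals", "(of|on|in)", "stats", "clusters"))
  expect_equal(r2$capture, c(3, 4))

  # typographic quotes as printed are accepted too
  r3 <- parse_rule("a(totals) re(‘(of|on|in)’) [@stats a(clusters)]",
                   "population")
  expect_equal(r3$constituents[[2]]$payload, "(of|on|in)")

  # '?' marks the preceding constituent optional
  r4 <- parse_rule("[@multiple] a(be) a(related) a(with) eq('onset')? eq('of')?",
                   "exposure")
  expect_equal(vapply(r4$constituents, `[[`, logical(1), "optional"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("malformed rules are rejected with informative errors", {
  expect_error(parse_rule("a(types", "study_design"), "syntax error")
  expect_error(parse_rule("a(types)", "study_design"), "exactly one capture")
  expect_error(parse_rule("[a(types)] [@st]", "study_design"),
               "exactly one capture")
  expect_error(parse_rule("[a(types)", "study_design"), "unbalanced")
  expect_error(parse_rule("[@st a(types)] @nosuchmacro", "study_design",
                          macros = read_macros()), "unknown macro")
  expect_error(parse_rule("[re('(unclosed')]", "study_design"),
               "does not compile")
})

test_that("matching consumes tags, literals and regexes within one sentence", {
  lex <- RES$lexicon
  rule <- parse_rule("a(totals) re('(of|on|in)') [@stats a(clusters)]",
                     "population", macros = RES$macros)
  doc <- epi_document("d1",
    "Sibling study in a prospective cohort of 208,866 men from five countries.")
  m <- match_rule(rule, doc, tag_semantic_classes(doc, lex), RES$macros)
  expect_equal(m$surface, "208,866 men")
  expect_equal(substr(doc$abstract, m$start + 1, m$end), m$surface)

  # no match across the sentence boundary
  doc2 <- epi_document("d2", "Data came from a cohort of. 214 men enrolled.")
  expect_equal(nrow(match_rule(rule, doc2, tag_semantic_classes(doc2, lex),
                               RES$macros)), 0)
})

test_that("coordinated term runs back off so later anchors can match", {
  lex <- RES$lexicon
  rule <- parse_rule("a(relations) eq('between') [@multiple] eq('and') @multiple",
                     "exposure", macros = RES$macros)
  doc <- epi_document("d3",
    "We assessed the association between body mass index and blood pressure.")
  m <- match_rule(rule, doc, tag_semantic_classes(doc, lex), RES$macros)
  expect_equal(m$surface, "body mass index")
})

test_that("rule application unions rules, splits covariate lists, dedupes spans", {
  lex <- RES$lexicon
  doc <- epi_document("d4", paste(
    "Models were adjusted for age, smoking status, and clinical history of",
    "diabetes mellitus. Hernia prevalence was 32.4% in this series."))
  tags <- tag_semantic_classes(doc, lex)
  m <- apply_ruleset(RES$rules, doc, tags, RES$macros)
  cov <- m[m$characteristic == "covariate", ]
  expect_equal(cov$surface,
               c("age", "smoking status", "clinical history of diabetes mellitus"))
  es <- m[m$characteristic == "effect_size", ]
  expect_equal(es$surface, "prevalence was 32.4%")
  # every mention slices back to its surface, and stays in its rule's class
  expect_equal(substr(rep(doc$abstract, nrow(m)), m$start + 1, m$end), m$surface)
  expect_true(all(m$characteristic %in% c("covariate", "effect_size")))
})

test_that("matching is deterministic", {
  lex <- RES$lexicon
  sim <- generate_corpus(4, seed = 23)
  for (doc in sim$documents) {
    tags <- tag_semantic_classes(doc, lex)
    a <- apply_ruleset(RES$rules, doc, tags, RES$macros)
    b <- apply_ruleset(RES$rules, doc, tags, RES$macros)
    expect_identical(a, b)
  }
})

test_that("match agrees with a brute-force enumeration oracle on random cases", {
  set.seed(202)
  classes <- c("ca", "cb", "cc")
  words <- c("w1", "w2", "w3", "w4")
  for (case in 1:60) {
    n_tok <- sample(4:15, 1)
    tok_class <- sample(c(classes, NA, NA), n_tok, replace = TRUE)
    tokens <- ifelse(is.na(tok_class), sample(words, n_tok, replace = TRUE),
                     paste0("t", match(tok_class, classes)))
    text <- paste(tokens, collapse = " ")
    tags <- do.call(rbind, lapply(which(!is.na(tok_class)), function(i) {
      start <- if (i == 1) 0L else nchar(paste(tokens[1:(i - 1)], collapse = " ")) + 1L
      data.frame(class_name = tok_class[i], start = start,
                 end = start + nchar(tokens[i]), surface = tokens[i],
                 stringsAsFactors = FALSE)
    }))
    n_con <- sample(2:4, 1)
    make_con <- function() {
      kind <- sample(c("class", "lit", "re"), 1)
      switch(kind,
        class = paste0("a(", sample(classes, 1), ")"),
        lit = paste0("eq('", sample(c(words, paste0("t", 1:3)), 1), "')"),
        re = "re('w[12]|t1')")
    }
    parts <- replicate(n_con, paste0(make_con(),
                                     if (runif(1) < 0.3) "?" else ""))
    cap <- sort(sample(n_con, 2, replace = TRUE))
    parts[cap[1]] <- paste0("[", parts[cap[1]])
    parts[cap[2]] <- paste0(parts[cap[2]], "]")
    rule <- parse_rule(paste(parts, collapse = " "), "exposure")
    got <- match_rule(rule, text, tags)
    want <- oracle_match_rule(rule$constituents, rule$capture, tokens,
                              tok_class)
    # compare captured token index ranges
    tok_starts <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
    tok_ends <- tok_starts + nchar(tokens)
    got_tok <- lapply(seq_len(nrow(got)), function(i) {
      c(which(tok_starts == got$start[i]), which(tok_ends == got$end[i]) + 1L)
    })
    expect_equal(got_tok, want, info = paste("rule:", rule$source,
                                             "text:", text))
  }
})
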