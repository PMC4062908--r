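test_that("the bundled lexicon loads fourteen semantic classes", {
  lex <- RES$lexicon
  expect_length(lex$classes, 14)
  expect_true(all(c("types", "totals", "clusters", "relations", "be",
                    "related", "with", "adj", "preva", "adverbs", "synonyms",
                    "factors", "study-cues", "multiple-cues")
                  %in% names(lex$classes)))
  expect_true(all(vapply(lex$classes, function(x) all(nzchar(x)), logical(1))))
})

test_that("loading reports missing directories and empty classes", {
  expect_error(load_lexicon(file.path(tempdir(), "nowhere")), "no such")
  dir <- file.path(tempdir(), "minilex")
  dir.create(file.path(dir, "dicts"), recursive = TRUE, showWarnings = FALSE)
  writeLines(c("alpha", "alpha", "beta"), file.path(dir, "dicts", "c1.txt"))
  writeLines(character(), file.path(dir, "dicts", "c2.txt"))
  for (f in c("biomedical_terms.txt", "stopwords.txt", "functionwords.txt"))
    writeLines("placeholder", file.path(dir, f))
  writeLines("human\thuman", file.path(dir, "species.tsv"))
  expect_warning(lex <- load_lexicon(dir), "empty")
  expect_equal(lex$classes$c1, c("alpha", "beta"))  # duplicates collapsed
  expect_length(lex$classes$c2, 0)
})

test_that("semantic tagging finds dictionary classes and number shapes", {
  lex <- RES$lexicon
  tags <- tag_semantic_classes(
    epi_document("t", "This was a cross-sectional study of 214 patients."), lex)
  expect_true(any(tags$class_name == "types" & tags$surface == "cross-sectional"))
  expect_true(any(tags$class_name == "study-cues" & tags$surface == "study"))

  tags2 <- tag_semantic_classes(
    epi_document("t", "Sibling study in a cohort of 208,866 men."), lex)
  expect_true(any(tags2$class_name == "STATS_NUMBER" & tags2$surface == "208,866"))
  expect_true(any(tags2$class_name == "clusters" & tags2$surface == "men"))

  none <- tag_semantic_classes(
    epi_document("t", "Zzz qqq www unrelated tokens only."), lex)
  expect_false(any(none$class_name %in% c("types", "MULTIPLE_TERM")))
})

test_that("tagging is idempotent, offsets slice exactly, same class never nests", {
  lex <- RES$lexicon
  sim <- generate_corpus(5, seed = 11)
  for (doc in sim$documents) {
    tags <- tag_semantic_classes(doc, lex)
    again <- tag_semantic_classes(doc, lex)
    expect_identical(tags, again)
    expect_equal(substr(rep(doc$abstract, nrow(tags)), tags$start + 1, tags$end),
                 tags$surface)
    for (cls in unique(tags$class_name)) {
      tt <- tags[tags$class_name == cls, , drop = FALSE]
      tt <- tt[order(tt$start), , drop = FALSE]
      if (nrow(tt) > 1) {
        expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
      }
    }
  }
})

test_that("stop-word filtering removes candidates made only of stop words", {
  lex <- RES$lexicon
  expect_equal(filter_stopwords(c("of the", "body mass index"), lex),
               "body mass index")
  expect_equal(filter_stopwords(character(), lex), character())

  # oracle: direct per-candidate set comprehension with the same rule
  set.seed(42)
  pool <- c(lex$stopwords[1:20], "obesity", "cohort", "mellitus", "bias")
  cands <- replicate(100, paste(sample(pool, sample(1:3, 1)), collapse = " "))
  oracle <- cands[vapply(cands, function(x) {
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    !all(toks %in% lex$stopwords)
  }, logical(1))]
  expect_equal(sort(unique(filter_stopwords(cands, lex))), sort(unique(oracle)))
})

test_that("the species gate keeps human studies and flags non-human ones", {
  lex <- RES$lexicon
  mouse <- epi_document("m", "Weight gain was studied in diet-induced obese mice.")
  expect_false(is_human_study(mouse, lex)$human_study)
  expect_true(any(is_human_study(mouse, lex)$evidence$kind == "non_human"))

  people <- epi_document("p", "We recruited 214 overweight/obese patients.")
  expect_true(is_human_study(people, lex)$human_study)

  mixed <- epi_document("x", "Findings in humans and in mouse models agree.")
  expect_true(is_human_study(mixed, lex)$human_study)
})
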