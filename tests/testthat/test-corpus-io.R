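test_that("MEDLINE XML reading keeps only citations with abstracts and counts skips", {
  path <- write_medline_fixture(list(
    "101" = "A first synthetic abstract about adults.",
    "102" = NULL,
    "103" = "A second synthetic abstract about women."))
  corpus <- read_medline_xml(path)
  expect_length(corpus$documents, 2)
  expect_equal(corpus$n_skipped_no_abstract, 1)
  expect_equal(vapply(corpus$documents, `[[`, character(1), "doc_id"),
               c("101", "103"))

  empty <- read_medline_xml(write_medline_fixture(list()))
  expect_length(empty$documents, 0)
  expect_equal(empty$n_skipped_no_abstract, 0)
})

test_that("structured abstracts concatenate sections with single spaces", {
  secs <- c("BACKGROUND: Obesity is common.",
            "METHODS: We measured waist circumference in adults.",
            "RESULTS: Prevalence differed by region.")
  path <- write_medline_fixture(list("201" = secs))
  corpus <- read_medline_xml(path)
  # oracle: manual concatenation of the fixture's sections
  expect_equal(corpus$documents[[1]]$abstract, paste(secs, collapse = " "))
})

test_that("non-English citations are dropped when a language field is present", {
  path <- write_medline_fixture(
    list("301" = "Un résumé synthétique.", "302" = "An English abstract."),
    languages = list("301" = "fre", "302" = "eng"))
  corpus <- read_medline_xml(path)
  expect_equal(corpus$documents[[1]]$doc_id, "302")
  expect_equal(corpus$n_skipped_language, 1)
})

test_that("malformed XML raises a parse error and empty abstracts are refused", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><PubmedArticle>", bad)
  expect_error(read_medline_xml(bad), "malformed XML")
  expect_error(epi_document("x", ""), "non-empty abstract")
})

test_that("standoff parsing checks offsets and surfaces", {
  doc <- epi_document("41", "We studied the impact of body mass index on outcomes.")
  start <- regexpr("body mass index", doc$abstract, fixed = TRUE) - 1L
  end <- start + nchar("body mass index")
  ann <- tempfile(fileext = ".ann")
  writeLines(sprintf("T1\tExposure %d %d\tbody mass index", start, end), ann)
  got <- read_standoff(ann, doc)
  expect_equal(got$characteristic, "exposure")
  expect_equal(got$surface, "body mass index")
  expect_equal(substr(doc$abstract, got$start + 1, got$end), got$surface)

  writeLines(sprintf("T1\tExposure %d %d\tsomething else!", start, end), ann)
  expect_error(read_standoff(ann, doc), "surface mismatch")
  writeLines(sprintf("T1\tExposure %d 999\tbody mass index", start), ann)
  expect_error(read_standoff(ann, doc), "offset out of range")
  writeLines(sprintf("T1\tWeather %d %d\tbody mass index", start, end), ann)
  expect_error(read_standoff(ann, doc), "unknown characteristic")
})

test_that("standoff write/read round-trips random annotation sets", {
  set.seed(7)
  doc <- epi_document("51", paste(rep("some abstract text with words", 12),
                                  collapse = " "))
  ann <- random_annotations(doc, 50)
  path <- tempfile(fileext = ".ann")
  write_standoff(ann, path)
  back <- read_standoff(path, doc)
  expect_equal(back, ann, ignore_attr = TRUE)
})

test_that("profile JSONL round-trips through write_profiles/read_profiles", {
  res <- RES
  doc <- epi_document("61",
    "The aim was to analyze the association between obesity and asthma in this sample.")
  profiles <- list(process_document(doc, res))
  expect_equal(nrow(profiles[[1]]$mentions$exposure), 1)
  path <- tempfile(fileext = ".jsonl")
  write_profiles(profiles, path)
  back <- read_profiles(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$doc_id, "61")
  expect_equal(back[[1]]$mentions$exposure$surface,
               profiles[[1]]$mentions$exposure$surface)
  expect_equal(back[[1]]$mentions$exposure$start,
               profiles[[1]]$mentions$exposure$start)
  expect_equal(back[[1]]$mentions$exposure$semantic_group, "Disorders")

  empty_path <- tempfile(fileext = ".jsonl")
  write_profiles(list(), empty_path)
  expect_length(read_profiles(empty_path), 0)
})
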