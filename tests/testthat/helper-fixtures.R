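# Shared fixtures built in code.

# bundled resources, loaded once per test run
RES <- load_resources()

# the classic nested-term corpus: 2 x "soft contact lens", 4 x "contact lens"
contact_lens_corpus <- function() {
  c(rep("soft contact lens", 2), rep("contact lens", 4))
}

# write a minimal PubmedArticleSet file; `abstracts` is a named list
# PMID -> character vector of AbstractText sections (NULL = no abstract)
write_medline_fixture <- function(abstracts, path = tempfile(fileext = ".xml"),
                                  languages = NULL) {
  arts <- vapply(names(abstracts), function(pmid) {
    secs <- abstracts[[pmid]]
    abstract <- if (is.null(secs)) "" else paste0(
      "<Abstract>",
      paste0("<AbstractText>", secs, "</AbstractText>", collapse = ""),
      "</Abstract>")
    lang <- if (!is.null(languages[[pmid]]))
      paste0("<Language>", languages[[pmid]], "</Language>") else ""
    paste0("<PubmedArticle><MedlineCitation><PMID>", pmid, "</PMID>",
           "<Article>", lang,
           "<ArticleTitle>Title ", pmid, "</ArticleTitle>",
           abstract, "</Article></MedlineCitation></PubmedArticle>")
  }, character(1))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<PubmedArticleSet>", arts, "</PubmedArticleSet>"), path)
  path
}

# random annotation set over a synthetic document, for round-trip tests
random_annotations <- function(doc, n) {
  len <- nchar(doc$abstract)
  starts <- sample.int(len - 2L, n, replace = TRUE) - 1L
  ends <- pmin(starts + sample.int(12L, n, replace = TRUE), len)
  data.frame(doc_id = doc$doc_id,
             characteristic = sample(c("study_design", "population",
                                       "exposure", "outcome", "covariate",
                                       "effect_size"), n, replace = TRUE),
             start = starts, end = ends,
             surface = vapply(seq_len(n), function(i)
               substr(doc$abstract, starts[i] + 1L, ends[i]), character(1)),
             stringsAsFactors = FALSE)
}
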