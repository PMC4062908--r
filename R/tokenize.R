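# Tokenisation and sentence segmentation shared by the tagger, the rule
# matcher and the term recogniser.
#
# Token classes:
#   - numbers, keeping internal thousands separators and decimal points
#     ("208,866", "32.4") as one token;
#   - words: letters followed by letters/digits/apostrophes; hyphen and
#     slash are token boundaries ("overweight/obese" -> 3 tokens);
#   - any other non-space character as a single-character token.
TOKEN_RX <- "[0-9]+(?:[.,][0-9]+)*|[A-Za-z][A-Za-z0-9']*|[^A-Za-z0-9[:space:]]"

# words after which a period is not a sentence boundary
ABBREV_GUARD <- c("vs", "e.g", "i.e", "et al", "al", "dr", "fig", "ca",
                  "approx", "no", "cf")

epi_tokenize <- function(text) {
  if (!nzchar(text)) {
    return(data.frame(start = integer(), end = integer(),
                      text = character(), lower = character(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr(TOKEN_RX, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer(),
                      text = character(), lower = character(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  txt <- regmatches(text, list(m))[[1]]
  sent_ends <- sentence_ends(text)
  sentence <- findInterval(start, sent_ends) + 1L
  data.frame(start = start, end = end, text = txt,
             lower = tolower(txt), sentence = as.integer(sentence),
             stringsAsFactors = FALSE)
}

# 0-based offsets one past each sentence-final punctuation mark
sentence_ends <- function(text) {
  m <- gregexpr("[.?!]+(?=\\s)", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  ends <- integer()
  for (i in seq_along(m)) {
    pos <- as.integer(m[i])                       # 1-based position of mark
    before <- substr(text, max(1L, pos - 12L), pos - 1L)
    word <- tolower(sub(".*?([A-Za-z][A-Za-z.]*)$", "\\1", before))
    if (word %in% ABBREV_GUARD) next
    # single capital initial ("J. Smith")
    if (grepl("(^|[^A-Za-z])[A-Z]$", substr(text, max(1L, pos - 2L), pos - 1L))) next
    ends <- c(ends, pos - 1L + attr(m, "match.length")[i])
  }
  ends
}
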