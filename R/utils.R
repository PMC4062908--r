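`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open slice of a string
slice <- function(text, start, end) substr(text, start + 1L, end)

rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

empty_mention_df <- function() {
  data.frame(doc_id = character(), characteristic = character(),
             start = integer(), end = integer(), surface = character(),
             rule_id = character(), all_rule_ids = character(),
             semantic_group = character(), stringsAsFactors = FALSE)
}

as_mention_df <- function(df) {
  out <- empty_mention_df()
  if (is.null(df) || nrow(df) == 0) return(out)
  for (col in names(out)) {
    if (is.null(df[[col]])) {
      df[[col]] <- if (col %in% c("start", "end")) NA_integer_ else NA_character_
    }
  }
  keep <- c(names(out), intersect("in_title", names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Locate a bundled resource directory or file
#'
#' The package ships reconstructed dictionaries, gazetteers, macro
#' definitions and rule files under `inst/extdata`.
#'
#' @param ... path components below `extdata`.
#' @return Absolute path.
#' @export
epi_resource <- function(...) {
  p <- system.file("extdata", ..., package = "epimine")
  if (!nzchar(p)) stop("resource not found: ", file.path(...), call. = FALSE)
  p
}
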