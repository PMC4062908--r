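# Span-level scoring of predicted mentions against gold standoff
# annotations: TP/FP/FN tallies, precision/recall/F-score, micro and macro
# aggregation, and absolute inter-annotator agreement.

#' Count true/false positives and false negatives for one document
#'
#' Predictions and gold annotations are matched one-to-one (maximum
#' bipartite matching, processed in span-start order so results are
#' deterministic). In `strict` mode a prediction matches a gold annotation of
#' the same characteristic with the identical span; in `relaxed` mode any
#' overlapping span of the same characteristic matches. Both sides are
#' deduplicated on (characteristic, span) first, consistent with
#' document-level unification.
#'
#' @param pred Mention data frame (unified predictions for one document).
#' @param gold Gold annotation data frame for the same document.
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @return Data frame with one row per characteristic: `characteristic`,
#'   `tp`, `fp`, `fn`.
#' @export
match_spans <- function(pred, gold, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  pids <- unique(c(pred$doc_id, gold$doc_id))
  pids <- pids[!is.na(pids)]
  if (length(pids) > 1L) {
    stop("match_spans compares one document at a time; got doc_ids: ",
         paste(pids, collapse = ", "), call. = FALSE)
  }
  dedup <- function(df) df[!duplicated(paste(df$characteristic, df$start,
                                             df$end)), , drop = FALSE]
  pred <- dedup(pred)
  gold <- dedup(gold)
  out <- data.frame(characteristic = CHARACTERISTICS, tp = 0L, fp = 0L,
                    fn = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(CHARACTERISTICS)) {
    chr <- CHARACTERISTICS[k]
    p <- pred[pred$characteristic == chr, , drop = FALSE]
    g <- gold[gold$characteristic == chr, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    # maximum one-to-one matching (augmenting paths, span-start order);
    # in strict mode this coincides with greedy pairing of identical spans
    compatible <- function(i, j) {
      if (mode == "strict") {
        p$start[i] == g$start[j] && p$end[i] == g$end[j]
      } else {
        g$start[j] < p$end[i] && g$end[j] > p$start[i]
      }
    }
    match_of_gold <- rep(NA_integer_, nrow(g))
    for (i in seq_len(nrow(p))) {
      visited <- rep(FALSE, nrow(g))
      try_assign <- function(i) {
        for (j in seq_len(nrow(g))) {
          if (visited[j] || !compatible(i, j)) next
          visited[j] <<- TRUE
          if (is.na(match_of_gold[j]) || try_assign(match_of_gold[j])) {
            match_of_gold[j] <<- i
            return(TRUE)
          }
        }
        FALSE
      }
      try_assign(i)
    }
    tp <- sum(!is.na(match_of_gold))
    out$tp[k] <- tp
    out$fp[k] <- nrow(p) - tp
    out$fn[k] <- nrow(g) - tp
  }
  out
}

#' Precision, recall and F-score from TP/FP/FN counts
#'
#' `P = 100 tp / (tp + fp)`, `R = 100 tp / (tp + fn)`,
#' `F = 2PR / (P + R)` (harmonic mean), all on the percentage scale at full
#' precision. When a denominator is zero the metrics are undefined and
#' `defined` is `FALSE`.
#'
#' @param tp,fp,fn Counts, or a data frame with those columns as `tp`.
#' @return List `precision`, `recall`, `f_score`, `defined`.
#' @export
compute_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    fp <- sum(tp$fp); fn <- sum(tp$fn); tp <- sum(tp$tp)
  }
  if (tp + fp == 0L || tp + fn == 0L) {
    return(list(precision = NA_real_, recall = NA_real_, f_score = NA_real_,
                defined = FALSE))
  }
  p <- 100 * tp / (tp + fp)
  r <- 100 * tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f_score = f, defined = TRUE)
}

#' Aggregate per-class counts into micro or macro metrics
#'
#' Micro averaging pools TP/FP/FN over classes before computing metrics;
#' macro averaging is the unweighted mean of per-class precision, recall
#' and F-score over the classes whose metrics are defined (classes with
#' zero denominators are excluded, not scored 0 or 100).
#'
#' @param counts Data frame with `tp`, `fp`, `fn` rows per class.
#' @param mode `"micro"` or `"macro"`.
#' @return List `precision`, `recall`, `f_score`, `defined`.
#' @export
aggregate_metrics <- function(counts, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (nrow(counts) == 0L) stop("no per-class counts to aggregate", call. = FALSE)
  if (mode == "micro") {
    return(compute_metrics(sum(counts$tp), sum(counts$fp), sum(counts$fn)))
  }
  per <- lapply(seq_len(nrow(counts)), function(i)
    compute_metrics(counts$tp[i], counts$fp[i], counts$fn[i]))
  per <- per[vapply(per, `[[`, logical(1), "defined")]
  if (length(per) == 0L) {
    return(list(precision = NA_real_, recall = NA_real_, f_score = NA_real_,
                defined = FALSE))
  }
  list(precision = mean(vapply(per, `[[`, numeric(1), "precision")),
       recall = mean(vapply(per, `[[`, numeric(1), "recall")),
       f_score = mean(vapply(per, `[[`, numeric(1), "f_score")),
       defined = TRUE)
}

#' Evaluate extraction over a corpus
#'
#' Sums per-document span matches into per-class counts and derives
#' per-class, micro and macro metrics. Title mentions (separate offset
#' space) are excluded; gold annotations refer to abstracts.
#'
#' @param profiles List of `epi_profile` (predictions).
#' @param gold Data frame of gold annotations for the same documents
#'   (`doc_id`, `characteristic`, `start`, `end`, `surface`).
#' @param mode `"strict"` or `"relaxed"`.
#' @return `epi_eval`: list with `counts` (per class) and `report` (data
#'   frame mirroring the published result tables: class, TP, FP, FN, P, R,
#'   F, plus micro and macro rows; display values rounded to one decimal).
#' @export
evaluate_corpus <- function(profiles, gold, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  counts <- data.frame(characteristic = CHARACTERISTICS, tp = 0L, fp = 0L,
                       fn = 0L, stringsAsFactors = FALSE)
  gold_ids <- unique(gold$doc_id)
  seen <- character()
  for (p in profiles) {
    pred <- do.call(rbind, lapply(p$mentions, function(m) {
      if (!is.null(m$in_title)) m <- m[!m$in_title, , drop = FALSE]
      m[, names(empty_mention_df()), drop = FALSE]
    }))
    pred$doc_id <- rep(p$doc_id, nrow(pred))
    g <- gold[gold$doc_id == p$doc_id, , drop = FALSE]
    cc <- match_spans(pred, g, mode)
    counts$tp <- counts$tp + cc$tp
    counts$fp <- counts$fp + cc$fp
    counts$fn <- counts$fn + cc$fn
    seen <- c(seen, p$doc_id)
  }
  # gold for documents with no profile counts entirely as misses
  for (id in setdiff(gold_ids, seen)) {
    g <- gold[gold$doc_id == id, , drop = FALSE]
    cc <- match_spans(g[0, , drop = FALSE], g, mode)
    counts$fn <- counts$fn + cc$fn
  }
  structure(list(counts = counts, mode = mode,
                 report = eval_report(counts)), class = "epi_eval")
}

eval_report <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    m <- compute_metrics(counts$tp[i], counts$fp[i], counts$fn[i])
    data.frame(class = counts$characteristic[i], tp = counts$tp[i],
               fp = counts$fp[i], fn = counts$fn[i],
               P = round(m$precision, 1), R = round(m$recall, 1),
               F = round(m$f_score, 1), stringsAsFactors = FALSE)
  })
  mi <- aggregate_metrics(counts, "micro")
  ma <- aggregate_metrics(counts, "macro")
  rows[[length(rows) + 1L]] <- data.frame(
    class = "all_micro", tp = sum(counts$tp), fp = sum(counts$fp),
    fn = sum(counts$fn), P = round(mi$precision, 1), R = round(mi$recall, 1),
    F = round(mi$f_score, 1), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    class = "all_macro", tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    P = round(ma$precision, 1), R = round(ma$recall, 1),
    F = round(ma$f_score, 1), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' @export
print.epi_eval <- function(x, ...) {
  cat("<epi_eval> mode = ", x$mode, "\n", sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Absolute inter-annotator agreement rate
#'
#' Annotations from two annotators over the same document set are matched
#' exactly (document, characteristic and span). The agreement rate is
#' `100 * matched_pairs / (matched_pairs + unmatched)`, each matched pair
#' counted once and each unmatched annotation (either side) counted singly.
#' Symmetric in its arguments.
#'
#' @param ann_a,ann_b Annotation data frames (`doc_id`, `characteristic`,
#'   `start`, `end`).
#' @return Agreement percentage.
#' @export
absolute_agreement <- function(ann_a, ann_b) {
  key <- function(df) paste(df$doc_id, df$characteristic, df$start, df$end)
  a <- key(ann_a); b <- key(ann_b)
  matched <- 0L
  for (k in a) {
    hit <- match(k, b)
    if (!is.na(hit)) {
      matched <- matched + 1L
      b <- b[-hit]   # one-to-one: each annotation matched at most once
    }
  }
  unmatched <- (length(key(ann_a)) - matched) + length(b)
  if (matched + unmatched == 0L) return(100)
  100 * matched / (matched + unmatched)
}
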