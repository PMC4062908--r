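ann <- function(spans, chr = "exposure", doc_id = "d") {
  n <- length(spans)
  data.frame(doc_id = rep(doc_id, n), characteristic = rep(chr, length.out = n),
             start = vapply(spans, `[[`, numeric(1), 1),
             end = vapply(spans, `[[`, numeric(1), 2),
             surface = rep("x", n), stringsAsFactors = FALSE)
}

test_that("span matching distinguishes strict and relaxed agreement", {
  pred <- ann(list(c(5, 12)))
  gold <- ann(list(c(5, 12)))
  cc <- match_spans(pred, gold)
  expect_equal(cc[cc$characteristic == "exposure", c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 0L), ignore_attr = TRUE)

  off <- ann(list(c(6, 12)))   # boundary off by one
  strict <- match_spans(off, gold, "strict")
  expect_equal(unlist(strict[strict$characteristic == "exposure", 2:4]),
               c(tp = 0L, fp = 1L, fn = 1L))
  relaxed <- match_spans(off, gold, "relaxed")
  expect_equal(unlist(relaxed[relaxed$characteristic == "exposure", 2:4]),
               c(tp = 1L, fp = 0L, fn = 0L))

  # class must agree even on identical spans
  wrongc <- ann(list(c(5, 12)), chr = "outcome")
  cc2 <- match_spans(wrongc, gold, "strict")
  expect_equal(sum(cc2$tp), 0)
  expect_equal(sum(cc2$fp), 1)
  expect_equal(sum(cc2$fn), 1)

  expect_error(match_spans(ann(list(c(0, 1)), doc_id = "a"),
                           ann(list(c(0, 1)), doc_id = "b")),
               "one document")
})

test_that("greedy matching agrees with the exhaustive bipartite oracle", {
  set.seed(77)
  for (case in 1:30) {
    relaxed <- runif(1) < 0.5
    mk <- function() {
      n <- sample(0:5, 1)
      if (n == 0) return(ann(list())[0, ])
      s <- sample(0:15, n, replace = TRUE)
      ann(Map(c, s, s + sample(1:6, n, replace = TRUE)),
          chr = sample(c("exposure", "outcome"), n, replace = TRUE))
    }
    pred <- mk(); gold <- mk()
    got <- match_spans(pred, gold, if (relaxed) "relaxed" else "strict")
    # dedupe as the implementation documents, then brute-force match
    dd <- function(df) df[!duplicated(paste(df$characteristic, df$start,
                                            df$end)), , drop = FALSE]
    want <- oracle_match_counts(dd(pred), dd(gold), relaxed)
    expect_equal(c(sum(got$tp), sum(got$fp), sum(got$fn)),
                 unname(want), info = paste("case", case))
    # tally invariants
    expect_equal(sum(got$tp) + sum(got$fn), nrow(dd(gold)))
    expect_equal(sum(got$tp) + sum(got$fp), nrow(dd(pred)))
  }
})

test_that("precision/recall/F-score follow the standard definitions", {
  m <- compute_metrics(247, 32, 39)
  expect_equal(round(m$precision, 1), 88.5)
  expect_equal(round(m$f_score, 1), 87.4)

  m2 <- compute_metrics(12, 0, 1)
  expect_equal(m2$precision, 100)
  expect_equal(round(m2$recall, 1), 92.3)

  m3 <- compute_metrics(0, 0, 0)
  expect_false(m3$defined)
})

test_that("micro pools counts and macro averages defined classes", {
  counts <- data.frame(tp = c(12, 35, 45, 73, 17, 65),
                       fp = c(0, 1, 8, 19, 2, 2),
                       fn = c(1, 4, 11, 13, 0, 10))
  mi <- aggregate_metrics(counts, "micro")
  expect_equal(round(mi$precision, 1), 88.5)
  ma <- aggregate_metrics(counts, "macro")
  expect_equal(round(ma$precision, 1), 91.3)
  # micro precision lies between the per-class extremes (weighted mean)
  per_p <- 100 * counts$tp / (counts$tp + counts$fp)
  expect_gte(mi$precision, min(per_p))
  expect_lte(mi$precision, max(per_p))

  one <- counts[1, , drop = FALSE]
  expect_equal(aggregate_metrics(one, "micro"), aggregate_metrics(one, "macro"))
  expect_error(aggregate_metrics(counts[0, ]), "aggregate")

  # undefined classes are excluded from the macro mean, not scored
  with_zero <- rbind(counts[1:2, ], data.frame(tp = 0, fp = 0, fn = 0))
  expect_equal(aggregate_metrics(with_zero, "macro")$precision,
               mean(100 * counts$tp[1:2] / (counts$tp[1:2] + counts$fp[1:2])))
})

test_that("absolute agreement counts matched pairs once, unmatched singly", {
  a <- ann(list(c(0, 5), c(10, 14), c(20, 30)))
  expect_equal(absolute_agreement(a, a), 100)
  b <- ann(list(c(50, 55)))
  expect_equal(absolute_agreement(a, b), 0)

  # 8 matched pairs + 2 unmatched in total -> 80%
  s8 <- lapply(0:7, function(i) c(i * 10, i * 10 + 4))
  annA <- ann(c(s8, list(c(90, 95))))
  annB <- ann(c(s8, list(c(96, 99))))
  expect_equal(absolute_agreement(annA, annB), 80)
  expect_equal(absolute_agreement(annB, annA), 80)   # symmetric
})

test_that("corpus evaluation sums documents and mirrors the report layout", {
  res <- RES
  sim <- generate_corpus(8, seed = 12)
  profiles <- process_corpus(sim$documents, res)
  ev <- evaluate_corpus(profiles, sim$gold, "strict")
  expect_equal(ev$report$class,
               c(epimine:::CHARACTERISTICS, "all_micro", "all_macro"))
  micro <- ev$report[ev$report$class == "all_micro", ]
  expect_equal(micro$tp, sum(ev$counts$tp))
  # gold in documents without profiles counts as misses
  ev2 <- evaluate_corpus(profiles[-1], sim$gold, "strict")
  expect_equal(sum(ev2$counts$fn),
               sum(ev$counts$fn) + sum(sim$gold$doc_id ==
                                         sim$documents[[1]]$doc_id))
})
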