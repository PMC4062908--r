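# Synthetic abstracts with gold annotations, built from sentence templates
# aligned with the shipped rules, so the full pipeline and the evaluator
# can be exercised end-to-end without any external corpus.
#
# Template notation: {slot} substitutes a vocabulary filler; <<...>> marks a
# gold region for the template's characteristic. Coordinated covariate gold
# is marked per conjunct, mirroring how the extractor splits captures.

#' Sentence template families
#'
#' `synthetic` templates are parameterised sentences aligned one-to-one
#' with the shipped rules; `examples` are the published worked example
#' sentences embedded in complete sentences; `adversarial` are known-trap
#' sentences (e.g. "relationship between race and gender") whose gold
#' reflects the rules' intended behaviour, as regression material.
#'
#' @param family Which families to include.
#' @return List of template specs (`characteristic`, `template`).
#' @export
epi_templates <- function(family = c("synthetic", "examples")) {
  family <- match.arg(family, c("synthetic", "examples", "adversarial"),
                      several.ok = TRUE)
  synthetic <- list(
    list(characteristic = "study_design",
         template = "Methods: This was a <<{types} {st}>> conducted over two years."),
    list(characteristic = "study_design",
         template = "We performed a <<{types} {st}>> to describe current practice."),
    list(characteristic = "population",
         template = "Data were drawn from a {total} of <<{n} {cluster}>> at baseline."),
    list(characteristic = "population",
         template = "We measured {term1} in <<{cluster} with {term2}>>."),
    list(characteristic = "exposure",
         template = "The aim was to analyze the association between <<{term1}>> and {term2} in this sample."),
    list(characteristic = "exposure",
         template = "<<{term1}>> is associated with onset of {term2}."),
    list(characteristic = "outcome",
         template = "This work identified determinants of <<{term1}>> in the community."),
    list(characteristic = "outcome",
         template = "In conclusion, {term1} is {adverb} associated with <<{term2}>>."),
    list(characteristic = "covariate",
         template = "Models were adjusted for <<{term1}>>, <<{term2}>>, and <<{term3}>>."),
    list(characteristic = "covariate",
         template = "Analyses were performed including <<{term1}>> and <<{term2}>> as covariates."),
    list(characteristic = "effect_size",
         template = "{term1} <<prevalence was {pct}>>."),
    list(characteristic = "effect_size",
         template = "Participants were more likely to have {term1} <<(or = {orv}, 95% ci: {cilo}, {cihi})>>."))
  examples <- list(
    list(characteristic = "study_design",
         template = "Methods: This was a <<cross-sectional study>> of 214 overweight/obese patients."),
    list(characteristic = "population",
         template = "Sibling study in a prospective cohort of <<208,866 men>> from five countries."),
    list(characteristic = "population",
         template = "We measured bone mineral density in <<patients with type 2 diabetes>>."),
    list(characteristic = "exposure",
         template = "The aim was to analyze the association between <<body mass index>> and blood pressure in this sample."),
    list(characteristic = "exposure",
         template = "<<Short sleep duration>> is associated with onset of obesity."),
    list(characteristic = "outcome",
         template = "Cardiovascular and disease related predictors of <<depression>> were considered."),
    list(characteristic = "outcome",
         template = "Conclusions coffee intake is inversely associated with <<t2dm>> in Chinese."),
    list(characteristic = "covariate",
         template = "Risk estimates changed little after adjusting for <<age>>, <<smoking status>>, and <<clinical history of diabetes mellitus>>."),
    list(characteristic = "covariate",
         template = "Analyses were performed including <<visceral adipose tissue (vat)>> and <<subcutaneous adipose tissue (sat)>> as covariates."),
    list(characteristic = "effect_size",
         template = "Hernia <<prevalence was 32.4%>> in this series."),
    list(characteristic = "effect_size",
         template = "Obese adults were more likely to have elevated blood pressure <<(or = 9.05, 95% ci: 1.44, 56.83)>>."))
  adversarial <- list(
    # the rules read any "association between X and Y" as exposure X, even
    # when X is not a determinant in the epidemiological sense
    list(characteristic = "exposure",
         template = "We examined the relationship between <<race>> and gender in this cohort."),
    # a prevalence cue without a preceding concept or number yields nothing
    list(characteristic = "effect_size",
         template = "The prevalence was high across all regions."))
  fams <- list(synthetic = synthetic, examples = examples,
               adversarial = adversarial)
  out <- do.call(c, unname(fams[family]))
  for (i in seq_along(out)) out[[i]]$family <-
    rep(family, times = vapply(fams[family], length, integer(1)))[i]
  out
}

#' Filler vocabularies for the sentence templates
#'
#' Term fillers are seeded from high-frequency exposures/outcomes/covariates
#' of the obesity literature and are all gazetteer entries, chosen so that
#' no filler is a substring of another (keeping gold spans unambiguous).
#'
#' @return Named list of character vectors.
#' @export
epi_template_vocab <- function() {
  list(
    types = c("cross-sectional", "case-control", "observational",
              "longitudinal", "retrospective"),
    st = c("study", "analysis", "survey", "trial"),
    total = c("cohort", "sample", "population", "group"),
    cluster = c("men", "women", "adults", "children", "participants",
                "patients", "adolescents"),
    adverb = c("inversely", "positively", "strongly", "independently"),
    term = c("body mass index", "physical activity", "waist circumference",
             "blood pressure", "insulin resistance", "birth weight",
             "alcohol consumption", "marital status", "energy intake",
             "bone mineral density", "asthma", "depression", "hypertension",
             "dyslipidemia", "obesity", "type 2 diabetes", "smoking",
             "socioeconomic status", "metabolic syndrome", "sleep duration"))
}

DISTRACTOR_SENTENCES <- c(
  "These findings may inform public health policy development.",
  "Further research is needed to confirm these findings.",
  "Data collection took place over several months.",
  "The implications are discussed in the final section.",
  "Recruitment procedures followed established protocols.")

# render one template: substitute slots, strip gold markers, compute offsets
render_template <- function(spec, vocab) {
  tpl <- spec$template
  # substitute slots first (slot fillers never contain << or >>)
  slots <- regmatches(tpl, gregexpr("\\{[a-z0-9]+\\}", tpl))[[1]]
  if (length(slots)) {
    term_pool <- sample(vocab$term)
    term_i <- 0L
    for (sl in unique(slots)) {
      name <- gsub("[{}]", "", sl)
      filler <- if (grepl("^term[0-9]*$", name)) {
        term_i <- term_i + 1L
        term_pool[term_i]
      } else if (name == "n") {
        formatC(sample(100:999999, 1L), big.mark = ",", format = "d")
      } else if (name == "pct") {
        sprintf("%.1f%%", stats::runif(1, 1, 80))
      } else if (name == "orv") {
        sprintf("%.2f", stats::runif(1, 1.05, 20))
      } else if (name == "cilo") {
        sprintf("%.2f", stats::runif(1, 1.0, 4.9))
      } else if (name == "cihi") {
        sprintf("%.2f", stats::runif(1, 5.0, 80))
      } else {
        pool <- vocab[[name]]
        if (is.null(pool)) stop("template slot without filler: ", name,
                                call. = FALSE)
        sample(pool, 1L)
      }
      tpl <- gsub(sl, filler, tpl, fixed = TRUE)
    }
  }
  # capitalise the sentence (inside a leading gold marker if present)
  tpl <- sub("^((?:<<)?)([a-z])", "\\1\\U\\2", tpl, perl = TRUE)
  # extract gold regions
  text <- ""
  gold <- data.frame(characteristic = character(), start = integer(),
                     end = integer(), surface = character(),
                     stringsAsFactors = FALSE)
  open <- NA_integer_
  rest <- tpl
  repeat {
    m <- regexpr("<<|>>", rest)
    if (m == -1L) { text <- paste0(text, rest); break }
    text <- paste0(text, substr(rest, 1L, m - 1L))
    if (substr(rest, m, m + 1L) == "<<") {
      open <- nchar(text)
    } else {
      gold[nrow(gold) + 1L, ] <- list(spec$characteristic, open, nchar(text),
                                      slice(text, open, nchar(text)))
      open <- NA_integer_
    }
    rest <- substring(rest, m + 2L)
  }
  list(text = text, gold = gold)
}

#' Generate one synthetic abstract with gold annotations
#'
#' Deterministic given the seed; gold offsets are computed during rendering
#' and always slice back to their surfaces.
#'
#' @param specs Template specs (subset of [epi_templates()]).
#' @param seed Integer seed.
#' @param doc_id Document identifier.
#' @param distractor_rate Probability of inserting a distractor sentence
#'   after each template sentence; `1` with zero-gold specs yields a fully
#'   gold-free abstract.
#' @param vocab Filler vocabularies.
#' @return List with `document` (`epi_document`) and `gold` (data frame).
#' @export
generate_abstract <- function(specs, seed, doc_id = "SYN1",
                              distractor_rate = 0,
                              vocab = epi_template_vocab()) {
  with_seed(seed, build_abstract(specs, doc_id, distractor_rate, vocab))
}

build_abstract <- function(specs, doc_id, distractor_rate, vocab) {
  text <- ""
  gold <- NULL
  add_sentence <- function(sent_text, sent_gold = NULL) {
    offset <- nchar(text)
    if (nzchar(text)) {
      text <<- paste0(text, " ", sent_text)
      offset <- offset + 1L
    } else {
      text <<- sent_text
    }
    if (!is.null(sent_gold) && nrow(sent_gold)) {
      sent_gold$start <- sent_gold$start + offset
      sent_gold$end <- sent_gold$end + offset
      gold <<- rbind(gold, sent_gold)
    }
  }
  for (spec in specs) {
    r <- render_template(spec, vocab)
    add_sentence(r$text, r$gold)
    if (stats::runif(1) < distractor_rate) {
      add_sentence(sample(DISTRACTOR_SENTENCES, 1L))
    }
  }
  if (!nzchar(text)) text <- sample(DISTRACTOR_SENTENCES, 1L)
  gold <- gold %||% data.frame(characteristic = character(), start = integer(),
                               end = integer(), surface = character(),
                               stringsAsFactors = FALSE)
  gold <- cbind(doc_id = rep(doc_id, nrow(gold)), gold,
                stringsAsFactors = FALSE)
  doc <- epi_document(doc_id, abstract = text,
                      title = paste("Synthetic epidemiological abstract", doc_id))
  list(document = doc, gold = gold)
}

#' Generate a synthetic evaluation corpus
#'
#' Each abstract draws, per characteristic, a Bernoulli(`mix[chr]`) decision
#' to include one randomly chosen template sentence of that characteristic,
#' so expected gold-sentence totals are `n * mix` and binomially
#' distributed. Optionally writes `<id>.txt`, `<id>.ann` (BRAT standoff)
#' and `manifest.json` to a directory.
#'
#' @param n Number of abstracts.
#' @param seed Integer seed; the single source of randomness.
#' @param mix Named per-characteristic inclusion probabilities (default 1
#'   for all six: every abstract carries every characteristic).
#' @param distractor_rate Probability of a distractor sentence after each
#'   template sentence.
#' @param templates Template pool, by default the rule-aligned synthetic
#'   and worked-example families.
#' @param dir Optional output directory.
#' @return List with `documents`, `gold` (single data frame), `manifest`.
#' @export
generate_corpus <- function(n, seed = 42L, mix = NULL, distractor_rate = 0,
                            templates = epi_templates(), dir = NULL) {
  stopifnot(n >= 1L)
  if (is.null(mix)) {
    mix <- stats::setNames(rep(1, length(CHARACTERISTICS)), CHARACTERISTICS)
  }
  vocab <- epi_template_vocab()
  by_chr <- split(templates, vapply(templates, `[[`, character(1),
                                    "characteristic"))
  out <- with_seed(seed, {
    documents <- vector("list", n)
    gold <- vector("list", n)
    for (i in seq_len(n)) {
      specs <- list()
      for (chr in sample(CHARACTERISTICS)) {
        p <- mix[[chr]] %||% 0
        if (length(by_chr[[chr]]) && stats::runif(1) < p) {
          specs[[length(specs) + 1L]] <-
            by_chr[[chr]][[sample.int(length(by_chr[[chr]]), 1L)]]
        }
      }
      res <- build_abstract(specs, sprintf("SYN%05d", i), distractor_rate,
                            vocab)
      documents[[i]] <- res$document
      gold[[i]] <- res$gold
    }
    list(documents = documents, gold = do.call(rbind, gold))
  })
  manifest <- list(n = n, seed = seed, mix = as.list(mix),
                   distractor_rate = distractor_rate,
                   doc_ids = vapply(out$documents, `[[`, character(1), "doc_id"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      doc <- out$documents[[i]]
      writeLines(doc$abstract, file.path(dir, paste0(doc$doc_id, ".txt")),
                 useBytes = TRUE)
      g <- out$gold[out$gold$doc_id == doc$doc_id, , drop = FALSE]
      write_standoff(g, file.path(dir, paste0(doc$doc_id, ".ann")))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(documents = out$documents, gold = out$gold, manifest = manifest)
}

#' Read the gold annotations of a generated corpus directory
#'
#' @param dir Directory written by [generate_corpus()].
#' @return List with `documents` (`epi_corpus`) and `gold` data frame.
#' @export
read_gold_corpus <- function(dir) {
  corpus <- read_plaintext(dir)
  gold <- do.call(rbind, lapply(corpus$documents, function(doc) {
    ann <- file.path(dir, paste0(doc$doc_id, ".ann"))
    if (!file.exists(ann)) return(NULL)
    read_standoff(ann, doc)
  }))
  list(documents = corpus, gold = gold)
}
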