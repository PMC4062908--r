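Package: epimine
Title: Rule-Based Extraction of Key Characteristics from Epidemiological Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies six key characteristics of epidemiological studies
    (study design, population, exposure, outcome, covariate and effect size)
    in MEDLINE/PubMed abstracts with a cascaded rule-based method: semantic
    dictionaries and C-value automatic term recognition tag candidate
    concepts, a small annotation-grammar DSL combines dictionary classes,
    frozen lexical anchors and macros into extraction rules, candidate
    mentions are unified at document level and mapped to coarse semantic
    groups, and corpora are summarised into frequency tables. Includes a
    span-level evaluation harness (precision/recall/F-score, micro and macro,
    absolute inter-annotator agreement) against BRAT-style standoff gold
    annotations, and a synthetic-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
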