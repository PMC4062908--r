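---
title: "Mining key characteristics of epidemiological studies: methods and design notes"
author: "epimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining key characteristics of epidemiological studies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimine)
```

## The extraction problem

Epidemiological abstracts report six recurring kinds of information: the
study design, the population studied, the exposures under investigation,
the outcomes they are related to, the covariates adjusted for, and
quantified effect sizes. These are expressed with strong lexical
regularity — design statements ("a cross-sectional study"), population
counts ("a cohort of 208,866 men"), relational frames ("the association
between X and Y"), adjustment lists ("after adjusting for age, smoking
status, …") and statistical templates ("OR = 9.05, 95% CI: 1.44, 56.83").
`epimine` extracts all six with a cascade of dictionary tagging, automatic
term recognition and hand-readable pattern rules, unified per document.
The method assumes abstracts (not full text), English prose, and
sentence-local patterns: no rule ever matches across a sentence boundary,
so information spread over several sentences is out of reach by design.

## Offsets

Every annotation — semantic tag, extracted mention, gold annotation — is a
0-based, half-open code-point span on the raw abstract text, so slicing
the document by any span reproduces its surface string exactly. Titles are
kept out of this offset space; when title processing is enabled
(`load_resources(include_title = TRUE)`) title mentions live in their own
space and are flagged, and evaluation ignores them, because gold standoff
annotations refer to abstracts.

## Dictionary tagging

Fourteen semantic-class dictionaries drive the tagger: design `types`,
population `totals` and `clusters`, relation nouns (`relations`), copulae
(`be`), relatedness participles (`related`), linking prepositions
(`with`), adjustment cues (`adj`), prevalence nouns (`preva`), `adverbs`,
covariate cue nouns (`synonyms`), outcome cue nouns (`factors`),
study-cue nouns (`study-cues`) and term connectors (`multiple-cues`).
The inventory is exactly the set of classes the shipped rules reference;
the files are plain text and user-extendable. Matching is
case-insensitive, token-boundary-respecting and leftmost-longest per
class, so tags of one class never nest while tags of different classes
may overlap freely. Hyphen and slash are token boundaries
("overweight/obese" contributes both tokens and whatever multi-word
gazetteer forms cover them).

Three derived classes come from token shape rather than a word list:
`MULTIPLE_TERM` (biomedical-term gazetteer hits), `STATS_NUMBER` (numeric
tokens, thousands separators and decimal points kept inside one token) and
`PERCENT` (a number immediately followed by `%`).

The biomedical-term gazetteer stands in for a licensed terminology
look-up layer: it is a flat term file feeding the same `MULTIPLE_TERM`
tag that a UMLS/Specialist-derived list would feed, and C-value output
can be merged into it (`load_lexicon(extra_terms = ...)`).

## C-value term recognition

Multi-word candidates are maximal runs of content tokens (a closed-class
function-word list and punctuation delimit runs), with every contiguous
sub-sequence of length ≥ 2 emitted and counted corpus-wide — nested
occurrences included. The termhood score is

$$C(a) = \log_2 |a| \cdot f(a)$$

for candidates not nested in any longer candidate, and

$$C(a) = \log_2 |a| \cdot \Big(f(a) - \tfrac{1}{|T_a|}\sum_{b \in T_a} f(b)\Big)$$

otherwise, with $T_a$ the set of longer candidates containing $a$. On the
classic fixture (2 × "soft contact lens", 4 × "contact lens") this gives
`C("contact lens") = 4` and `C("soft contact lens") = 2·log2(3)`; a fully
nested bigram scores 0.

Design choices made here, where the method description left room:

* **No POS tagger.** The original linguistic filter is approximated with
  the function-word list and token-shape rules. The downstream consumer is
  only a gazetteer, so the cost of occasional non-noun-phrase candidates
  is a few extra gazetteer lines, and the package avoids a heavyweight
  dependency.
* **Corpus-wide counting**, not per-abstract: nesting statistics are much
  richer across a corpus, and the score is meant to rank corpus-level
  terms.
* **Admission threshold** `C ≥ 1.0` (configurable): the score itself fixes
  no threshold; 1.0 admits any non-fully-nested bigram seen at least
  twice while discarding fully nested fragments.
* **Variant merging** is deliberately trivial — case folding,
  hyphen-to-space normalisation, and final-token plural stripping — since
  synonym unification beyond orthographic variants is explicitly out of
  scope.

## The rule DSL

A rule is a sequence of constituents matched left-to-right over the token
stream of one sentence:

| constituent | consumes |
|---|---|
| `a(class)` | one semantic tag of that class (longest at the position) |
| `eq('word')` | one token equal to the payload, case-insensitive |
| `re('rx')` | one token matching the whole-token regex |
| `@name` | a macro: a named sub-pattern, or the built-in `@multiple` |
| suffix `?` | makes the preceding constituent optional |
| `[ … ]` | exactly one contiguous capture range: the emitted mention |

Macros other than `@multiple` are data, not code: `macros.tsv` maps each
name to a mini-pattern in the same notation (`@perce` is
`a(PERCENT)`, `@or` is `eq('(')? re('or|rr|hr|aor') eq('=')
a(STATS_NUMBER) eq(',')?`, and so on), so users can change them without
touching the engine. `@multiple` is built in because its semantics — one
or more `MULTIPLE_TERM` tags optionally joined by commas, `and`/`or`,
slashes, or a parenthesised abbreviation ("visceral adipose tissue
(vat)") — are a small grammar rather than a fixed sequence.

Matching policy, chosen once and applied everywhere:

* Per starting position the **longest overall match** wins (ties: longest
  capture, then the first alternative tried). Matching restarts after each
  match end, so matches of one rule never overlap; overlaps *across* rules
  are kept, because document-level unification expects them.
* The engine backtracks: a greedy `@multiple` backs off so a later
  `eq('and')` anchor can still match ("association between **body mass
  index** and blood pressure").
* **Order inside a capture bracket is unordered.** The published
  study-design rule `[@st a(types)]` identifies "cross-sectional study",
  i.e. the type word *precedes* the cue noun even though the bracket lists
  the cue first — the bracket order is display order, not text order. The
  matcher therefore tries the written order first and then the other
  permutations of the capture block, keeping the deterministic preference
  above. Constituents outside the capture keep their written order.
* `?` scopes over exactly the preceding constituent, including inside
  captures.
* Sentence segmentation is a period/question/exclamation heuristic with an
  abbreviation guard ("e.g.", "et al.", single initials); decimal numbers
  never split because the tokenizer keeps them whole.
* Captured covariate lists are split into one mention per conjunct
  (splitting on ", and", ",", " and "), mirroring how adjustment lists
  enumerate concepts. A conjunct such as "clinical history of diabetes
  mellitus" survives intact because splitting only happens at list
  punctuation.

One notation wrinkle: the published effect-size rule `@multiple @or @ci`
is printed without a capture bracket, while its identified span is the
parenthesised statistics. The shipped rule restores the bracket as
`@multiple [@or @ci]`; the parser treats bracketless rules as syntax
errors rather than guessing. Typographic quotes (`‘…’`) are accepted
wherever straight quotes are.

## Unification and semantic groups

Within a document and characteristic, any mention strictly contained in
another is discarded and exact duplicates collapse, yielding an antichain
under span containment (idempotent, never inventing spans). Mentions of
exposures, outcomes and covariates are then mapped to one of 15 coarse
semantic groups by the longest group-gazetteer entry contained in the
mention surface; ties go to the earlier-starting entry (an arbitrary but
documented choice), and unmapped mentions fall back to `"Other"` — a
fallback bucket, not a sixteenth group.

Corpus summaries count *mention occurrences* (post-unification), not
unique documents — outcomes in particular are routinely reported several
times per abstract — keyed by case-folded surface, with shares
`100·count/total` rounded to one decimal. No synonym merging is applied
beyond case folding.

## Evaluation conventions

* **Strict span equality is the default**; a relaxed overlap mode exists
  behind a flag and should be reported separately.
* Matching is one-to-one and maximal (augmenting-path bipartite matching,
  processed in span-start order, so counts are deterministic and agree
  with exhaustive matching); both sides are deduplicated on
  (characteristic, span) first, consistent with unification.
* `P`, `R` and `F` are computed at full precision on the percentage scale
  and displayed to one decimal. When a denominator is zero the metric is
  *undefined* and the class is excluded from macro averaging — not scored
  0 or 100.
* Micro pools TP/FP/FN before computing; macro averages per-class values.
* Published result tables of this genre often truncate rather than round,
  and occasionally contain cells that are not derivable from their own
  row's counts; the package's tests therefore check recomputed metrics
  against printed values within ±0.1 and exclude cells whose printed
  value is internally inconsistent, rather than loosening the tolerance.
* The absolute agreement rate between two annotators is
  `100 · matched / (matched + unmatched)`, exact span-and-label matches
  counted once per pair and unmatched annotations singly; it is symmetric.

## The synthetic-corpus generator

Real annotated epidemiological corpora are not redistributable, so the
generator builds abstracts from sentence templates aligned one-to-one
with the shipped rules, plus the published worked-example sentences
verbatim as a second family, plus an adversarial family (the
"relationship between race and gender" trap, prevalence cues with nothing
to capture) whose gold encodes the rules' *intended* behaviour. Fillers
are drawn from high-frequency exposure/outcome/covariate terms of the
obesity literature so the gazetteer and group mapping are exercised
realistically; numeric slots (population sizes with thousands separators,
percentages, odds ratios, confidence bounds) are sampled fresh each time.
Gold offsets are computed during rendering, so they are correct by
construction. One integer seed drives everything; the same seed gives
byte-identical corpora.

Each abstract draws one template sentence per characteristic with
probability `mix[chr]` (default 1), optionally followed by distractor
sentences that contain no dictionary or gazetteer material. Because every
template is rule-aligned and the distractors are inert, the full pipeline
on a distractor-free corpus scores perfect precision and recall in strict
mode, and distractors can lower neither. This closed loop is a strong
*internal consistency* check — it shows the tagger, matcher, splitter,
unifier and evaluator compose without span drift — but it says nothing
about recall on real prose, where expressions outside the shipped rule
inventory are common: a real corpus will surface designs, populations and
effect sizes these rules do not cover, and dictionary gaps the gazetteer
does not fill. Template text is also simpler than real abstracts (no
anaphora, no cross-sentence structure, no meta-analysis populations).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mode` (evaluation) | `"strict"` | span equality vs any overlap |
| `include_title` | `FALSE` | also run rules over titles (separate offset space) |
| `threshold` (gazetteer admission) | 1.0 | minimum C-value |
| `max_len` (ATR) | 6 tokens | longest candidate considered |
| `mix` (generator) | 1 per characteristic | per-abstract inclusion probability |
| `distractor_rate` | 0 | distractor sentence probability |
| `drop_non_english` | `TRUE` | language gate on MEDLINE input |

## Problem sizes

The test suite exercises: 1000 random span sets against a brute-force
containment oracle; random toy corpora of up to 50 short documents
against an exhaustive-substring C-value oracle (agreement to 1e-9); 60
random rule/tag-stream cases against a full-enumeration matching oracle;
and 60-abstract closed-loop corpora (about ten seconds end-to-end on one
core). These sizes were chosen to exhaust the combinatorial behaviour of
each component — larger inputs add runtime, not coverage, because every
code path is already reached.

## Known limitations

* Recall on real corpora is bounded by the shipped rule and dictionary
  inventory, which reconstructs only the published examples of a much
  larger grammar.
* Exposure/outcome confusion is inherent to sentence-local patterns: the
  same concept can be either, depending on study framing.
* The species gate is a gazetteer with a human-cue precedence rule, not a
  full species tagger (no abbreviation resolution or disambiguation).
* No concept normalisation: mentions are surface strings; only simple
  orthographic variants ever merge.
* Coordinated effect sizes ("60.3% and 44.6%, respectively") and
  multi-value statistical expressions are not covered by the shipped
  effect-size rules.
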