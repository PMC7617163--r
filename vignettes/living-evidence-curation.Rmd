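---
title: "Curating a living evidence summary: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a living evidence summary: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soles)
```

A systematic online living evidence summary (SOLES) maintains a continuously
updated, machine-curated map of a research literature — here, in vivo
experiments in animal models of Alzheimer's disease (AD). The pipeline this
package implements has five stages: citations are retrieved from
bibliographic databases and **deduplicated**; a classifier **screens** them
for in vivo relevance; regex **dictionaries tag** each study by animal model,
intervention, outcome measure, species and sex across several matching
surfaces; a **validation harness** scores those tagging methods against human
annotations and selects the combination policy; and **reporting** functions
emit the aggregations a dashboard serves. This vignette explains the model
behind each stage, the tunable parameters and their defaults, and the design
choices made where the design was genuinely open.

## Dictionary tagging

### The matching model

Each canonical label (say, the `3xTg-AD` model or the Morris water maze) is
compiled to a single regular expression: the alternation of all surface
variants of the label and its declared synonyms, each alternative anchored on
both sides by word boundaries.

Two details carry most of the precision:

* **Boundaries treat letters *and digits* as word characters** (underscore
  excluded). `APP` must not fire inside `PAPP` (a different protein) nor
  inside `APP23` (a different model), but must fire in `APP/PS1`, where the
  slash is a legitimate boundary. PCRE's `\b` treats digits as word
  characters too, but we state the class explicitly (`\p{L}\p{N}`) so the
  rule is locale-independent and auditable in the exported dictionaries.
* **Variant expansion** generalises inter-token separators over space,
  hyphen, `x`, `×` (with or without surrounding spaces), asterisk and
  nothing, so `3 × Tg`, `3xTg` and `3-Tg` all hit the `3xTg-AD` entry. Upper
  case variants are generated for mixed-case tokens (`3 × TG`), Greek
  letters are spelled out as additional variants (`Aβ` also compiles
  `Abeta`; AD text demands it), and a trailing `AD` token is treated as an
  optional disease designator, since running text says "the 3 × Tg model"
  far more often than the full registered name. Expansion is capped at 5000
  variants per entry; beyond that only the conservative separator set
  (space, hyphen, nothing) is used.

Short all-caps acronyms of up to three characters default to
*case-sensitive* matching — `AD` as a lowercase word is almost always the
English word "ad" or an artefact — with a per-entry override column in the
lexicon CSV.

Counting is a leftmost, non-overlapping scan in which the longest
alternative wins at each position: "The Morris water maze (MWM) was used"
counts two mentions (the full phrase and the acronym), not three — the inner
"water maze" is consumed by the longer span. Whether overlapping synonym
hits should count once or many times is not something published pipelines
state; longest-wins is this package's declared convention, and a brute-force
per-variant oracle in the test suite pins the semantics down exactly.
Different labels may still claim overlapping spans — a text can genuinely
evidence both a generic and a specific model name — so deduplication of
spans happens only within a label.

### Matching surfaces

Three surfaces are searched per citation:

* **tiabkw** — title + abstract + keywords, joined with a sentinel
  containing a non-whitespace control character so that whitespace-flexible
  variants can never span two fields;
* **full text** — the document truncated at a references/bibliography
  heading, since a dictionary hit inside a reference list cites someone
  else's experiment;
* **model sentences** — the subset of full-text sentences containing a cue
  phrase ("obtained from", "backcrossed", "transgenic", ...), the place
  where papers say which animals they actually used. Model, sex and species
  dictionaries are applied to this extract; intervention dictionaries never
  leave tiabkw (drug synonyms are too unspecific in full text — a compound
  can be an intervention in one study and a culture medium in the next).

The sentence splitter is rule-based (period/question/exclamation followed by
whitespace and a capital or digit, with an English abbreviation guard list
and an initials guard) — deliberately not a statistical model, so the same
input always yields the same sentences. The cue list is versioned
configuration: the original extractor behind the production pipeline is
unpublished, so parity is not claimed; acceptance is defined against the
declared cue list.

When a citation has no full text, the full-text and model-sentence results
are *omitted*, not zero-filled: "no text available" and "no mention in the
text" are different statements, and the validation harness needs to
distinguish them.

## The tagging policy

A tag is assigned when any enabled surface reaches its threshold. The
default policy is the validated combination rule:

| category | rule |
|---|---|
| model, species, sex | ≥ 1 tiabkw **or** ≥ 1 in model sentences |
| outcome | ≥ 1 tiabkw **or** ≥ 2 in full text |
| intervention | ≥ 1 tiabkw only |

"More than one match" thresholds are strict: *full text > 1* means a count
of at least 2. A **high-sensitivity** toggle additionally assigns model,
intervention and outcome tags on any single full-text mention — for
systematic-review exports where missing a study is worse than admitting
false positives. Monotonicity (the high-sensitivity set is a superset of the
default set; raising any threshold never adds assignments) is enforced by
property tests.

Assignment is a pure function of the stored per-surface counts and the
policy, so any assignment can be replayed from its evidence; the policy and
lexicon versions (content hashes) ride along on every row. Incremental runs
re-tag only citations new since the previous run, unless either version
changed — any dictionary or policy edit forces a full re-tag, trading
compute for auditability.

## Validating tagging methods and selecting the policy

Candidate methods per category are: tiabkw ≥ 1; full text > 0, > 1, > 2;
and model sentence ≥ 1 (model/sex/species only). A human reviewer marks each
candidate tag TRUE or FALSE on a validation sample drawn uniformly from the
stratum of records fully tagged in every required category under every
method (so every method can be scored on every sampled record); records
discovered to be conference abstracts are marked `skip` and leave all
counts.

True sensitivity is not estimable this way — nobody knows how many studies
using a model were never tagged at all — so the reference set is defined as
the union of verdict-TRUE tags found by *any* method. For each method, TP
and FP come from the tags it proposes (replayed from the evidence counts,
never trusted from the annotation sheet), FN are reference tags it missed,
and TN are verdict-FALSE candidates it did not propose. Precision,
specificity and this "versus all methods" sensitivity follow the standard
formulas and are reported at three decimals, rounded half-up, with the raw
fractions retained internally; a zero denominator leaves a metric undefined
rather than failing.

Policy selection is precision-primary: a method is admitted when its
precision exceeds `floor - tolerance` (defaults 0.80 and 0.01). The
tolerance exists because a strictly enforced 0.80 floor would reject a
model-sentence method at precision 0.793 that practitioners judge good
enough; admitting it silently would hide that judgement, so near-miss
admissions warn. Among admitted non-tiabkw methods, those within a 0.05
precision window of the best are treated as having similar precision and
the most sensitive of them is enabled — a plain "highest sensitivity among
admitted" rule would always pick *full text > 0* (sensitivity 1 by
construction) and throw the precision gains away. When no method clears the
floor and only one method exists for a category (the intervention
dictionary's tiabkw-only situation), that method is enabled with a warning
rather than leaving the category untaggable; with several candidates and no
admission, selection stops and asks for a manual choice.

Applied to the bundled published validation table this procedure reproduces
the production tagging logic exactly, near-miss warning included. The
bundled table carries both the printed metric cells and the raw confusion
counts; for a few rows the printed precision differs from the counts in the
third decimal, so the table keeps both and each analysis states which it
uses (selection consumes the metrics as printed; metric-reproduction checks
recompute from the counts).

## Deduplication and search updates

Two records merge when they share a normalised DOI (lowercased, resolver
prefix stripped), or when no DOI conflict exists and their normalised titles
(lowercase, punctuation stripped, diacritics folded, whitespace collapsed)
reach edit-distance similarity ≥ 0.95 with the same year and first-author
surname. Pairwise matches close transitively; each group keeps one record,
preferring an abstract, then a DOI, then the smallest uid — deterministic,
idempotent and order-insensitive, all property-tested. This is a declared,
versioned subset of what full deduplication services do; parity with their
manual-review queues and field-weight models is not claimed.

Weekly updates deduplicate incoming records against themselves and against
the previous 62 days of the store ("the previous two months", read
conservatively), appending only novel records; a full-store pass run
periodically catches duplicates of older records. Records lacking retrieval
dates fall back to comparison against the whole store, with a warning.

Abstract-only flagging requires positive evidence: no usable full text
(none attached, or fewer than `min_words = 500` words) *and* either a
meeting/conference-abstract publication type or single-page pagination.
Records with no metadata are left unflagged, and flagged records are
excluded from reporting, never deleted. Retraction is an input column
(sourced upstream from registries); retracted records are excluded from all
reporting.

## Screening

The production in vivo classifier is an external service and is deliberately
out of scope; what the package defines is the *scorer contract* — any
deterministic-given-seed function from title+abstract text to an inclusion
probability — plus a transparent baseline: ridge-penalised logistic
regression (glmnet, fixed λ = 0.05, no cross-validation) on sparse token
counts. Ties at the decision threshold count as included (≥ 0.5 by
default). Evaluation uses a stratified held-out split (20% per class,
seed-controlled) since the production validation protocol is unstated, and
every run appends a row — counts, metrics, threshold, training size — to an
append-only log; `performance_drift()` flags runs breaching sensitivity
0.90 or specificity 0.85, the signal that more training data are needed.
The production classifier's published averages depend on its external model
and corpus and are not reproduced here; the scorer contract is instead
validated on synthetic regimes (below).

## What the synthetic corpus does and does not emulate

`generate_corpus()` builds citation sets with planted ground truth: terms
embedded in template filler sentences (so sentence splitting and cue
detection are realistically exercised, rather than matching against word
soup), placements spanning title, abstract, full-text body, model sentences
and reference lists, confusable lookalikes (`PAPP`, `APP23`) for boundary
pitfalls, and a fraction of records duplicated with case/punctuation
perturbations. Reference-list placements are excluded from the ground truth
— finding them would be a false positive. The screening generator draws
inclusion texts from an in-vivo vocabulary and exclusions from a clinical
one, with a shift parameter running from perfectly separable to identical
distributions.

Passing these suites shows the machinery is correct: exact planted-tag
recovery, boundary behaviour, policy monotonicity, dedup idempotence, chance
behaviour at full vocabulary shift. It does **not** show that production
dictionaries achieve any particular precision on real text — real abstracts
misspell models, coin new ones and mention competitors' drugs — which is
exactly why the validation harness and its sampling machinery are part of
the package rather than a one-off analysis.

## Numerical conventions and problem sizes

Reported metrics and coverage percentages round half-up (0.0625 → 0.063 at
three decimals; 46.05% → 46.1% at one), implemented against an exact
integer-arithmetic oracle. Test and check sizes are chosen to keep the full
suite near a minute on a laptop while still exercising every rule: corpora
of 10–100 records, 1000 random short texts for the match-count oracle, the
exhaustive metric sweep over all confusion 4-tuples with entries ≤ 50, and
screening sets of 200 texts.

## Known limitations

Dictionary coverage is inherently behind the literature: pathological
(non-behavioural) outcomes, non-rodent models and novel therapeutics are
not in the shipped synthetic dictionaries, and statistical NER is out of
scope. The dedup rules are a deterministic subset of full services. The
model-sentence cue list is a curated approximation of an unpublished
extractor. Risk-of-bias, open-data and open-access columns are accepted as
inputs computed by external tools, and the interactive dashboard itself is
downstream of the tables this package emits.
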