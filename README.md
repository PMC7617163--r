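# soles

A curation engine for **systematic online living evidence summaries**
(SOLES): continuously updated, machine-curated maps of a research
literature, here oriented at in vivo experiments in animal models of
Alzheimer's disease. It is written for evidence-synthesis teams who run
such pipelines — and for systematic reviewers who want its pieces
(deduplication, dictionary tagging, tagging validation) on their own
corpora.

The package covers the full curation loop:

* **Ingest** — citation records from RIS, MEDLINE/PubMed XML or a flat CSV
  dialect; full texts as plain-text files or CSV; deterministic uids;
  deterministic merge of weekly search updates.
* **Deduplicate** — records merge on identical normalised DOI, or on
  title similarity ≥ 0.95 with matching year and first-author surname and
  no DOI conflict; transitive closure, deterministic keep-rule, idempotent.
* **Tag** — term lists compile to boundary-anchored, variant-expanded
  regular expressions (letters *and* digits are word characters, so `APP`
  never fires inside `PAPP` or `APP23`); matching runs over three surfaces:
  title/abstract/keywords ("tiabkw"), full text, and extracted
  model-description sentences.
* **Validate & select** — human TRUE/FALSE annotations score every
  (category, method) pair as a confusion matrix; sensitivity is computed
  against the union of verified tags across all methods
  (`sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
  `precision = TP/(TP+FP)`, `F1 = 2TP/(2TP+FP+FN)`), and
  `select_policy()` turns the score table into the per-category
  frequency-threshold policy (precision > 0.80 with a declared tolerance;
  sensitivity breaks near-ties).
* **Screen** — a pluggable scorer contract for in vivo relevance
  classification with a transparent bag-of-words ridge-logistic baseline
  and an append-only per-run performance log with drift monitoring.
* **Report** — per-year counts, tag coverage, co-occurrence gap maps,
  and Boolean (`AND`/`OR`, quoted phrases, parentheses) filtered exports
  with a high-sensitivity toggle.
* **Fixtures** — a synthetic-corpus generator with planted ground truth,
  so the whole pipeline is testable without any download.

## Worked example

Tag a small synthetic corpus with the bundled dictionaries and inspect the
evidence behind each assignment:

```r
library(soles)

lex  <- synthetic_lexicons()
corp <- generate_corpus(corpus_spec(
  20, fulltext_fraction = 0.8,
  planted = data.frame(
    category  = c("model", "outcome", "intervention", "sex"),
    label     = c("APP/PS1", "Morris water maze", "donepezil", "female"),
    placement = c("title", "fulltext_body", "abstract", "model_sentence"),
    copies    = c(1, 2, 1, 1)),
  seed = 42))

tags <- tag_corpus(corp$citations, corp$fulltexts, lex)
head(as.data.frame(tags[tags$label != "(none)", 1:7]), 5)
#>        uid     category             label assigned tiabkw_count fulltext_count
#> 1 syn:0001 intervention         donepezil     TRUE            1              0
#> 2 syn:0001        model           APP/PS1     TRUE            1              0
#> 3 syn:0001      outcome Morris water maze     TRUE            0              2
#> 4 syn:0001          sex            female     TRUE            0              1
#> 5 syn:0002 intervention         donepezil     TRUE            1              0
#>   model_sentence_count
#> 1                   NA
#> 2                    0
#> 3                   NA
#> 4                    1
#> 5                   NA
```

Each row is replayable: `assigned` is a pure function of the three evidence
counts and the policy (the outcome tag above holds because two full-text
mentions meet the "≥ 2 in full text" rule; the sex tag because one
model-sentence match suffices; `NA` means that surface does not apply).
Coverage is the dashboard's headline statistic:

```r
tag_coverage(tags, nrow(corp$citations))
#>       category n_tagged percent
#> 1 intervention       20     100
#> 2        model       20     100
#> 3      outcome       16      80
#> 4          sex       16      80
```

Re-deriving the production tagging logic from the bundled validation study
(a 98-article manual check of every candidate tag):

```r
select_policy(tagging_validation_table())
#> <tag policy 3e1120eee18f>
#>   model         tiabkw >= 1 OR model sentence >= 1
#>   sex           tiabkw >= 1 OR model sentence >= 1
#>   species       tiabkw >= 1 OR model sentence >= 1
#>   outcome       tiabkw >= 1 OR fulltext >= 2
#>   intervention  tiabkw >= 1
```

(with warnings flagging the model-sentence near miss at precision 0.793 and
the intervention fallback). The metric formulas themselves:

```r
compute_metrics(104, 14, 195, 39)
#>   sensitivity specificity precision    f1
#> 1       0.727       0.933     0.881 0.797
```

A thin command-line front end (`inst/cli/soles.R`) wraps the same functions
for shell use: `ingest`, `dedup`, `lexicon-compile`, `tag`,
`validate-score`, `select-policy`, `report-years`, `report-coverage`,
`export`, `fixtures-make`.

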