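# Match counting, surfaces, and policy application.

test_that("longest surface form wins and spans are consumed once", {
  mwm <- tiny_outcome_lexicon()$patterns[[1]]
  r <- count_matches(mwm, "The Morris water maze (MWM) was used")
  expect_equal(r$count, 2)   # "Morris water maze" + "MWM"; inner "water maze" not re-counted
  expect_equal(r$spans[1, ], c(start = 4, end = 21))
  expect_equal(r$spans[2, ], c(start = 23, end = 26))
  expect_equal(substr("The Morris water maze (MWM) was used",
                      r$spans[1, 1] + 1, r$spans[1, 2]), "Morris water maze")

  expect_equal(count_matches(mwm, "")$count, 0)
  expect_equal(nrow(count_matches(mwm, "")$spans), 0)

  p <- compile_term("APP")
  expect_equal(count_matches(p, "PAPP and APP and APP23")$count, 1)
})

test_that("count_matches agrees with the brute-force oracle on random texts", {
  pats <- list(
    compile_term("APP"),
    compile_term("Morris water maze", c("water maze", "MWM", "Morris maze"), "outcome"),
    compile_term("5xFAD", category = "model"),
    compile_term("rat", "rats", "species")
  )
  for (p in pats) {
    texts <- random_match_texts(60, p$variants[seq_len(min(3, length(p$variants)))],
                                seed = 100 + nchar(p$label))
    for (txt in texts) {
      expect_equal(count_matches(p, txt)$count, brute_force_count(p, txt),
                   info = paste(p$label, "|", txt))
    }
  }
})

test_that("tag_fields emits per-surface results and omits absent surfaces", {
  cit <- make_citations(list(uid = "u1", title = "5xFAD performance study",
                             abstract = "", year = 2020))
  doc <- paste("The 5xFAD line was tested twice: 5xFAD again.",
               "Mice were obtained from a 5xFAD colony.")
  res <- tag_fields(cit, doc, tiny_model_lexicon())
  r5 <- res[res$label == "5xFAD", ]
  expect_setequal(r5$field, c("tiabkw", "fulltext", "model_sentence"))
  expect_equal(r5$count[r5$field == "tiabkw"], 1L)
  expect_equal(r5$count[r5$field == "fulltext"], 3L)
  expect_equal(r5$count[r5$field == "model_sentence"], 1L)

  # no abstract/keywords, label absent from title -> tiabkw 0
  expect_equal(res$count[res$label == "APP/PS1" & res$field == "tiabkw"], 0L)

  # doc absent: fulltext/model_sentence omitted, not zero-filled
  res2 <- tag_fields(cit, NULL, tiny_model_lexicon())
  expect_setequal(unique(res2$field), "tiabkw")

  # intervention category never gets a model_sentence surface
  ilex <- lexicon(data.frame(label = "donepezil"), "intervention")
  res3 <- tag_fields(cit, doc, ilex)
  expect_setequal(unique(res3$field), c("tiabkw", "fulltext"))
})

test_that("policy application reproduces the validated combination logic", {
  mk <- function(uid, category, label, field, count) {
    tibble::tibble(uid = uid, category = category, label = label,
                   field = field, count = as.integer(count))
  }
  pol <- default_policy()
  # outcome: one full-text mention is not enough
  r <- apply_policy(rbind(mk("u", "outcome", "rotarod", "tiabkw", 0),
                          mk("u", "outcome", "rotarod", "fulltext", 1)), pol)
  expect_false(r$assigned)
  # ...but two are
  r2 <- apply_policy(rbind(mk("u", "outcome", "rotarod", "tiabkw", 0),
                           mk("u", "outcome", "rotarod", "fulltext", 2)), pol)
  expect_true(r2$assigned)
  # model: one model-sentence match suffices
  r3 <- apply_policy(rbind(mk("u", "model", "5xFAD", "tiabkw", 0),
                           mk("u", "model", "5xFAD", "model_sentence", 1)), pol)
  expect_true(r3$assigned)
  # intervention: full text never assigns under the default policy
  r4 <- apply_policy(rbind(mk("u", "intervention", "donepezil", "tiabkw", 0),
                           mk("u", "intervention", "donepezil", "fulltext", 5)), pol)
  expect_false(r4$assigned)
  # ...unless high sensitivity is on
  r5 <- apply_policy(rbind(mk("u", "intervention", "donepezil", "tiabkw", 0),
                           mk("u", "intervention", "donepezil", "fulltext", 5)),
                     default_policy(high_sensitivity = TRUE))
  expect_true(r5$assigned)
  # unknown category is an error
  expect_error(apply_policy(mk("u", "model2", "x", "tiabkw", 1), pol),
               "no policy entry")
})

test_that("policy constructor validates thresholds", {
  expect_error(tag_policy(list(model = list())), "no threshold")
  expect_error(tag_policy(list(model = list(tiabkw_min = 0))), ">= 1")
  f <- tempfile(fileext = ".yaml")
  write_policy(default_policy(), f)
  expect_equal(read_policy(f)$version, default_policy()$version)
})

test_that("corpus tagging recovers planted labels and is deterministic", {
  lex <- synthetic_lexicons()
  spec <- corpus_spec(50, fulltext_fraction = 1, planted = data.frame(
    category = c("model", "outcome", "intervention", "sex", "species"),
    label = c("Tg2576", "Barnes maze", "memantine", "female", "rat"),
    placement = c("title", "fulltext_body", "abstract", "model_sentence",
                  "model_sentence"),
    copies = c(1, 2, 1, 1, 1)), seed = 13)
  corp <- generate_corpus(spec)
  tags <- tag_corpus(corp$citations, corp$fulltexts, lex)
  hit <- unique(tags[tags$assigned & tags$label != "(none)",
                     c("uid", "category", "label")])
  truth <- corp$truth$tags
  expect_equal(nrow(dplyr::anti_join(hit, truth, by = names(truth))), 0)
  expect_equal(nrow(dplyr::anti_join(truth, hit, by = names(truth))), 0)

  # re-run with identical versions is byte-identical
  tags2 <- tag_corpus(corp$citations, corp$fulltexts, lex)
  expect_identical(as.data.frame(tags), as.data.frame(tags2))

  # empty corpus
  empty <- tag_corpus(citation_set(), NULL, lex)
  expect_equal(nrow(empty), 0)
})

test_that("untagged categories get an explicit marker row", {
  cit <- make_citations(list(uid = "u1", title = "Nothing of note",
                             abstract = "Plain text."))
  tags <- tag_corpus(cit, NULL, list(tiny_model_lexicon(), tiny_outcome_lexicon()))
  expect_setequal(tags$category, c("model", "outcome"))
  expect_true(all(tags$label == "(none)"))
  expect_false(any(tags$assigned))
})

test_that("incremental tagging re-tags only new citations unless versions change", {
  lex <- list(tiny_model_lexicon())
  c1 <- make_citations(list(uid = "a", title = "5xFAD study"))
  t1 <- tag_corpus(c1, NULL, lex)
  c2 <- make_citations(list(uid = "a", title = "5xFAD study"),
                       list(uid = "b", title = "APP/PS1 study"))
  t2 <- tag_corpus(c2, NULL, lex, previous = t1)
  expect_setequal(t2$uid, c("a", "b"))
  expect_identical(t2[t2$uid == "a", ], t1[t1$uid == "a", ])
  # a changed policy version forces a full re-tag (assignments recomputed)
  pol_hs <- default_policy(high_sensitivity = TRUE)
  t3 <- tag_corpus(c2, NULL, lex, policy = pol_hs, previous = t1)
  expect_true(all(t3$policy_version == pol_hs$version))
})

test_that("high-sensitivity assignments are a superset; raising thresholds never adds tags", {
  lex <- synthetic_lexicons()
  corp <- generate_corpus(corpus_spec(40, fulltext_fraction = 0.7,
    planted = data.frame(
      category = c("model", "outcome", "intervention"),
      label = c("J20", "rotarod", "curcumin"),
      placement = c("fulltext_body", "fulltext_body", "fulltext_body"),
      copies = c(1, 1, 1)), seed = 17))
  t_def <- tag_corpus(corp$citations, corp$fulltexts, lex)
  t_hs <- tag_corpus(corp$citations, corp$fulltexts, lex,
                     policy = default_policy(high_sensitivity = TRUE))
  key <- function(t) paste(t$uid, t$category, t$label)[t$assigned & t$label != "(none)"]
  expect_true(all(key(t_def) %in% key(t_hs)))
  expect_gt(length(key(t_hs)), length(key(t_def)))   # single full-text mentions admitted

  # raising a threshold can only shrink the assignment set
  strict <- tag_policy(list(
    model = list(tiabkw_min = 1L, model_sentence_min = 2L),
    species = list(tiabkw_min = 1L, model_sentence_min = 2L),
    sex = list(tiabkw_min = 1L, model_sentence_min = 2L),
    outcome = list(tiabkw_min = 1L, fulltext_min = 3L),
    intervention = list(tiabkw_min = 2L)
  ))
  t_strict <- tag_corpus(corp$citations, corp$fulltexts, lex, policy = strict)
  expect_true(all(key(t_strict) %in% key(t_def)))
})

test_that("stored assignments replay exactly from their evidence", {
  lex <- synthetic_lexicons()
  corp <- generate_corpus(corpus_spec(30, fulltext_fraction = 0.6,
    planted = data.frame(category = c("model", "outcome"),
                         label = c("PS19", "Y-maze"),
                         placement = c("model_sentence", "abstract"),
                         copies = c(1, 1)), seed = 19))
  pol <- default_policy()
  tags <- tag_corpus(corp$citations, corp$fulltexts, lex, policy = pol)
  ev <- tags[tags$label != "(none)", ]
  replayed <- vapply(seq_len(nrow(ev)), function(i) {
    soles:::policy_assigns(pol, ev$category[i], ev$tiabkw_count[i],
                           ev$fulltext_count[i], ev$model_sentence_count[i])
  }, logical(1))
  expect_equal(replayed, ev$assigned)
})

test_that("tag export writes the long-format CSV", {
  lex <- list(tiny_model_lexicon())
  cit <- make_citations(list(uid = "u1", title = "A 5xFAD experiment"))
  tags <- tag_corpus(cit, NULL, lex)
  f <- tempfile(fileext = ".csv")
  write_tags(tags, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_setequal(names(back),
                  c("uid", "category", "label", "assigned", "tiabkw_count",
                    "fulltext_count", "model_sentence_count", "policy_version",
                    "lexicon_version"))
  expect_equal(back$assigned[back$label == "5xFAD"], TRUE)
})
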