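# Synthetic corpora with planted ground truth. Every other module is
# testable end-to-end from these generators, without any download.

#' Load the bundled synthetic lexicons
#'
#' Small hand-verifiable dictionaries (12 models, 10 outcomes, 15
#' interventions, 4 species, 2 sexes) shipped as lexicon CSVs under
#' `extdata`. They emulate the shape of production dictionaries — synonyms,
#' group hierarchies, acronyms — at a size where every pattern can be checked
#' by eye.
#'
#' @return named list of `soles_lexicon` objects, one per category.
#' @export
synthetic_lexicons <- function() {
  files <- c(model = "synthetic_models.csv", outcome = "synthetic_outcomes.csv",
             intervention = "synthetic_interventions.csv",
             species = "synthetic_species.csv", sex = "synthetic_sex.csv")
  out <- lapply(names(files), function(cat) {
    load_lexicon(system.file("extdata", files[[cat]], package = "soles",
                             mustWork = TRUE), cat)
  })
  stats::setNames(out, names(files))
}

#' Specify a synthetic corpus
#'
#' @param n_citations number of base records (>= 1).
#' @param fulltext_fraction fraction of records with a full text attached.
#' @param planted data frame with columns `category`, `label`, `placement`
#'   (one of `title`, `abstract`, `fulltext_body`, `model_sentence`,
#'   `references_only`) and `copies`; each row is planted into every record
#'   (full-text placements only materialise in records that have a full
#'   text).
#' @param confusables character vector of lookalike strings (e.g. `"PAPP"`)
#'   planted into every abstract to exercise boundary behaviour.
#' @param duplicate_fraction fraction of records duplicated with
#'   case/punctuation perturbations.
#' @param seed integer seed; the whole corpus is deterministic given it.
#' @return a `soles_corpus_spec` list.
#' @export
corpus_spec <- function(n_citations, fulltext_fraction = 0.8, planted = NULL,
                        confusables = character(), duplicate_fraction = 0,
                        seed = 1L) {
  stopifnot(n_citations >= 1,
            fulltext_fraction >= 0, fulltext_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  if (is.null(planted)) {
    planted <- data.frame(category = character(), label = character(),
                          placement = character(), copies = integer())
  }
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  if (nrow(planted) > 0) {
    stopifnot(all(planted$placement %in% c("title", "abstract", "fulltext_body",
                                           "model_sentence", "references_only")),
              all(planted$copies >= 1))
  }
  structure(list(n_citations = as.integer(n_citations),
                 fulltext_fraction = fulltext_fraction, planted = planted,
                 confusables = confusables,
                 duplicate_fraction = duplicate_fraction, seed = as.integer(seed)),
            class = "soles_corpus_spec")
}

# Filler sentence pools. Deliberately free of dictionary terms, cue phrases
# and sex/species words so planted content is the only signal.
FILLER_TITLES <- c(
  "Longitudinal assessment of a preclinical cohort",
  "Dose-response characterisation under standard protocols",
  "Quantitative evaluation of repeated testing schedules",
  "A controlled comparison of laboratory procedures"
)
FILLER_SENTENCES <- c(
  "Experimental groups were compared using standard protocols.",
  "Assessments were repeated at fixed intervals across the study period.",
  "Data were analysed with mixed-effects regression.",
  "All procedures followed institutional guidelines.",
  "Group allocation lists were prepared in advance by the core facility.",
  "Measurements were recorded by trained personnel."
)
FILLER_KEYWORDS <- c("preclinical", "cohort", "longitudinal", "protocol",
                     "dose-response", "laboratory")
FILLER_SURNAMES <- c("Ainsworth", "Baptiste", "Cardoso", "Delacroix", "Eriksen",
                     "Fontaine", "Grieve", "Holloway", "Ivanova", "Jablonski")

plant_sentence <- function(placement, label, k) {
  switch(placement,
    abstract = sprintf("We examined %s in this cohort.", label),
    fulltext_body = sprintf("%s was evaluated in the present experiments (set %d).", label, k),
    model_sentence = sprintf("Animals were obtained from a commercial supplier and %s colonies were maintained under standard housing.", label),
    references_only = sprintf("%d. Roe A, Doe B. Prior observations on %s. J Res. 2018.", k, label)
  )
}

#' Generate a synthetic citation corpus with planted ground truth
#'
#' Planted terms are embedded in natural-ish template sentences (so sentence
#' splitting and cue detection are exercised realistically): `title` /
#' `abstract` placements feed the tiabkw surface, `fulltext_body` the full
#' text, `model_sentence` a sentence carrying an "obtained from" cue, and
#' `references_only` a numbered entry *after* a "References" heading —
#' excluded from the ground truth, since a reference-list mention is not
#' usage. Confusable strings are planted in every abstract. A
#' `duplicate_fraction` of records is emitted twice with case/punctuation
#' perturbations and recorded in the truth's duplicate groups.
#'
#' @param spec a [corpus_spec()].
#' @return list with `citations` (a `soles_citations`), `fulltexts` (tibble
#'   `uid,text,char_count,origin_format`) and `truth` (list with `tags`, a
#'   tibble `uid,category,label`; and `duplicates`, a list of uid groups).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "soles_corpus_spec"))
  n <- spec$n_citations
  with_seed(spec$seed, {
    has_ft <- rep(FALSE, n)
    n_ft <- round(spec$fulltext_fraction * n)
    if (n_ft > 0) has_ft[sample.int(n, n_ft)] <- TRUE
    planted <- spec$planted
    title_terms <- planted$label[planted$placement == "title"]
    abstract_rows <- which(planted$placement == "abstract")
    ft_rows <- which(planted$placement %in% c("fulltext_body", "model_sentence"))
    ref_rows <- which(planted$placement == "references_only")

    recs <- vector("list", n)
    fts <- list()
    truth_rows <- list()
    for (i in seq_len(n)) {
      uid <- sprintf("syn:%04d", i)
      # a per-record code keeps unrelated titles below any plausible
      # similarity threshold while perturbed duplicates still match
      code <- paste(sample(LETTERS, 8, replace = TRUE), collapse = "")
      title <- if (length(title_terms)) {
        sprintf("Effects of %s: a longitudinal assessment (cohort %s)",
                paste(title_terms, collapse = " and "), code)
      } else {
        sprintf("%s (cohort %s)", sample(FILLER_TITLES, 1), code)
      }
      abs_sents <- sample(FILLER_SENTENCES, 3)
      for (r in abstract_rows) {
        abs_sents <- c(abs_sents,
                       rep(plant_sentence("abstract", planted$label[r], 1),
                           planted$copies[r]))
      }
      for (cf in spec$confusables) {
        abs_sents <- c(abs_sents, sprintf("Serum %s levels were also recorded.", cf))
      }
      abstract <- paste(abs_sents, collapse = " ")
      if (has_ft[i] && (length(ft_rows) || length(ref_rows))) {
        body <- c(sample(FILLER_SENTENCES, 2))
        for (r in ft_rows) {
          body <- c(body, vapply(seq_len(planted$copies[r]), function(k) {
            plant_sentence(planted$placement[r], planted$label[r], k)
          }, character(1)))
        }
        body <- c(body, sample(FILLER_SENTENCES, 2))
        text <- paste(body, collapse = " ")
        if (length(ref_rows)) {
          refs <- unlist(lapply(ref_rows, function(r) {
            vapply(seq_len(planted$copies[r]), function(k) {
              plant_sentence("references_only", planted$label[r], k)
            }, character(1))
          }))
          text <- paste(text, "\nReferences\n", paste(refs, collapse = "\n"))
        }
        fts[[length(fts) + 1L]] <- tibble::tibble(uid = uid, text = text)
      } else if (has_ft[i]) {
        fts[[length(fts) + 1L]] <- tibble::tibble(
          uid = uid, text = paste(sample(FILLER_SENTENCES, 4), collapse = " "))
      }
      # ground truth: recoverable plantings only
      tr <- planted[planted$placement %in% c("title", "abstract") |
                      (has_ft[i] & planted$placement %in%
                         c("fulltext_body", "model_sentence")), , drop = FALSE]
      if (nrow(tr) > 0) {
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          uid = uid, category = tr$category, label = tr$label)
      }
      recs[[i]] <- tibble::tibble(
        uid = uid, title = title, abstract = abstract,
        keywords = list(sample(FILLER_KEYWORDS, 2)),
        authors = list(sprintf("%s, %s", sample(FILLER_SURNAMES, 2), c("A", "B"))),
        year = sample(2010:2023, 1),
        doi = if (stats::runif(1) < 0.9) sprintf("10.9999/synth.%d.%04d", spec$seed, i) else NA_character_,
        journal = "Journal of Synthetic Results", source_db = "other",
        retrieved = as.Date("2023-06-01")
      )
    }
    df <- dplyr::bind_rows(recs)
    dup_groups <- list()
    n_dup <- round(spec$duplicate_fraction * n)
    if (n_dup > 0) {
      dup_idx <- sample.int(n, n_dup)
      dups <- df[dup_idx, ]
      dups$uid <- paste0(dups$uid, "-dup")
      dups$doi <- NA_character_      # force the title/year/author rule
      dups$abstract <- ""            # keep-rule prefers the original
      dups$title <- toupper(gsub(",", "", paste0(dups$title, ".")))
      dups$source_db <- "wos"
      df <- dplyr::bind_rows(df, dups)
      dup_groups <- lapply(dup_idx, function(i) {
        c(sprintf("syn:%04d", i), sprintf("syn:%04d-dup", i))
      })
      # duplicates keep their (perturbed) titles, so title-planted tags are
      # still true for them; their abstracts are blanked and they carry no
      # full text
      title_rows <- planted[planted$placement == "title", , drop = FALSE]
      if (nrow(title_rows) > 0) {
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          uid = rep(dups$uid, each = nrow(title_rows)),
          category = rep(title_rows$category, nrow(dups)),
          label = rep(title_rows$label, nrow(dups))
        )
      }
    }
    citations <- citation_set(df)
    fulltexts <- if (length(fts)) dplyr::bind_rows(fts) else
      tibble::tibble(uid = character(), text = character())
    fulltexts$char_count <- nchar(fulltexts$text)
    fulltexts$origin_format <- rep("txt", nrow(fulltexts))
    truth <- list(
      tags = unique(dplyr::bind_rows(truth_rows)),
      duplicates = dup_groups
    )
    list(citations = citations, fulltexts = fulltexts, truth = truth)
  })
}

# Disjoint vocabularies for the screening task: laboratory in-vivo language
# versus clinical-study language.
INVIVO_VOCAB <- c(
  "transgenic", "littermates", "rodent", "cage", "housing", "injection",
  "intraperitoneal", "hippocampal", "plaque", "immunohistochemistry",
  "genotype", "wildtype", "behavioural", "locomotor", "perfusion",
  "sacrificed", "cortex", "neuronal", "amyloid", "stereotaxic", "probe",
  "latency", "vehicle", "saline", "histology"
)
CLINICAL_VOCAB <- c(
  "patients", "clinical", "trial", "caregivers", "diagnosis", "cognition",
  "questionnaire", "hospital", "dementia", "elderly", "community",
  "screening", "imaging", "biomarker", "cerebrospinal", "enrolment",
  "placebo", "randomised", "consent", "neuropsychological", "tomography",
  "participants", "symptoms", "prognosis", "comorbidity"
)

#' Generate a labelled screening set
#'
#' Inclusion texts draw from an in-vivo laboratory vocabulary, exclusions
#' from a clinical vocabulary; `vocabulary_shift` mixes the two (0 =
#' perfectly separable, 1 = identical word distributions, so held-out
#' performance approaches chance).
#'
#' @param n_pos,n_neg number of included / excluded texts (each >= 2).
#' @param vocabulary_shift overlap between class vocabularies, in `[0, 1]`.
#' @param seed integer seed.
#' @param words_per_text tokens per generated text (default 30).
#' @return list with `texts` (named character vector) and `decisions`
#'   (tibble `uid`, `included`, `n_reviewers = 2`).
#' @export
generate_screening_set <- function(n_pos, n_neg, vocabulary_shift = 0,
                                   seed = 1L, words_per_text = 30L) {
  if (n_pos < 2 || n_neg < 2) stop("need at least 2 texts per class")
  stopifnot(vocabulary_shift >= 0, vocabulary_shift <= 1)
  with_seed(seed, {
    make_text <- function(own, other) {
      from_other <- stats::runif(words_per_text) < vocabulary_shift / 2
      toks <- ifelse(from_other,
                     sample(other, words_per_text, replace = TRUE),
                     sample(own, words_per_text, replace = TRUE))
      paste(toks, collapse = " ")
    }
    uids <- sprintf("scr:%04d", seq_len(n_pos + n_neg))
    texts <- c(
      vapply(seq_len(n_pos), function(i) make_text(INVIVO_VOCAB, CLINICAL_VOCAB),
             character(1)),
      vapply(seq_len(n_neg), function(i) make_text(CLINICAL_VOCAB, INVIVO_VOCAB),
             character(1))
    )
    names(texts) <- uids
    decisions <- tibble::tibble(
      uid = uids,
      included = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
      n_reviewers = 2L
    )
    list(texts = texts, decisions = decisions)
  })
}
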