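# Match counting and the frequency-threshold tagging policy.

#' Count dictionary matches in a text
#'
#' Scans `text` with a compiled pattern using a leftmost, non-overlapping
#' scan; where several surface forms could match at the same position the
#' longest alternative wins and consumes its span, so "Morris water maze"
#' is one hit, not a hit plus an inner "water maze".
#'
#' @param pattern a `soles_pattern` from [compile_term()].
#' @param text character scalar to scan.
#' @param field which matching surface this text represents (`tiabkw`,
#'   `fulltext`, `model_sentence`); recorded on the result.
#' @param uid optional citation id recorded on the result.
#' @return a `soles_matches` list: `uid`, `label`, `category`, `field`,
#'   `count`, and `spans`, an n x 2 integer matrix of 0-based half-open
#'   character offsets into `text`.
#' @export
count_matches <- function(pattern, text, field = "tiabkw", uid = NA_character_) {
  stopifnot(inherits(pattern, "soles_pattern"))
  if (is.na(text) || !nzchar(text)) {
    spans <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
    return(structure(list(uid = uid, label = pattern$label,
                          category = pattern$category, field = field,
                          count = 0L, spans = spans), class = "soles_matches"))
  }
  m <- gregexpr(pattern$expression, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    spans <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  } else {
    start <- as.integer(m) - 1L                      # 0-based
    end <- start + attr(m, "match.length")           # half-open
    spans <- cbind(start = start, end = end)
  }
  structure(list(uid = uid, label = pattern$label, category = pattern$category,
                 field = field, count = nrow(spans), spans = spans),
            class = "soles_matches")
}

#' @export
print.soles_matches <- function(x, ...) {
  cat(sprintf("<matches: '%s' in %s, count %d>\n", x$label, x$field, x$count))
  invisible(x)
}

# Sentinel joining title/abstract/keywords: contains a non-whitespace
# control character so whitespace-flexible surface forms can never span two
# fields (a bare newline would be crossed by "\\s+").
TIABKW_SENTINEL <- "\n\u001f\n"

tiabkw_text <- function(citation_row) {
  paste(citation_row$title, citation_row$abstract,
        paste(citation_row$keywords[[1]], collapse = TIABKW_SENTINEL),
        sep = TIABKW_SENTINEL)
}

# Categories for which the model-sentence surface applies.
MODEL_SENTENCE_CATEGORIES <- c("model", "sex", "species")

#' Tag the matching surfaces of one citation
#'
#' Applies every pattern of a lexicon to the citation's tiabkw surface
#' (title + abstract + keywords, joined with an unmatchable sentinel), to the
#' full text when a document is supplied, and — for the model, sex and
#' species categories — to the concatenated model sentences extracted from
#' the full text. When no document is supplied the fulltext and
#' model-sentence results are *omitted*, not zero-filled, so "no text" stays
#' distinguishable from "no mention".
#'
#' @param citation a one-row `soles_citations` tibble.
#' @param doc full-text character scalar, or `NULL` when no text exists.
#' @param lex a `soles_lexicon`.
#' @param cues cue phrases for [extract_model_sentences()].
#' @return a tibble with columns `uid`, `category`, `label`, `field`, `count`.
#' @export
tag_fields <- function(citation, doc = NULL, lex, cues = default_model_cues()) {
  stopifnot(nrow(citation) == 1, inherits(lex, "soles_lexicon"))
  uid <- citation$uid
  tia <- tiabkw_text(citation)
  ms_text <- NULL
  if (!is.null(doc) && !is.na(doc) && lex$category %in% MODEL_SENTENCE_CATEGORIES) {
    ms_text <- paste(extract_model_sentences(doc, cues), collapse = "\n")
  }
  rows <- lapply(lex$patterns, function(p) {
    out <- list(count_matches(p, tia, field = "tiabkw", uid = uid))
    if (!is.null(doc) && !is.na(doc)) {
      out <- c(out, list(count_matches(p, strip_references(doc),
                                       field = "fulltext", uid = uid)))
      if (!is.null(ms_text)) {
        out <- c(out, list(count_matches(p, ms_text, field = "model_sentence",
                                         uid = uid)))
      }
    }
    out
  })
  rows <- unlist(rows, recursive = FALSE)
  tibble::tibble(
    uid = vapply(rows, `[[`, character(1), "uid"),
    category = vapply(rows, `[[`, character(1), "category"),
    label = vapply(rows, `[[`, character(1), "label"),
    field = vapply(rows, `[[`, character(1), "field"),
    count = vapply(rows, `[[`, integer(1), "count")
  )
}

# ---- policies ---------------------------------------------------------------

#' Construct a tagging policy
#'
#' A policy holds, per category, the minimum match counts per surface
#' (`tiabkw_min`, `fulltext_min`, `model_sentence_min`; `NULL` disables a
#' surface), plus a `high_sensitivity` flag. A tag is assigned when *any*
#' enabled surface reaches its threshold; with high sensitivity on, a single
#' full-text mention additionally assigns model, intervention and outcome
#' tags (trading precision for recall in systematic-review exports).
#'
#' @param categories named list, one entry per category, each a list with any
#'   of `tiabkw_min`, `fulltext_min`, `model_sentence_min` (integers >= 1).
#' @param high_sensitivity logical flag.
#' @return a `soles_policy`.
#' @export
tag_policy <- function(categories, high_sensitivity = FALSE) {
  for (cat in names(categories)) {
    p <- categories[[cat]]
    th <- unlist(p[c("tiabkw_min", "fulltext_min", "model_sentence_min")])
    if (length(th) == 0) stop("category '", cat, "' has no threshold set")
    if (any(th < 1)) stop("thresholds must be >= 1 (category '", cat, "')")
  }
  pol <- structure(list(categories = categories,
                        high_sensitivity = isTRUE(high_sensitivity)),
                   class = "soles_policy")
  pol$version <- substr(content_hash(yaml::as.yaml(unclass(pol))), 1, 12)
  pol
}

#' The default tagging policy
#'
#' The validated combination rule: model, species and sex assigned on >= 1
#' tiabkw match OR >= 1 match in the extracted model sentences; outcome on
#' >= 1 tiabkw match OR >= 2 full-text mentions; intervention on >= 1 tiabkw
#' match only (the intervention dictionary is too unspecific for full text).
#'
#' @param high_sensitivity enable the single-full-text-mention rule.
#' @return a `soles_policy`.
#' @export
default_policy <- function(high_sensitivity = FALSE) {
  tag_policy(list(
    model = list(tiabkw_min = 1L, model_sentence_min = 1L),
    species = list(tiabkw_min = 1L, model_sentence_min = 1L),
    sex = list(tiabkw_min = 1L, model_sentence_min = 1L),
    outcome = list(tiabkw_min = 1L, fulltext_min = 2L),
    intervention = list(tiabkw_min = 1L)
  ), high_sensitivity = high_sensitivity)
}

#' @export
print.soles_policy <- function(x, ...) {
  cat(sprintf("<tag policy %s%s>\n", x$version,
              if (x$high_sensitivity) ", high-sensitivity" else ""))
  for (cat_name in names(x$categories)) {
    p <- x$categories[[cat_name]]
    parts <- c(
      if (!is.null(p$tiabkw_min)) sprintf("tiabkw >= %d", p$tiabkw_min),
      if (!is.null(p$fulltext_min)) sprintf("fulltext >= %d", p$fulltext_min),
      if (!is.null(p$model_sentence_min)) sprintf("model sentence >= %d", p$model_sentence_min)
    )
    cat(sprintf("  %-13s %s\n", cat_name, paste(parts, collapse = " OR ")))
  }
  invisible(x)
}

#' Read / write a tagging policy as YAML
#'
#' The YAML mirrors the policy fields: one mapping per category with
#' `tiabkw_min` / `fulltext_min` / `model_sentence_min` keys, plus a
#' top-level `high_sensitivity` flag.
#'
#' @param path YAML file path.
#' @return [read_policy()] returns a `soles_policy`; [write_policy()] returns
#'   `path` invisibly.
#' @export
read_policy <- function(path) {
  y <- yaml::read_yaml(path)
  tag_policy(y$categories, high_sensitivity = isTRUE(y$high_sensitivity))
}

#' @rdname read_policy
#' @param policy a `soles_policy`.
#' @export
write_policy <- function(policy, path) {
  yaml::write_yaml(list(categories = policy$categories,
                        high_sensitivity = policy$high_sensitivity), path)
  invisible(path)
}

# Does the policy assign, given the per-surface evidence counts (NA = surface
# not available for this record)? Pure function of evidence and policy.
policy_assigns <- function(policy, category, tiabkw, fulltext, model_sentence) {
  p <- policy$categories[[category]]
  if (is.null(p)) stop("no policy entry for category '", category, "'")
  ok <- FALSE
  if (!is.null(p$tiabkw_min) && !is.na(tiabkw) && tiabkw >= p$tiabkw_min) ok <- TRUE
  if (!is.null(p$fulltext_min) && !is.na(fulltext) && fulltext >= p$fulltext_min) ok <- TRUE
  if (!is.null(p$model_sentence_min) && !is.na(model_sentence) &&
      model_sentence >= p$model_sentence_min) ok <- TRUE
  if (policy$high_sensitivity && category %in% c("model", "intervention", "outcome") &&
      !is.na(fulltext) && fulltext >= 1) ok <- TRUE
  ok
}

#' Apply a tagging policy to match results
#'
#' Folds long-format match results (one row per uid/label/surface) into one
#' tag assignment per (uid, category, label). Assignment is a pure function of
#' the evidence counts and the policy, so it can be replayed from the stored
#' evidence at any time.
#'
#' @param results tibble from [tag_fields()] (rows from several citations and
#'   lexicons may be concatenated).
#' @param policy a `soles_policy`.
#' @param lexicon_version version string recorded on the assignments.
#' @return a tibble with columns `uid`, `category`, `label`, `assigned`,
#'   `tiabkw_count`, `fulltext_count`, `model_sentence_count` (NA where the
#'   surface was unavailable), `policy_version`, `lexicon_version`.
#' @export
apply_policy <- function(results, policy, lexicon_version = "dev") {
  stopifnot(inherits(policy, "soles_policy"))
  missing_cat <- setdiff(unique(results$category), names(policy$categories))
  if (length(missing_cat)) {
    stop("results reference categories with no policy entry: ",
         paste(missing_cat, collapse = ", "))
  }
  pick1 <- function(x) if (length(x)) x[1] else NA_integer_
  ev <- dplyr::summarise(
    dplyr::group_by(results, .data$uid, .data$category, .data$label),
    tiabkw_count = pick1(.data$count[.data$field == "tiabkw"]),
    fulltext_count = pick1(.data$count[.data$field == "fulltext"]),
    model_sentence_count = pick1(.data$count[.data$field == "model_sentence"]),
    .groups = "drop"
  )
  ev$assigned <- vapply(seq_len(nrow(ev)), function(i) {
    policy_assigns(policy, ev$category[i], ev$tiabkw_count[i],
                   ev$fulltext_count[i], ev$model_sentence_count[i])
  }, logical(1))
  ev$policy_version <- policy$version
  ev$lexicon_version <- lexicon_version
  ev[, c("uid", "category", "label", "assigned", "tiabkw_count",
         "fulltext_count", "model_sentence_count", "policy_version",
         "lexicon_version")]
}

UNTAGGED_LABEL <- "(none)"

#' Tag a whole corpus
#'
#' Runs [tag_fields()] + [apply_policy()] over every citation and lexicon.
#' Labels with no evidence on any surface are dropped; a citation with no
#' evidenced label in a category receives an explicit `"(none)"` marker row.
#' Output is deterministic given the inputs and versions. When `previous` is
#' supplied and both the lexicon versions and the policy version are
#' unchanged, only citations absent from `previous` are re-tagged (any
#' version change forces a full re-tag).
#'
#' @param citations a `soles_citations` tibble.
#' @param fulltexts tibble from [read_fulltexts()], or `NULL`.
#' @param lexicons list of `soles_lexicon` objects (distinct categories).
#' @param policy a `soles_policy` (default [default_policy()]).
#' @param cues cue phrases for model-sentence extraction.
#' @param previous a prior `soles_tags` result for incremental runs.
#' @return a `soles_tags` tibble (the [apply_policy()] columns) with
#'   attributes `policy_version` and `lexicon_versions`.
#' @export
tag_corpus <- function(citations, fulltexts = NULL, lexicons,
                       policy = default_policy(), cues = default_model_cues(),
                       previous = NULL) {
  if (inherits(lexicons, "soles_lexicon")) lexicons <- list(lexicons)
  versions <- stats::setNames(
    vapply(lexicons, `[[`, character(1), "version"),
    vapply(lexicons, `[[`, character(1), "category")
  )
  if (anyDuplicated(names(versions))) stop("one lexicon per category, please")
  todo <- citations
  base <- NULL
  if (!is.null(previous) &&
      identical(attr(previous, "policy_version"), policy$version) &&
      identical(attr(previous, "lexicon_versions"), versions)) {
    todo <- citations[!citations$uid %in% previous$uid, ]
    base <- previous
  }
  ft_map <- if (!is.null(fulltexts)) stats::setNames(fulltexts$text, fulltexts$uid) else character()
  out_rows <- vector("list", nrow(todo))
  for (i in seq_len(nrow(todo))) {
    cit <- todo[i, ]
    doc <- if (cit$uid %in% names(ft_map)) ft_map[[cit$uid]] else NULL
    res <- dplyr::bind_rows(lapply(lexicons, function(lex) {
      tag_fields(cit, doc = doc, lex = lex, cues = cues)
    }))
    if (nrow(res) > 0) {
      keep_labels <- dplyr::summarise(
        dplyr::group_by(res, .data$category, .data$label),
        any_hit = any(.data$count > 0), .groups = "drop"
      )
      res <- dplyr::semi_join(res, keep_labels[keep_labels$any_hit, ],
                              by = c("category", "label"))
    }
    assigned <- if (nrow(res) > 0) {
      apply_policy(res, policy, lexicon_version = paste(versions, collapse = "+"))
    } else NULL
    # explicit untagged markers for categories with no evidenced label
    empty_cats <- setdiff(names(versions),
                          if (is.null(assigned)) character() else unique(assigned$category))
    if (length(empty_cats)) {
      marker <- tibble::tibble(
        uid = cit$uid, category = empty_cats, label = UNTAGGED_LABEL,
        assigned = FALSE, tiabkw_count = NA_integer_,
        fulltext_count = NA_integer_, model_sentence_count = NA_integer_,
        policy_version = policy$version,
        lexicon_version = paste(versions, collapse = "+")
      )
      assigned <- dplyr::bind_rows(assigned, marker)
    }
    out_rows[[i]] <- assigned
  }
  out <- dplyr::bind_rows(c(list(base), out_rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      uid = character(), category = character(), label = character(),
      assigned = logical(), tiabkw_count = integer(),
      fulltext_count = integer(), model_sentence_count = integer(),
      policy_version = character(), lexicon_version = character()
    )
  }
  out <- out[order(out$uid, out$category, out$label), ]
  attr(out, "policy_version") <- policy$version
  attr(out, "lexicon_versions") <- versions
  class(out) <- c("soles_tags", class(tibble::tibble()))
  out
}

#' Export tag assignments as long-format CSV
#'
#' @param tags a `soles_tags` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  utils::write.csv(as.data.frame(tags), path, row.names = FALSE, na = "")
  invisible(path)
}
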