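# Term-list compilation: variant expansion, boundary-anchored patterns,
# lexicon loading, and model-sentence extraction.

TAG_CATEGORIES <- c("model", "intervention", "outcome", "species", "sex")

# Greek letters commonly spelled out in AD text ("Abeta" for "Aβ").
GREEK_MAP <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "κ" = "kappa",
  "μ" = "mu", "τ" = "tau", "ω" = "omega"
)

greek_fold <- function(x) {
  for (g in names(GREEK_MAP)) x <- gsub(g, GREEK_MAP[[g]], x, fixed = TRUE)
  x
}

# Inter-token separators a surface form may use. Spaced forms of the
# multiplication signs are included so "3 × Tg" is generated verbatim.
SEPARATORS <- c(" ", "-", "x", "×", "*", "", " x ", " × ")

tokenize_term <- function(term) {
  parts <- strsplit(term,
                    "\\s*[-–—×*]\\s*|\\s+|(?<=[0-9])[xX](?=[A-Za-z])",
                    perl = TRUE)[[1]]
  parts[nzchar(parts)]
}

is_mixed_case <- function(tok) grepl("[a-z]", tok) && grepl("[A-Z]", tok)

case_forms <- function(tok) {
  if (is_mixed_case(tok)) unique(c(tok, toupper(tok))) else tok
}

# The trailing disease designator in model names ("3xTg-AD") is optional in
# running text ("the 3 × Tg model"), so a base form without it is added.
drop_disease_suffix <- function(term) {
  toks <- tokenize_term(term)
  if (length(toks) >= 2 && toupper(toks[length(toks)]) == "AD") {
    sub("[\\s–—-]*[aA][dD]\\s*$", "", term, perl = TRUE)
  } else {
    character()
  }
}

variant_forms <- function(term) {
  toks <- tokenize_term(term)
  if (length(toks) == 0) return(character())
  token_opts <- lapply(toks, case_forms)
  gaps <- length(toks) - 1L
  seps <- SEPARATORS
  total <- prod(lengths(token_opts)) * length(seps)^gaps
  if (total > 5000) {
    seps <- c(" ", "-", "")
    token_opts <- lapply(toks, function(t) t[1])
    total <- length(seps)^gaps
  }
  if (total > 5000) return(term)
  opts <- vector("list", 2L * length(toks) - 1L)
  opts[seq(1, length(opts), by = 2)] <- token_opts
  if (gaps > 0) opts[seq(2, length(opts), by = 2)] <- rep(list(seps), gaps)
  grid <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
  unique(do.call(paste0, grid))
}

#' Expand a term into its surface-form variants
#'
#' Generates the spelling variants a term may take in running text:
#' inter-token separators generalised over space, hyphen, the multiplication
#' signs `x`/`×` (with or without surrounding spaces), asterisk, and
#' nothing; upper-case variants of mixed-case tokens; spelled-out Greek
#' letters (so `Aβ` also yields `Abeta`); and, for model names carrying a
#' trailing `AD` token, the base name without the disease designator. The
#' original term is always first; the list is deduplicated.
#'
#' @param term a non-empty character scalar.
#' @return character vector of variants, original term first.
#' @export
#' @examples
#' expand_variants("Morris water maze")[1:6]
expand_variants <- function(term) {
  term <- as.character(term)
  stopifnot(length(term) == 1, !is.na(term), nzchar(trimws(term)))
  term <- trimws(term)
  bases <- unique(c(term, greek_fold(term)))
  bases <- unique(c(bases, unlist(lapply(bases, drop_disease_suffix))))
  out <- unique(unlist(lapply(bases, variant_forms)))
  unique(c(term, out))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# A single variant as a regex fragment: literal, with whitespace runs
# flexible so "Morris water maze" spans a line wrap.
variant_regex <- function(v) gsub(" +", "\\\\s+", escape_regex(v))

# Word characters are letters and digits (underscore excluded): "APP" must
# not match inside "PAPP" or "APP23", but may touch "/" in "APP/PS1".
BOUND_L <- "(?<![\\p{L}\\p{N}])"
BOUND_R <- "(?![\\p{L}\\p{N}])"

#' Compile a term entry into a boundary-anchored pattern
#'
#' Builds one regular expression per canonical label: the alternation of
#' [expand_variants()] over the label and all synonyms, each alternative
#' anchored on both sides by boundaries that treat letters *and digits* as
#' word characters. Alternatives are ordered longest-first so that at a match
#' position the longest surface form wins. Matching is case-insensitive
#' unless `case_sensitive`; when `case_sensitive = NULL` short all-caps
#' acronyms (<= 3 characters) default to case-sensitive to limit spurious
#' matches.
#'
#' @param label canonical name.
#' @param synonyms character vector of synonyms (may be empty).
#' @param category one of `model`, `intervention`, `outcome`, `species`, `sex`.
#' @param case_sensitive logical or `NULL` (auto rule above).
#' @param dictionary_version version string recorded on the pattern.
#' @param group optional parent group label.
#' @return a `soles_pattern`: list with `label`, `category`, `expression`,
#'   `variant_count`, `variants`, `case_sensitive`, `group`,
#'   `dictionary_version`.
#' @export
#' @examples
#' p <- compile_term("APP", case_sensitive = TRUE)
#' count_matches(p, "the APP gene")$count   # 1
#' count_matches(p, "PAPP")$count           # 0
compile_term <- function(label, synonyms = character(), category = "model",
                         case_sensitive = NULL, dictionary_version = "dev",
                         group = NA_character_) {
  stopifnot(length(label) == 1, nzchar(trimws(label)))
  synonyms <- unique(synonyms[!is.na(synonyms) & nzchar(trimws(synonyms))])
  bad <- c(label, synonyms)[!nzchar(trimws(gsub("[^\\p{L}\\p{N}]", "",
                                                c(label, synonyms), perl = TRUE)))]
  if (length(bad)) {
    stop("synonym compiles to an expression that can match the empty string: ",
         paste(sQuote(bad), collapse = ", "))
  }
  if (is.null(case_sensitive)) {
    case_sensitive <- nchar(label) <= 3 && label == toupper(label) &&
      grepl("[A-Z]", label)
  }
  variants <- unique(unlist(lapply(c(label, synonyms), expand_variants)))
  ord <- order(-nchar(variants), variants)
  variants <- variants[ord]
  body <- paste(vapply(variants, variant_regex, character(1)), collapse = "|")
  expr <- paste0(if (!case_sensitive) "(?i)", BOUND_L, "(?:", body, ")", BOUND_R)
  stopifnot(!is.na(regexpr(expr, "", perl = TRUE)))  # must compile
  structure(list(label = label, category = category, expression = expr,
                 variant_count = length(variants), variants = variants,
                 case_sensitive = case_sensitive, group = group,
                 dictionary_version = dictionary_version),
            class = "soles_pattern")
}

#' @export
print.soles_pattern <- function(x, ...) {
  cat(sprintf("<pattern '%s' (%s): %d variants, %s>\n", x$label, x$category,
              x$variant_count,
              if (x$case_sensitive) "case-sensitive" else "case-insensitive"))
  invisible(x)
}

new_lexicon <- function(patterns, category, version, source_file = NA_character_) {
  labels <- vapply(patterns, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate labels in lexicon: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(category = category, patterns = patterns, version = version,
                 source_file = source_file),
            class = "soles_lexicon")
}

#' Build a lexicon from an in-memory entry table
#'
#' @param entries data frame with columns `label`, and optionally `synonyms`
#'   (pipe-separated), `group`, `case_sensitive`.
#' @param category tag category for every entry.
#' @param version version string (default: hash of the entry contents).
#' @return a `soles_lexicon`.
#' @export
lexicon <- function(entries, category, version = NULL) {
  stopifnot(category %in% TAG_CATEGORIES)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) > 0 && any(!nzchar(trimws(entries$label)))) {
    stop("lexicon entries must have non-empty labels")
  }
  if (is.null(version)) {
    version <- substr(content_hash(paste(utils::capture.output(
      utils::write.csv(entries, stdout(), row.names = FALSE)), collapse = "\n")), 1, 12)
  }
  check_group_forest(entries)
  patterns <- lapply(seq_len(nrow(entries)), function(i) {
    syn <- if ("synonyms" %in% names(entries)) entries$synonyms[i] else ""
    syn <- if (is.na(syn) || !nzchar(syn)) character() else trimws(strsplit(syn, "|", fixed = TRUE)[[1]])
    cs <- if ("case_sensitive" %in% names(entries)) entries$case_sensitive[i] else NA
    cs <- if (is.na(cs) || (is.character(cs) && !nzchar(cs))) NULL else as.logical(cs)
    grp <- if ("group" %in% names(entries)) entries$group[i] else NA_character_
    if (is.na(grp) || !nzchar(grp)) grp <- NA_character_
    compile_term(trimws(entries$label[i]), syn, category = category,
                 case_sensitive = cs, dictionary_version = version, group = grp)
  })
  new_lexicon(patterns, category, version)
}

# Group labels must form a forest: a group may itself appear as a label with
# its own parent, but chains must not cycle.
check_group_forest <- function(entries) {
  if (!"group" %in% names(entries) || nrow(entries) == 0) return(invisible(TRUE))
  parent <- stats::setNames(as.character(entries$group), entries$label)
  for (start in names(parent)) {
    seen <- character()
    node <- start
    while (!is.na(parent[node] %||% NA_character_) && nzchar(parent[node] %||% "")) {
      if (node %in% seen) stop("group labels contain a cycle at: ", node)
      seen <- c(seen, node)
      node <- parent[[node]]
      if (!node %in% names(parent)) break
    }
  }
  invisible(TRUE)
}

#' Load a lexicon from CSV
#'
#' The CSV carries columns `label`, `synonyms` (pipe-separated), `group`,
#' `case_sensitive`. Every row is compiled with [compile_term()]; the lexicon
#' version is a content hash of the file, recorded on every pattern and
#' carried into downstream tag assignments.
#'
#' @param path CSV file path.
#' @param category tag category of the file.
#' @return a `soles_lexicon`.
#' @export
load_lexicon <- function(path, category) {
  stopifnot(category %in% TAG_CATEGORIES)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  version <- substr(file_hash(path), 1, 12)
  if (nrow(df) == 0) return(new_lexicon(list(), category, version, path))
  dup <- df$label[duplicated(df$label)]
  if (length(dup)) stop("duplicate labels in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  lex <- lexicon(df, category, version = version)
  lex$source_file <- path
  lex
}

#' @export
print.soles_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %s, %d labels, version %s>\n", x$category,
              length(x$patterns), x$version))
  invisible(x)
}

lexicon_labels <- function(lex) vapply(lex$patterns, `[[`, character(1), "label")

#' Built-in sex lexicon
#'
#' Simple male/female patterns for laboratory animals. Boundary anchoring
#' keeps "male" from firing inside "female".
#'
#' @return a `soles_lexicon` of category `sex`.
#' @export
sex_lexicon <- function() {
  lexicon(data.frame(label = c("male", "female"),
                     synonyms = c("males", "females"),
                     case_sensitive = c(FALSE, FALSE),
                     stringsAsFactors = FALSE),
          category = "sex", version = "builtin-sex-1")
}

#' Built-in species lexicon
#'
#' Patterns for the rodents most commonly used in neurodegeneration research,
#' with their inflections.
#'
#' @return a `soles_lexicon` of category `species`.
#' @export
species_lexicon <- function() {
  lexicon(data.frame(label = c("mouse", "rat"),
                     synonyms = c("mice|murine", "rats"),
                     case_sensitive = c(FALSE, FALSE),
                     stringsAsFactors = FALSE),
          category = "species", version = "builtin-species-1")
}

#' Export a compiled lexicon for audit
#'
#' Writes a plain-text dictionary file, one `label TAB expression` line per
#' pattern, so the compiled expressions can be deposited and versioned
#' alongside the source term list.
#'
#' @param lex a `soles_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_lexicon <- function(lex, path) {
  lines <- vapply(lex$patterns, function(p) paste(p$label, p$expression, sep = "\t"),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- sentence handling ------------------------------------------------------

# English abbreviations whose trailing period does not end a sentence.
ABBREVIATIONS <- c("al", "e.g", "i.e", "cf", "vs", "fig", "figs", "dr", "mr",
                   "mrs", "ms", "st", "no", "vol", "approx", "ca", "etc", "jr",
                   "resp", "eq", "ref", "refs")

#' Split text into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `?` or `!` followed by
#' whitespace and a capital letter, digit or opening quote/parenthesis, unless
#' the period terminates a known abbreviation ("et al.", "Fig.", "e.g."...).
#' Deterministic by construction; no statistical model.
#'
#' @param text character scalar.
#' @return character vector of sentences, in order.
#' @export
split_sentences <- function(text) {
  text <- gsub("\\s+", " ", trimws(text))
  if (!nzchar(text)) return(character())
  m <- gregexpr("[.?!]+(?=[\")\\]]*\\s[A-Z0-9(\"])", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1) {
    ends <- m + attr(m, "match.length") - 1L
    for (k in seq_along(m)) {
      punct <- substr(text, m[k], ends[k])
      if (grepl("\\.", punct)) {
        head_txt <- substr(text, 1, m[k] - 1L)
        word <- regmatches(head_txt, regexpr("[A-Za-z.]+$", head_txt))
        if (length(word) == 1 &&
            tolower(sub("\\.$", "", word)) %in% ABBREVIATIONS) next
        # single initials ("J. Smith") do not end sentences either
        if (length(word) == 1 && grepl("^[A-Z]$", word)) next
      }
      cuts <- c(cuts, ends[k])
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

# Truncate a document at a references/bibliography heading (on its own line)
# so dictionary hits inside reference lists are not mistaken for usage.
strip_references <- function(text) {
  m <- regexpr("(?im)^[[:space:]]*(references|bibliography|literature cited)[[:space:]]*$",
               text, perl = TRUE)
  if (m[1] != -1) substr(text, 1, m[1] - 1L) else text
}

#' Default cue list for model-description sentences
#'
#' Versioned configuration: the phrases that signal a sentence describes where
#' an animal model was obtained or how it was generated.
#'
#' @return character vector of cue phrases.
#' @export
default_model_cues <- function() {
  c("obtained from", "purchased from", "generated", "bred", "backcrossed",
    "background", "Jackson", "Charles River", "transgenic", "knock-in",
    "knockout", "crossed with", "supplied by")
}

#' Extract model-description sentences from a full text
#'
#' Splits the document (truncated at any references heading) into sentences
#' and returns, in original order and deduplicated, those containing at least
#' one cue phrase. Model, sex and species dictionaries applied to this
#' extract are far more specific than on the whole full text, where mentions
#' of other groups' models inflate false positives.
#'
#' @param text full-text character scalar.
#' @param cues character vector of cue phrases (default
#'   [default_model_cues()]).
#' @return character vector of sentences (possibly empty).
#' @export
extract_model_sentences <- function(text, cues = default_model_cues()) {
  stopifnot(length(cues) > 0)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  sents <- split_sentences(strip_references(text))
  if (length(sents) == 0) return(character())
  cue_re <- paste0("(?i)(?:", paste(vapply(cues, variant_regex, character(1)),
                                    collapse = "|"), ")")
  unique(sents[grepl(cue_re, sents, perl = TRUE)])
}
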