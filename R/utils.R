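# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Round half away from zero
#'
#' Base [round()] rounds half to even; reported metrics and coverage
#' percentages use conventional half-up rounding instead, so 0.0625 at three
#' decimals is 0.063, not 0.062.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # 1e-9 guards against quotients that sit a float ulp below the .5 boundary
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# md5 content hash of a character scalar (used for uids and dictionary/policy
# versions). Written through a tempfile so the base `tools` hasher can be used.
content_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

# Hash of a file's contents (lexicon versioning).
file_hash <- function(path) unname(tools::md5sum(path))

#' Normalise a DOI
#'
#' Lowercases and strips any `https://doi.org/` (or `http://dx.doi.org/`)
#' prefix and surrounding whitespace. Empty or missing input returns
#' `NA_character_`.
#'
#' @param doi character vector of DOIs as found in source records.
#' @return character vector of normalised DOIs.
#' @export
#' @examples
#' normalize_doi("https://doi.org/10.1/ABC")
normalize_doi <- function(doi) {
  out <- trimws(tolower(as.character(doi)))
  out <- sub("^https?://(dx\\.)?doi\\.org/", "", out)
  out[is.na(out) | out == "" | out == "na"] <- NA_character_
  out
}

# Fold diacritics to ASCII where the platform transliterator allows;
# characters that cannot be transliterated are dropped.
fold_diacritics <- function(x) {
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  out[is.na(out)] <- iconv(x[is.na(out)], from = "UTF-8", to = "ASCII", sub = "")
  out
}

# Title normal form used by deduplication: lowercase, diacritics folded,
# punctuation removed, whitespace runs collapsed.
normalize_title <- function(x) {
  out <- tolower(fold_diacritics(as.character(x)))
  out <- gsub("[^a-z0-9 ]+", " ", out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

# Similarity of two normalised titles: 1 - levenshtein/max length.
title_similarity <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

# Surname of the first author. Accepts "Surname, Initials" or
# "Surname Initials"; returns lowercase folded surname or "".
first_author_surname <- function(authors) {
  vapply(authors, function(a) {
    if (length(a) == 0 || is.na(a[1]) || !nzchar(a[1])) return("")
    first <- trimws(a[1])
    surname <- if (grepl(",", first)) {
      trimws(strsplit(first, ",", fixed = TRUE)[[1]][1])
    } else {
      strsplit(first, "\\s+")[[1]][1]
    }
    tolower(fold_diacritics(surname))
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Minimal union-find for transitive closure of duplicate pairs.
uf_new <- function(ids) {
  parent <- seq_along(ids)
  names(parent) <- ids
  parent
}
uf_find <- function(parent, i) {
  while (parent[[i]] != i) i <- parent[[i]]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
  parent
}
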