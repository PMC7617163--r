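# Citation records: construction, reading, writing.

SOURCE_DBS <- c("pubmed", "wos", "scopus", "other")

#' Construct a citation set
#'
#' A citation set is a tibble with one row per bibliographic record and a fixed
#' set of columns: `uid`, `title`, `abstract`, `keywords` (list of character),
#' `authors` (list of character), `year` (integer or `NA`), `doi` (normalised:
#' lowercase, no resolver prefix), `journal`, `source_db`, `accessions` (list of
#' named character), `retracted`, `abstract_only`, `ptype` (publication-type
#' metadata, free text), `pages`, and `retrieved` (a `Date`, used by
#' [merge_update()]'s lookback window).
#'
#' Missing fields are filled with empty strings / `NA` / empty lists; uids must
#' be unique and years, when present, plausible (1800--2100).
#'
#' @param df a data frame carrying any subset of the columns above; at minimum
#'   `title` or `uid`.
#' @return a `soles_citations` tibble.
#' @export
citation_set <- function(df = NULL) {
  if (is.null(df)) df <- tibble::tibble(uid = character())
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  chr <- function(col, default = "") {
    if (col %in% names(df)) {
      x <- as.character(df[[col]])
      x[is.na(x)] <- default
      x
    } else rep(default, n)
  }
  lst <- function(col) {
    if (col %in% names(df)) {
      x <- df[[col]]
      if (!is.list(x)) x <- lapply(as.character(x), function(s) {
        if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
      })
      lapply(x, function(v) as.character(v[!is.na(v) & nzchar(v)]))
    } else rep(list(character()), n)
  }
  year <- if ("year" %in% names(df)) suppressWarnings(as.integer(df[["year"]])) else rep(NA_integer_, n)
  year[!is.na(year) & (year < 1800 | year > 2100)] <- NA_integer_
  doi <- normalize_doi(chr("doi", NA_character_))
  source_db <- chr("source_db", "other")
  source_db[!source_db %in% SOURCE_DBS] <- "other"
  lg <- function(col) {
    if (col %in% names(df)) {
      x <- as.logical(df[[col]])
      x[is.na(x)] <- FALSE
      x
    } else rep(FALSE, n)
  }
  retrieved <- if ("retrieved" %in% names(df)) as.Date(df[["retrieved"]]) else as.Date(rep(NA, n))
  out <- tibble::tibble(
    uid = chr("uid", NA_character_),
    title = chr("title"),
    abstract = chr("abstract"),
    keywords = lst("keywords"),
    authors = lst("authors"),
    year = year,
    doi = doi,
    journal = chr("journal"),
    source_db = source_db,
    accessions = if ("accessions" %in% names(df)) df[["accessions"]] else rep(list(character()), n),
    retracted = lg("retracted"),
    abstract_only = lg("abstract_only"),
    ptype = chr("ptype"),
    pages = chr("pages"),
    retrieved = retrieved
  )
  missing_uid <- is.na(out$uid) | !nzchar(out$uid)
  if (any(missing_uid)) out$uid[missing_uid] <- assign_uids(out[missing_uid, ])
  if (anyDuplicated(out$uid)) {
    stop("duplicate uids in citation set: ",
         paste(unique(out$uid[duplicated(out$uid)]), collapse = ", "))
  }
  class(out) <- c("soles_citations", class(tibble::tibble()))
  out
}

# Deterministic uid: source accession when present (stable across re-ingest),
# else a content hash of the normalised title/year/doi.
assign_uids <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    acc <- df$accessions[[i]]
    if (length(acc) > 0 && nzchar(acc[[1]])) {
      db <- if (!is.null(names(acc)) && nzchar(names(acc)[1])) names(acc)[1] else df$source_db[i]
      paste0(db, ":", acc[[1]])
    } else {
      key <- paste(normalize_title(df$title[i]), df$year[i] %||% NA, df$doi[i], sep = "|")
      paste0("h:", substr(content_hash(key), 1, 12))
    }
  }, character(1))
}

#' @export
print.soles_citations <- function(x, ...) {
  cat(sprintf("<citation set: %d records, %d with DOI, %d retracted>\n",
              nrow(x), sum(!is.na(x$doi)), sum(x$retracted)))
  NextMethod()
}

CSV_HEADER <- c("uid", "title", "abstract", "keywords", "authors", "year",
                "doi", "journal", "source_db", "retracted")

#' Read citation records
#'
#' Reads bibliographic records from RIS (tags TY/TI/AB/KW/AU/PY/DO/JO plus
#' ER record terminator), MEDLINE/PubMed XML (`PubmedArticle` elements) or the
#' flat CSV dialect (header `uid,title,abstract,keywords,authors,year,doi,
#' journal,source_db,retracted`, keywords and authors semicolon-separated;
#' extra columns `ptype`, `pages`, `retrieved` are honoured when present).
#'
#' Malformed records are skipped with a warning and counted in the
#' `n_skipped` attribute; missing fields are left empty rather than failing.
#' Uids are assigned deterministically from the source accession when one
#' exists, else from a content hash.
#'
#' @param path path to the input file.
#' @param format one of `"ris"`, `"medline_xml"`, `"csv"`.
#' @return a `soles_citations` tibble (see [citation_set()]).
#' @export
read_citations <- function(path, format = c("csv", "ris", "medline_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read citations: no such file: ", path)
  switch(format,
    csv = read_citations_csv(path),
    ris = read_citations_ris(path),
    medline_xml = read_citations_medline(path)
  )
}

read_citations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  if (nrow(df) == 0) return(citation_set())
  citation_set(df)
}

read_citations_ris <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- list()
  cur <- NULL
  n_skipped <- 0L
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (!isTRUE(cur$complete)) {
      n_skipped <<- n_skipped + 1L
      warning("skipping malformed RIS record (no ER terminator)", call. = FALSE)
      return(NULL)
    }
    cur
  }
  for (line in lines) {
    m <- regmatches(line, regexec("^([A-Z][A-Z0-9])  - ?(.*)$", line))[[1]]
    if (length(m) == 0) next
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "TY") {
      if (!is.null(cur)) {
        done <- flush(cur)
        if (!is.null(done)) recs[[length(recs) + 1L]] <- done
      }
      cur <- list(keywords = character(), authors = character(), ptype = val,
                  complete = FALSE)
    } else if (is.null(cur)) {
      next
    } else if (tag == "ER") {
      cur$complete <- TRUE
      recs[[length(recs) + 1L]] <- cur
      cur <- NULL
    } else {
      switch(tag,
        TI = cur$title <- val,
        AB = cur$abstract <- val,
        KW = cur$keywords <- c(cur$keywords, val),
        AU = cur$authors <- c(cur$authors, val),
        PY = cur$year <- val,
        DO = cur$doi <- val,
        JO = cur$journal <- val,
        AN = cur$accession <- val,
        DB = cur$source_db <- tolower(val),
        NULL
      )
    }
  }
  if (!is.null(cur)) flush(cur)
  if (length(recs) == 0) {
    out <- citation_set()
  } else {
    df <- tibble::tibble(
      title = vapply(recs, function(r) r$title %||% "", character(1)),
      abstract = vapply(recs, function(r) r$abstract %||% "", character(1)),
      keywords = lapply(recs, function(r) r$keywords),
      authors = lapply(recs, function(r) r$authors),
      year = vapply(recs, function(r) {
        y <- regmatches(r$year %||% "", regexpr("[0-9]{4}", r$year %||% ""))
        if (length(y)) y else NA_character_
      }, character(1)),
      doi = vapply(recs, function(r) r$doi %||% NA_character_, character(1)),
      journal = vapply(recs, function(r) r$journal %||% "", character(1)),
      source_db = vapply(recs, function(r) r$source_db %||% "other", character(1)),
      accessions = lapply(recs, function(r) {
        if (is.null(r$accession)) character() else stats::setNames(r$accession, r$source_db %||% "other")
      }),
      ptype = vapply(recs, function(r) r$ptype %||% "", character(1))
    )
    out <- citation_set(df)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

read_citations_medline <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0) return(citation_set())
  txt <- function(node, xp) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    if (is.na(v)) "" else trimws(v)
  }
  df <- tibble::tibble(
    title = vapply(arts, txt, character(1), xp = ".//ArticleTitle"),
    abstract = vapply(arts, function(a) {
      paste(xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")), collapse = " ")
    }, character(1)),
    keywords = lapply(arts, function(a) trimws(xml2::xml_text(xml2::xml_find_all(a, ".//Keyword")))),
    authors = lapply(arts, function(a) {
      nodes <- xml2::xml_find_all(a, ".//AuthorList/Author")
      vapply(nodes, function(n) {
        ln <- xml2::xml_text(xml2::xml_find_first(n, "./LastName"))
        fn <- xml2::xml_text(xml2::xml_find_first(n, "./ForeName"))
        trimws(paste(c(if (!is.na(ln)) ln else NULL,
                       if (!is.na(fn)) fn else NULL), collapse = ", "))
      }, character(1))
    }),
    year = vapply(arts, function(a) {
      y <- txt(a, ".//JournalIssue/PubDate/Year")
      if (!nzchar(y)) y <- txt(a, ".//ArticleDate/Year")
      if (nzchar(y)) y else NA_character_
    }, character(1)),
    doi = vapply(arts, function(a) {
      v <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleId[@IdType='doi']"))
      if (is.na(v)) NA_character_ else v
    }, character(1)),
    journal = vapply(arts, txt, character(1), xp = ".//Journal/Title"),
    source_db = "pubmed",
    accessions = lapply(arts, function(a) {
      pmid <- txt(a, ".//MedlineCitation/PMID")
      if (nzchar(pmid)) c(pubmed = pmid) else character()
    }),
    ptype = vapply(arts, function(a) {
      paste(xml2::xml_text(xml2::xml_find_all(a, ".//PublicationType")), collapse = "; ")
    }, character(1)),
    pages = vapply(arts, txt, character(1), xp = ".//Pagination/MedlinePgn")
  )
  citation_set(df)
}

#' Write citation records
#'
#' Serialises a citation set to the flat CSV dialect or to RIS. Both round-trip
#' through [read_citations()] field-by-field for the fields each dialect
#' carries.
#'
#' @param citations a `soles_citations` tibble.
#' @param path output file path.
#' @param format `"csv"` or `"ris"`.
#' @return `path`, invisibly.
#' @export
write_citations <- function(citations, path, format = c("csv", "ris")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(
      uid = citations$uid,
      title = citations$title,
      abstract = citations$abstract,
      keywords = vapply(citations$keywords, paste, character(1), collapse = "; "),
      authors = vapply(citations$authors, paste, character(1), collapse = "; "),
      year = citations$year,
      doi = ifelse(is.na(citations$doi), "", citations$doi),
      journal = citations$journal,
      source_db = citations$source_db,
      retracted = citations$retracted,
      ptype = citations$ptype,
      pages = citations$pages,
      retrieved = as.character(citations$retrieved),
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    for (i in seq_len(nrow(citations))) {
      r <- citations[i, ]
      w <- function(tag, val) {
        for (v in val) if (!is.na(v) && nzchar(v)) writeLines(sprintf("%s  - %s", tag, v), con)
      }
      w("TY", if (nzchar(r$ptype)) r$ptype else "JOUR")
      w("TI", r$title)
      w("AB", r$abstract)
      w("KW", r$keywords[[1]])
      w("AU", r$authors[[1]])
      w("PY", as.character(r$year))
      w("DO", r$doi)
      w("JO", r$journal)
      acc <- r$accessions[[1]]
      if (length(acc)) w("AN", acc[[1]])
      w("DB", r$source_db)
      writeLines("ER  - ", con)
    }
  }
  invisible(path)
}

#' Read full-text documents
#'
#' Full texts are plain text keyed by citation uid: either a directory of
#' UTF-8 `<uid>.txt` files, or a two-column CSV (`uid,text`).
#'
#' @param path directory or CSV file path.
#' @return a tibble with columns `uid`, `text`, `char_count`, `origin_format`.
#' @export
read_fulltexts <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    out <- tibble::tibble(
      uid = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                                             collapse = "\n"), character(1), USE.NAMES = FALSE),
      origin_format = "txt"
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    out <- tibble::tibble(uid = df$uid, text = df$text, origin_format = "txt")
  }
  out$char_count <- nchar(out$text)
  out[, c("uid", "text", "char_count", "origin_format")]
}

#' Write full-text documents as a two-column CSV
#'
#' @param fulltexts tibble with `uid` and `text` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fulltexts <- function(fulltexts, path) {
  utils::write.csv(data.frame(uid = fulltexts$uid, text = fulltexts$text,
                              stringsAsFactors = FALSE), path, row.names = FALSE)
  invisible(path)
}
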