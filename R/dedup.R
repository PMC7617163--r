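# Deduplication and search-update merging.

#' Deduplicate a citation set
#'
#' Two records are considered copies of the same publication when
#' (a) they share an identical normalised DOI, or (b) neither's DOI
#' contradicts the other's (one or both missing, or equal), their normalised
#' titles (lowercase, punctuation stripped, diacritics folded, whitespace
#' collapsed) have edit-distance similarity at or above `title_threshold`,
#' they carry the same year, and the same first-author surname. Pairwise
#' matches are closed transitively; within each group one record is kept,
#' preferring a record with an abstract, then one with a DOI, then the
#' lexicographically smallest uid. The operation is idempotent and insensitive
#' to input order.
#'
#' @param citations a `soles_citations` tibble.
#' @param title_threshold minimum normalised-title similarity for rule (b)
#'   (default 0.95).
#' @return a list with elements `citations` (the kept records, input order
#'   preserved) and `duplicates` (a list with `groups`, a list of uid character
#'   vectors of size >= 2, and `kept`, the kept uid per group).
#' @export
deduplicate <- function(citations, title_threshold = 0.95) {
  n <- nrow(citations)
  if (n <= 1) {
    return(list(citations = citations,
                duplicates = list(groups = list(), kept = character())))
  }
  ord <- order(citations$uid)
  cs <- citations[ord, ]
  parent <- uf_new(cs$uid)

  # rule (a): identical normalised DOI
  has_doi <- !is.na(cs$doi)
  if (any(has_doi)) {
    for (grp in split(which(has_doi), cs$doi[has_doi])) {
      if (length(grp) > 1) {
        for (k in grp[-1]) parent <- uf_union(parent, grp[1], k)
      }
    }
  }

  # rule (b): blocked by year; title similarity + first author + no DOI conflict
  norm_title <- normalize_title(cs$title)
  surname <- first_author_surname(cs$authors)
  blocks <- split(seq_len(n), cs$year)
  for (blk in blocks) {
    if (length(blk) < 2) next
    for (a in seq_along(blk)[-length(blk)]) {
      for (b in seq((a + 1), length(blk))) {
        i <- blk[a]; j <- blk[b]
        if (!identical(surname[i], surname[j])) next
        doi_conflict <- !is.na(cs$doi[i]) && !is.na(cs$doi[j]) && cs$doi[i] != cs$doi[j]
        if (doi_conflict) next
        if (title_similarity(norm_title[i], norm_title[j]) >= title_threshold) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }

  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups_all <- split(seq_len(n), root)
  keep_idx <- integer(0)
  groups <- list()
  kept <- character()
  for (grp in groups_all) {
    if (length(grp) == 1) {
      keep_idx <- c(keep_idx, grp)
      next
    }
    # keep-rule: abstract > DOI > smallest uid (grp already sorted by uid)
    score <- 2L * nzchar(cs$abstract[grp]) + 1L * !is.na(cs$doi[grp])
    k <- grp[order(-score, cs$uid[grp])][1]
    keep_idx <- c(keep_idx, k)
    groups[[length(groups) + 1L]] <- cs$uid[grp]
    kept <- c(kept, cs$uid[k])
  }
  kept_uids <- cs$uid[keep_idx]
  out <- citations[citations$uid %in% kept_uids, ]
  list(citations = out, duplicates = list(groups = groups, kept = kept))
}

#' Merge a search update into an existing citation set
#'
#' Incoming records are deduplicated against themselves, then against the
#' existing records retrieved within the lookback window (the periodic full
#' pass over the whole store catches older duplicates); only novel records are
#' appended. Existing records are never modified or removed.
#'
#' @param existing the current citation store; records should carry a
#'   `retrieved` date. If none do, all of `existing` is compared (with a
#'   warning).
#' @param incoming the newly retrieved records.
#' @param lookback number of days of existing records to compare against
#'   (default 62, a conservative two months).
#' @param today reference date for the lookback window (default the most
#'   recent `retrieved` date in `existing`, else today's date).
#' @return a list with `citations` (existing plus novel incoming) and
#'   `n_appended`.
#' @export
merge_update <- function(existing, incoming, lookback = 62, today = NULL) {
  inc <- deduplicate(incoming)$citations
  if (nrow(existing) == 0) {
    out <- inc
    return(list(citations = out, n_appended = nrow(inc)))
  }
  dates <- existing$retrieved
  if (all(is.na(dates))) {
    warning("existing records carry no retrieval dates; comparing against all of them",
            call. = FALSE)
    window <- existing
  } else {
    if (is.null(today)) today <- max(dates, na.rm = TRUE)
    keep <- !is.na(dates) & dates >= (as.Date(today) - lookback)
    window <- existing[keep, ]
  }
  pool <- rbind(window, inc[!inc$uid %in% existing$uid, ])
  dd <- deduplicate(pool)
  dup_uids <- unlist(dd$duplicates$groups)
  # an incoming record is novel unless it shares a uid with the store or
  # merged into a group containing an existing (window) record
  novel <- inc[!inc$uid %in% existing$uid, ]
  drop <- vapply(novel$uid, function(u) {
    for (g in dd$duplicates$groups) {
      if (u %in% g && any(g %in% window$uid)) return(TRUE)
      # merged with another incoming record: keep only the group's keeper
      if (u %in% g && !u %in% dd$duplicates$kept) return(TRUE)
    }
    FALSE
  }, logical(1))
  novel <- novel[!drop, ]
  out <- rbind(existing, novel)
  class(out) <- class(existing)
  list(citations = out, n_appended = nrow(novel))
}

#' Flag records that are likely abstracts only
#'
#' A record is flagged (never deleted) when no usable full text is attached
#' (none at all, or one shorter than `min_words` words) and its metadata gives
#' positive evidence of an abstract-only publication: a publication type
#' containing "meeting abstract" / "conference abstract", or a pagination
#' field denoting a single page. Records with no type or pages metadata are
#' left unflagged (insufficient evidence).
#'
#' @param citations a `soles_citations` tibble.
#' @param fulltexts tibble from [read_fulltexts()] (may be empty).
#' @param min_words minimum word count for an attached text to count as a
#'   full text (default 500).
#' @return the citation set with `abstract_only` updated.
#' @export
flag_abstract_only <- function(citations, fulltexts = NULL, min_words = 500) {
  stopifnot(min_words > 0)
  has_ft <- rep(FALSE, nrow(citations))
  if (!is.null(fulltexts) && nrow(fulltexts) > 0) {
    wc <- vapply(strsplit(trimws(fulltexts$text), "\\s+"), length, integer(1))
    usable <- fulltexts$uid[wc >= min_words]
    has_ft <- citations$uid %in% usable
  }
  type_hit <- grepl("(meeting|conference)\\s+abstract", citations$ptype, ignore.case = TRUE)
  single_page <- vapply(citations$pages, function(p) {
    p <- trimws(p)
    if (!nzchar(p)) return(FALSE)
    if (grepl("^[0-9]+$", p)) return(TRUE)
    m <- regmatches(p, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", p))[[1]]
    length(m) == 3 && m[2] == m[3]
  }, logical(1))
  citations$abstract_only <- unname(!has_ft & (type_hit | single_page))
  citations
}
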