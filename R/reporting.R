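# Dashboard-ready aggregations and Boolean filtered exports.

#' Citation counts per publication year
#'
#' Retracted and abstract-only-flagged records are excluded, as are records
#' with no usable year; years with zero remaining records are omitted.
#'
#' @param citations a `soles_citations` tibble.
#' @return a tibble with columns `year`, `count`.
#' @export
counts_by_year <- function(citations) {
  keep <- !citations$retracted & !citations$abstract_only & !is.na(citations$year)
  tab <- table(citations$year[keep])
  tibble::tibble(year = as.integer(names(tab)), count = as.integer(tab))
}

#' Tag coverage per category
#'
#' The proportion of the corpus carrying at least one assigned tag in each
#' category, as displayed on the dashboard ("n (xx.x %) tagged with at least
#' one model...").
#'
#' @param tags a `soles_tags` tibble, or a data frame with `category` and
#'   `n_tagged` columns for precomputed counts.
#' @param total corpus size the percentages are taken over.
#' @return a tibble with `category`, `n_tagged`, `percent` (one decimal,
#'   rounded half-up).
#' @export
#' @examples
#' tag_coverage(data.frame(category = "outcome", n_tagged = 16390), 35546)
tag_coverage <- function(tags, total) {
  if (inherits(tags, "soles_tags") ||
      all(c("uid", "assigned") %in% names(tags))) {
    hit <- tags[tags$assigned & tags$label != UNTAGGED_LABEL, ]
    counts <- dplyr::summarise(dplyr::group_by(hit, .data$category),
                               n_tagged = dplyr::n_distinct(.data$uid),
                               .groups = "drop")
  } else {
    counts <- tibble::as_tibble(tags[, c("category", "n_tagged")])
  }
  if (any(counts$n_tagged > total)) stop("n_tagged exceeds corpus total")
  counts$percent <- round_half_up(100 * counts$n_tagged / total, 1)
  counts
}

#' Tag co-occurrence cross-tabulation (gap map)
#'
#' Cell (i, j) counts the distinct citations assigned both label i of
#' `cat_a` and label j of `cat_b` — the matrix behind the dashboard's
#' interactive gap map. When both categories are equal the diagonal equals
#' the per-label citation counts. `row_groups` (a named character vector,
#' label -> group) aggregates rows to dictionary groups, e.g. all drugs
#' targeting the cholinergic system.
#'
#' @param tags a `soles_tags` tibble.
#' @param cat_a,cat_b row / column categories.
#' @param labels_a,labels_b optional label subsets (default: all assigned).
#' @param row_groups optional named character vector mapping row labels to
#'   group names.
#' @return a `soles_crosstab`: list with `row_category`, `col_category` and
#'   `cells`, an integer matrix with label dimnames.
#' @export
crosstab <- function(tags, cat_a, cat_b, labels_a = NULL, labels_b = NULL,
                     row_groups = NULL) {
  hit <- tags[tags$assigned & tags$label != UNTAGGED_LABEL, ]
  a <- hit[hit$category == cat_a, c("uid", "label")]
  b <- hit[hit$category == cat_b, c("uid", "label")]
  if (!is.null(row_groups)) {
    mapped <- row_groups[a$label]
    a$label <- ifelse(is.na(mapped), a$label, mapped)
    a <- unique(a)
  }
  if (is.null(labels_a)) labels_a <- sort(unique(a$label))
  if (is.null(labels_b)) labels_b <- sort(unique(b$label))
  cells <- matrix(0L, nrow = length(labels_a), ncol = length(labels_b),
                  dimnames = list(labels_a, labels_b))
  for (i in seq_along(labels_a)) {
    uids_a <- unique(a$uid[a$label == labels_a[i]])
    for (j in seq_along(labels_b)) {
      uids_b <- unique(b$uid[b$label == labels_b[j]])
      cells[i, j] <- length(intersect(uids_a, uids_b))
    }
  }
  structure(list(row_category = cat_a, col_category = cat_b, cells = cells),
            class = "soles_crosstab")
}

#' @export
print.soles_crosstab <- function(x, ...) {
  cat(sprintf("<gap map: %s x %s, %d x %d labels>\n", x$row_category,
              x$col_category, nrow(x$cells), ncol(x$cells)))
  print(x$cells)
  invisible(x)
}

# ---- Boolean query parser ---------------------------------------------------

# Grammar: expr := term (OR term)* ; term := factor (AND factor)* ;
# factor := WORD | "quoted phrase" | ( expr ). AND binds tighter than OR.

query_tokens <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { i <- i + nchar(ws); next }
    rest <- substr(text, i, n)
    ch <- substr(rest, 1, 1)
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
    } else if (ch == '"') {
      m <- regmatches(rest, regexpr('^"[^"]*"', rest))
      if (!length(m)) stop("unterminated quote at position ", i)
      toks[[length(toks) + 1L]] <- list(type = "term",
                                        value = substr(m, 2, nchar(m) - 1), pos = i)
      i <- i + nchar(m)
    } else {
      m <- regmatches(rest, regexpr('^[^\\s()"]+', rest, perl = TRUE))
      if (!length(m)) stop("cannot tokenise query at position ", i)
      up <- toupper(m)
      type <- if (up %in% c("AND", "OR")) up else "term"
      toks[[length(toks) + 1L]] <- list(type = type, value = m, pos = i)
      i <- i + nchar(m)
    }
  }
  toks
}

#' Parse a Boolean tiabkw query
#'
#' Terms are whitespace-delimited words or quoted phrases; `AND` binds
#' tighter than `OR`; parentheses group. Malformed input raises a parse error
#' naming the character position.
#'
#' @param text the query string.
#' @return a `soles_query` AST (nested lists with `op`/`args` or `term`).
#' @export
#' @examples
#' q <- parse_query('donepezil AND (memory OR maze)')
parse_query <- function(text) {
  toks <- query_tokens(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_more <- function(what) {
    t <- peek()
    if (is.null(t)) stop("unexpected end of query; expected ", what)
    t
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1) args[[1]] else list(op = "OR", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1) args[[1]] else list(op = "AND", args = args)
  }
  parse_factor <- function() {
    t <- expect_more("a term or '('")
    if (t$type == "(") {
      advance()
      inner <- parse_expr()
      close <- expect_more("')'")
      if (close$type != ")") stop("expected ')' at position ", close$pos)
      advance()
      inner
    } else if (t$type == "term") {
      advance()
      list(term = t$value)
    } else {
      stop("unexpected '", t$value, "' at position ", t$pos)
    }
  }
  if (length(toks) == 0) stop("empty query")
  out <- parse_expr()
  t <- peek()
  if (!is.null(t)) stop("unexpected '", t$value, "' at position ", t$pos)
  structure(out, class = "soles_query")
}

eval_query <- function(ast, text) {
  if (!is.null(ast$term)) {
    re <- paste0("(?i)", BOUND_L, "(?:", variant_regex(ast$term), ")", BOUND_R)
    return(grepl(re, text, perl = TRUE))
  }
  vals <- vapply(ast$args, eval_query, logical(length(text)), text = text)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(text))
  if (ast$op == "AND") apply(vals, 1, all) else apply(vals, 1, any)
}

#' Construct a filter query
#'
#' @param text_terms Boolean expression over tiabkw (string or parsed
#'   `soles_query`), or `NULL`.
#' @param tag_filters named list, category -> character vector of labels; a
#'   record passes when assigned at least one listed label per filtered
#'   category.
#' @param year_range length-2 integer vector `c(from, to)`, or `NULL`.
#' @param high_sensitivity use high-sensitivity tag assignments.
#' @return a `soles_filter_query`.
#' @export
filter_query <- function(text_terms = NULL, tag_filters = list(),
                         year_range = NULL, high_sensitivity = FALSE) {
  if (is.character(text_terms)) text_terms <- parse_query(text_terms)
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2, year_range[1] <= year_range[2])
  }
  structure(list(text_terms = text_terms, tag_filters = tag_filters,
                 year_range = year_range,
                 high_sensitivity = isTRUE(high_sensitivity)),
            class = "soles_filter_query")
}

#' Filtered export of the corpus
#'
#' Evaluates the text expression case-insensitively over each record's
#' tiabkw surface, applies the tag filters against assignments replayed from
#' the stored evidence (under the default policy, or the high-sensitivity
#' policy when the query's flag is set — the latter always yields a superset),
#' restricts to the year range, and excludes retracted records. Filter kinds
#' combine conjunctively.
#'
#' @param citations a `soles_citations` tibble.
#' @param tags the corpus `soles_tags` evidence.
#' @param query a `soles_filter_query` (default: empty query, full corpus).
#' @param policy base policy used to replay assignments (default
#'   [default_policy()]); the query's `high_sensitivity` flag toggles its
#'   high-sensitivity rule.
#' @return the filtered `soles_citations` tibble.
#' @export
export_filtered <- function(citations, tags, query = filter_query(),
                            policy = default_policy()) {
  stopifnot(inherits(query, "soles_filter_query"))
  keep <- !citations$retracted
  if (!is.null(query$year_range)) {
    keep <- keep & !is.na(citations$year) &
      citations$year >= query$year_range[1] &
      citations$year <= query$year_range[2]
  }
  if (!is.null(query$text_terms)) {
    tia <- vapply(seq_len(nrow(citations)), function(i) tiabkw_text(citations[i, ]),
                  character(1))
    keep <- keep & eval_query(query$text_terms, tia)
  }
  if (length(query$tag_filters) > 0) {
    pol <- policy
    pol$high_sensitivity <- query$high_sensitivity
    ev <- tags[tags$label != UNTAGGED_LABEL, ]
    replayed <- vapply(seq_len(nrow(ev)), function(i) {
      policy_assigns(pol, ev$category[i], ev$tiabkw_count[i],
                     ev$fulltext_count[i], ev$model_sentence_count[i])
    }, logical(1))
    for (cat in names(query$tag_filters)) {
      wanted <- query$tag_filters[[cat]]
      ok_uids <- unique(ev$uid[replayed & ev$category == cat &
                                 ev$label %in% wanted])
      keep <- keep & citations$uid %in% ok_uids
    }
  }
  citations[keep, ]
}
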