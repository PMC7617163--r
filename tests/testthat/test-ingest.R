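# Reading, writing, merging and deduplicating citation records.

test_that("CSV ingest fills missing fields and assigns deterministic uids", {
  path <- write_citations_fixture(data.frame(
    uid = c("a1", "a2", "a3"),
    title = c("First study", "Second study", "Third study"),
    abstract = c("Some text.", "", "More text."),
    keywords = c("k1; k2", "", "k3"),
    authors = c("Smith, J", "Lee, K; Park, M", ""),
    year = c(2019, 2020, 2021),
    doi = c("https://doi.org/10.1/ABC", "", "10.2/xyz"),
    journal = "J", source_db = c("pubmed", "wos", "bogus"),
    retracted = c(FALSE, FALSE, TRUE)
  ))
  cs <- read_citations(path, "csv")
  expect_s3_class(cs, "soles_citations")
  expect_equal(nrow(cs), 3)
  expect_equal(cs$abstract[2], "")
  expect_equal(cs$keywords[[1]], c("k1", "k2"))
  expect_equal(cs$authors[[2]], c("Lee, K", "Park, M"))
  expect_equal(cs$doi, c("10.1/abc", NA, "10.2/xyz"))  # normalised
  expect_equal(cs$source_db[3], "other")               # unknown enum folded
  expect_true(cs$retracted[3])

  empty <- read_citations(write_citations_fixture(
    data.frame(uid = character(), title = character())), "csv")
  expect_equal(nrow(empty), 0)
})

test_that("RIS ingest parses the tag dialect and normalises DOIs", {
  ris <- c(
    "TY  - JOUR", "TI  - A transgenic cohort study", "AB  - We tested things.",
    "KW  - cohort", "KW  - longitudinal", "AU  - Smith, J", "AU  - Doe, A",
    "PY  - 2018", "DO  - https://doi.org/10.1/ABC", "JO  - J Res",
    "AN  - 123456", "DB  - pubmed", "ER  - ",
    "TY  - JOUR", "TI  - Second record", "ER  - "
  )
  f <- tempfile(fileext = ".ris"); writeLines(ris, f)
  cs <- read_citations(f, "ris")
  expect_equal(nrow(cs), 2)
  expect_equal(cs$doi[1], "10.1/abc")
  expect_equal(cs$keywords[[1]], c("cohort", "longitudinal"))
  expect_equal(cs$uid[1], "pubmed:123456")   # accession-derived, stable
  expect_equal(cs$year[1], 2018L)

  # empty file and malformed trailing record
  f2 <- tempfile(); writeLines(character(), f2)
  expect_equal(nrow(read_citations(f2, "ris")), 0)
  f3 <- tempfile(); writeLines(c("TY  - JOUR", "TI  - Truncated"), f3)
  expect_warning(cs3 <- read_citations(f3, "ris"), "malformed")
  expect_equal(nrow(cs3), 0)
  expect_equal(attr(cs3, "n_skipped"), 1L)
})

test_that("MEDLINE XML ingest extracts title, abstract, ids and types", {
  xml <- '<?xml version="1.0"?><PubmedArticleSet><PubmedArticle>
    <MedlineCitation><PMID>999</PMID><Article>
      <Journal><Title>J Res</Title>
        <JournalIssue><PubDate><Year>2020</Year></PubDate></JournalIssue></Journal>
      <ArticleTitle>An XML record</ArticleTitle>
      <Pagination><MedlinePgn>12-19</MedlinePgn></Pagination>
      <Abstract><AbstractText>Part one.</AbstractText><AbstractText>Part two.</AbstractText></Abstract>
      <AuthorList><Author><LastName>Smith</LastName><ForeName>Jo</ForeName></Author></AuthorList>
      <PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>
    </Article><KeywordList><Keyword>cohort</Keyword></KeywordList></MedlineCitation>
    <PubmedData><ArticleIdList><ArticleId IdType="doi">10.5/QQ</ArticleId></ArticleIdList></PubmedData>
  </PubmedArticle></PubmedArticleSet>'
  f <- tempfile(fileext = ".xml"); writeLines(xml, f)
  cs <- read_citations(f, "medline_xml")
  expect_equal(cs$title, "An XML record")
  expect_equal(cs$abstract, "Part one. Part two.")
  expect_equal(cs$uid, "pubmed:999")
  expect_equal(cs$doi, "10.5/qq")
  expect_equal(cs$authors[[1]], "Smith, Jo")
  expect_equal(cs$year, 2020L)
  expect_equal(cs$pages, "12-19")
})

test_that("read -> write -> read is a fixed point field by field", {
  spec <- corpus_spec(8, fulltext_fraction = 0, seed = 11)
  cs <- generate_corpus(spec)$citations
  for (fmt in c("csv", "ris")) {
    f <- tempfile()
    write_citations(cs, f, fmt)
    back <- read_citations(f, fmt)
    expect_equal(back$title, cs$title, info = fmt)
    expect_equal(back$abstract, cs$abstract, info = fmt)
    expect_equal(back$doi, cs$doi, info = fmt)
    expect_equal(back$year, cs$year, info = fmt)
    expect_equal(back$keywords, cs$keywords, info = fmt)
    expect_equal(back$authors, cs$authors, info = fmt)
  }
  # CSV additionally preserves uids verbatim
  f <- tempfile(); write_citations(cs, f, "csv")
  expect_equal(read_citations(f, "csv")$uid, cs$uid)
})

test_that("full texts round-trip through directory and CSV forms", {
  d <- tempfile(); dir.create(d)
  writeLines("Animals were housed in groups.", file.path(d, "u1.txt"))
  writeLines("A second text.", file.path(d, "u2.txt"))
  ft <- read_fulltexts(d)
  expect_setequal(ft$uid, c("u1", "u2"))
  expect_equal(ft$char_count, nchar(ft$text))
  f <- tempfile(fileext = ".csv")
  write_fulltexts(ft, f)
  back <- read_fulltexts(f)
  expect_equal(back$text[order(back$uid)], ft$text[order(ft$uid)])
})

test_that("records sharing a DOI merge; title rule needs year, author and no DOI conflict", {
  cs <- make_citations(
    list(uid = "p:1", title = "Study of donepezil", abstract = "text",
         doi = "10.1/a", year = 2019, authors = list("Smith, J"), source_db = "pubmed"),
    list(uid = "w:1", title = "Study of donepezil [conference]", abstract = "",
         doi = "10.1/A", year = 2019, authors = list("Smith, J"), source_db = "wos"),
    # case/punctuation variant, same year + first author, no DOI
    list(uid = "s:1", title = "STUDY OF DONEPEZIL!", abstract = "",
         year = 2019, authors = list("Smith, Jane"), source_db = "scopus"),
    # same title, different year: must NOT merge by rule (b)
    list(uid = "y:1", title = "Study of donepezil", abstract = "",
         year = 2020, authors = list("Smith, J"), source_db = "other"),
    # identical titles but conflicting DOIs: must NOT merge
    list(uid = "q:1", title = "An unrelated cohort analysis", abstract = "",
         doi = "10.3/q", year = 2021, authors = list("Lee, K"), source_db = "pubmed"),
    list(uid = "q:2", title = "An unrelated cohort analysis", abstract = "",
         doi = "10.4/r", year = 2021, authors = list("Lee, K"), source_db = "wos")
  )
  dd <- deduplicate(cs)
  grp <- dd$duplicates$groups
  expect_length(grp, 1)
  expect_setequal(grp[[1]], c("p:1", "w:1", "s:1"))
  # keep-rule: p:1 has an abstract
  expect_equal(dd$duplicates$kept, "p:1")
  expect_setequal(dd$citations$uid, c("p:1", "y:1", "q:1", "q:2"))
})

test_that("deduplication is idempotent, order-insensitive, and groups replay the rules", {
  corp <- generate_corpus(corpus_spec(20, fulltext_fraction = 0,
                                      duplicate_fraction = 0.3, seed = 5))
  cs <- corp$citations
  dd <- deduplicate(cs)
  expect_setequal(lapply(dd$duplicates$groups, sort),
                  lapply(corp$truth$duplicates, sort))
  # idempotent
  dd2 <- deduplicate(dd$citations)
  expect_equal(nrow(dd2$citations), nrow(dd$citations))
  expect_length(dd2$duplicates$groups, 0)
  # order-insensitive
  perm <- soles:::with_seed(99, sample(nrow(cs)))
  ddp <- deduplicate(cs[perm, ])
  expect_setequal(ddp$citations$uid, dd$citations$uid)
  expect_setequal(lapply(ddp$duplicates$groups, sort),
                  lapply(dd$duplicates$groups, sort))
  # every merged pair chain satisfies rule (a) or rule (b): replay
  by_uid <- cs[match(unlist(dd$duplicates$groups), cs$uid), ]
  for (g in dd$duplicates$groups) {
    sub <- cs[match(g, cs$uid), ]
    pair_ok <- function(i, j) {
      doi_eq <- !is.na(sub$doi[i]) && !is.na(sub$doi[j]) && sub$doi[i] == sub$doi[j]
      conflict <- !is.na(sub$doi[i]) && !is.na(sub$doi[j]) && sub$doi[i] != sub$doi[j]
      tsim <- soles:::title_similarity(soles:::normalize_title(sub$title[i]),
                                       soles:::normalize_title(sub$title[j]))
      rule_b <- !conflict && tsim >= 0.95 &&
        identical(sub$year[i], sub$year[j]) &&
        identical(soles:::first_author_surname(sub$authors[i]),
                  soles:::first_author_surname(sub$authors[j]))
      doi_eq || rule_b
    }
    # connectivity of the pairwise match graph over the group
    adj <- outer(seq_len(nrow(sub)), seq_len(nrow(sub)),
                 Vectorize(function(i, j) i != j && pair_ok(i, j)))
    reach <- adj[1, ]
    for (k in seq_len(nrow(sub))) reach <- reach | (reach %*% adj > 0)[1, ]
    expect_true(all(reach[-1]))
  }
})

test_that("merge_update appends only novel records within the lookback window", {
  base <- generate_corpus(corpus_spec(6, fulltext_fraction = 0, seed = 21))$citations
  base$retrieved <- as.Date("2023-05-20")
  old <- generate_corpus(corpus_spec(3, fulltext_fraction = 0, seed = 22))$citations
  old$uid <- paste0("old-", old$uid)
  old$retrieved <- as.Date("2022-01-01")   # beyond any 62-day window
  store <- rbind(base, old)
  class(store) <- class(base)

  # incoming identical to existing -> nothing appended
  res <- merge_update(store, base)
  expect_equal(res$n_appended, 0)

  # 5 incoming, 2 duplicating recent records -> 3 appended
  fresh <- generate_corpus(corpus_spec(3, fulltext_fraction = 0, seed = 23))$citations
  fresh$uid <- paste0("new-", fresh$uid)
  dups <- base[1:2, ]
  dups$uid <- paste0("redo-", dups$uid)
  incoming <- rbind(fresh, dups)
  class(incoming) <- class(base)
  res2 <- merge_update(store, incoming)
  expect_equal(res2$n_appended, 3)
  expect_true(all(paste0("new-", fresh$uid[0:0]) %in% character(0)) ||
                all(fresh$uid %in% res2$citations$uid))

  # a duplicate of a record OLDER than the lookback slips through the weekly
  # merge, then the periodic full pass catches it
  old_dup <- old[1, ]
  old_dup$uid <- "redo-old"
  old_dup$doi <- NA_character_
  class(old_dup) <- class(base)
  res3 <- merge_update(store, old_dup)
  expect_equal(res3$n_appended, 1)
  full <- deduplicate(res3$citations)
  expect_true(any(vapply(full$duplicates$groups,
                         function(g) "redo-old" %in% g, logical(1))))

  # missing retrieval dates: warned, compared against everything
  store2 <- store
  store2$retrieved <- as.Date(NA)
  expect_warning(res4 <- merge_update(store2, old_dup), "retrieval dates")
  expect_equal(res4$n_appended, 0)
})

test_that("abstract-only flagging needs positive metadata evidence", {
  cs <- make_citations(
    list(uid = "a", title = "Full paper", ptype = "Journal Article"),
    list(uid = "b", title = "Meeting abstract", ptype = "Meeting Abstract"),
    list(uid = "c", title = "No metadata at all"),
    list(uid = "d", title = "Single page", pages = "103"),
    list(uid = "e", title = "Same start and end page", pages = "55-55")
  )
  ft <- tibble::tibble(uid = "a",
                       text = paste(rep("word", 4000), collapse = " "))
  out <- flag_abstract_only(cs, ft)
  expect_equal(out$abstract_only,
               c(FALSE, TRUE, FALSE, TRUE, TRUE))
  # an attached text below min_words does not count as a full text
  short_ft <- tibble::tibble(uid = "b", text = "too short")
  out2 <- flag_abstract_only(cs, short_ft, min_words = 500)
  expect_true(out2$abstract_only[2])
})
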