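# In-code fixture builders.

make_citations <- function(...) {
  rows <- list(...)
  citation_set(dplyr::bind_rows(lapply(rows, tibble::as_tibble)))
}

# A minimal model/outcome pair of lexicons for targeted tests.
tiny_model_lexicon <- function() {
  lexicon(data.frame(label = c("APP/PS1", "5xFAD"),
                     synonyms = c("APP/PSEN1", ""),
                     stringsAsFactors = FALSE), "model")
}

tiny_outcome_lexicon <- function() {
  lexicon(data.frame(label = "Morris water maze",
                     synonyms = "water maze|MWM|Morris maze",
                     stringsAsFactors = FALSE), "outcome")
}

# Write a small citations CSV and return its path.
write_citations_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

table3_scores <- function() tagging_validation_table()
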