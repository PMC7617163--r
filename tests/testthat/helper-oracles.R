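# Independent oracles used across tests.

# Brute-force match counter: each surface variant is located independently at
# every start position, boundaries are checked by hand on the flanking
# characters, and the leftmost / longest-alternative-first / non-overlapping
# selection is replayed in plain R. Independent of the compiled alternation.
brute_force_count <- function(pattern, text) {
  n <- nchar(text)
  if (n == 0) return(0L)
  chars <- strsplit(text, "")[[1]]
  is_word <- grepl("[\\p{L}\\p{N}]", chars, perl = TRUE)
  prefix <- if (pattern$case_sensitive) "" else "(?i)"
  # anchored single-variant regexes, in the pattern's longest-first order
  vres <- paste0(prefix, "^(?:",
                 vapply(pattern$variants, soles:::variant_regex, character(1)),
                 ")")
  cands <- list()  # (start, end, rank)
  for (s in seq_len(n)) {
    if (s > 1 && is_word[s - 1]) next       # left boundary
    rest <- substr(text, s, n)
    for (k in seq_along(vres)) {
      m <- regexpr(vres[k], rest, perl = TRUE)
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      e <- s + len - 1L
      if (e < n && is_word[e + 1]) next     # right boundary
      cands[[length(cands) + 1L]] <- c(s, e, k)
    }
  }
  if (length(cands) == 0) return(0L)
  cand <- do.call(rbind, cands)
  count <- 0L
  pos <- 1L
  repeat {
    live <- cand[cand[, 1] >= pos, , drop = FALSE]
    if (nrow(live) == 0) break
    s <- min(live[, 1])
    at <- live[live[, 1] == s, , drop = FALSE]
    pick <- at[order(at[, 3], -at[, 2]), , drop = FALSE][1, ]
    count <- count + 1L
    pos <- pick[2] + 1L
  }
  count
}

# Exact rational-arithmetic metric oracle: half-up rounding to 3 decimals
# done entirely in integer arithmetic. Vectorised.
rational_metrics <- function(tp, fp, tn, fn) {
  r3 <- function(num, den) {
    q <- (num * 1000) %/% den
    r <- (num * 1000) %% den
    out <- (q + (2 * r >= den)) / 1000
    out[den == 0] <- NA_real_
    out
  }
  list(
    sensitivity = r3(tp, tp + fn),
    specificity = r3(tn, tn + fp),
    precision = r3(tp, tp + fp),
    f1 = r3(2 * tp, 2 * tp + fp + fn)
  )
}

# Random short texts that exercise boundaries: variants, confusable
# lookalikes, fillers, punctuation and digit adjacency.
random_match_texts <- function(n_texts, variants, seed) {
  pieces <- c(variants, paste0("P", toupper(variants)), paste0(variants, "23"),
              "the", "and", "42", "x", "rats", "(", ")", "/", "-", ",", ".",
              "study", "of")
  glue <- c(" ", " ", " ", "", "-", "/")
  soles:::with_seed(seed, {
    vapply(seq_len(n_texts), function(i) {
      k <- sample(3:10, 1)
      toks <- sample(pieces, k, replace = TRUE)
      seps <- sample(glue, k - 1, replace = TRUE)
      out <- toks[1]
      for (j in seq_len(k - 1)) out <- paste0(out, seps[j], toks[j + 1])
      substr(out, 1, 200)
    }, character(1))
  })
}
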