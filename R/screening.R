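# Pluggable in-vivo-relevance screening: baseline scorer, run evaluation,
# drift monitoring.

tokenize_text <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nchar(t) >= 2])
}

# Sparse document-term matrix over a fixed vocabulary.
dtm <- function(token_lists, vocab) {
  ij <- lapply(seq_along(token_lists), function(i) {
    idx <- match(token_lists[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return(NULL)
    tab <- table(idx)
    cbind(i = i, j = as.integer(names(tab)), x = as.numeric(tab))
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij)) ij <- matrix(numeric(), ncol = 3, dimnames = list(NULL, c("i", "j", "x")))
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3],
                       dims = c(length(token_lists), length(vocab)))
}

#' Train the baseline screening scorer
#'
#' The scorer contract: any deterministic-given-seed function mapping a
#' title+abstract text to a probability of inclusion qualifies. The shipped
#' baseline is a transparent linear bag-of-words model: ridge-penalised
#' logistic regression (glmnet, fixed lambda, no cross-validation) on token
#' counts. Retraining with identical data and seed reproduces identical
#' scores.
#'
#' @param decisions data frame with columns `uid`, `included` (logical) and
#'   optionally `n_reviewers`; training decisions should be reviewer-verified
#'   (`n_reviewers >= 2`).
#' @param texts named character vector mapping uid to title+abstract text.
#' @param seed integer seed.
#' @param lambda ridge penalty (default 0.05).
#' @return a `soles_scorer`: list with `score(texts)` returning probabilities
#'   in `[0, 1]`, plus `vocab` and `train_size`.
#' @export
train_scorer <- function(decisions, texts, seed = 1L, lambda = 0.05) {
  stopifnot(all(decisions$uid %in% names(texts)))
  y <- as.logical(decisions$included)
  if (length(unique(y)) < 2) stop("training data contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 decisions per class")
  x_txt <- unname(texts[decisions$uid])
  toks <- tokenize_text(x_txt)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) < 2) stop("training texts contain too few distinct tokens")
  X <- dtm(toks, vocab)
  fit <- with_seed(seed, glmnet::glmnet(X, factor(y), family = "binomial",
                                        alpha = 0, lambda = lambda,
                                        standardize = FALSE))
  scorer <- structure(list(vocab = vocab, fit = fit, lambda = lambda,
                           train_size = length(y), seed = seed),
                      class = "soles_scorer")
  scorer$score <- function(new_texts) {
    Xn <- dtm(tokenize_text(unname(new_texts)), vocab)
    p <- as.numeric(stats::predict(fit, newx = Xn, type = "response"))
    stats::setNames(p, names(new_texts))
  }
  scorer
}

#' @export
print.soles_scorer <- function(x, ...) {
  cat(sprintf("<screening scorer: bag-of-words ridge logistic, %d training decisions, %d terms>\n",
              x$train_size, length(x$vocab)))
  invisible(x)
}

#' Stratified holdout split
#'
#' @param decisions data frame with `uid` and `included`.
#' @param holdout fraction held out per class (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` decision data frames.
#' @export
split_holdout <- function(decisions, holdout = 0.2, seed = 1L) {
  with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(decisions)), decisions$included),
                              function(ix) {
      n_test <- max(1L, round(length(ix) * holdout))
      sample(ix, n_test)
    }))
    list(train = decisions[-test_idx, ], test = decisions[test_idx, ])
  })
}

#' Evaluate a screening run
#'
#' Predicts inclusion where score >= `threshold` (ties count as included),
#' tallies the confusion counts against the human truth, derives sensitivity,
#' specificity, precision and F1, and appends a run row to the log.
#'
#' @param scores named numeric vector, uid -> probability of inclusion.
#' @param truth data frame with `uid` and `included`; every scored uid must
#'   appear.
#' @param threshold decision threshold (default 0.5).
#' @param log existing run-log tibble, or `NULL` to start one.
#' @param train_size recorded on the run row.
#' @return the run log with the new row appended (class `soles_runlog`);
#'   columns `run_id`, `timestamp`, `train_size`, `threshold`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
evaluate_run <- function(scores, truth, threshold = 0.5, log = NULL,
                         train_size = NA_integer_) {
  if (nrow(truth) == 0) stop("empty truth set")
  missing <- setdiff(names(scores), truth$uid)
  if (length(missing)) stop("scored uids without truth: ",
                            paste(missing, collapse = ", "))
  truth_map <- stats::setNames(as.logical(truth$included), truth$uid)
  pred <- scores >= threshold
  actual <- truth_map[names(scores)]
  tp <- sum(pred & actual); fp <- sum(pred & !actual)
  tn <- sum(!pred & !actual); fn <- sum(!pred & actual)
  m <- compute_metrics(tp, fp, tn, fn)
  run_id <- if (is.null(log) || nrow(log) == 0) 1L else max(log$run_id) + 1L
  row <- tibble::tibble(
    run_id = run_id, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    train_size = train_size, threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = m$sensitivity, specificity = m$specificity,
    precision = m$precision, f1 = m$f1
  )
  out <- dplyr::bind_rows(log, row)
  class(out) <- c("soles_runlog", class(tibble::tibble()))
  out
}

#' Flag runs whose performance breaches the monitoring floors
#'
#' The living workflow retrains its classifier at every update; tracking
#' per-run metrics against floors signals when new training data are needed.
#'
#' @param log run-log tibble from [evaluate_run()].
#' @param floor_sens minimum acceptable sensitivity (default 0.90).
#' @param floor_spec minimum acceptable specificity (default 0.85).
#' @return integer vector of breaching `run_id`s.
#' @export
performance_drift <- function(log, floor_sens = 0.90, floor_spec = 0.85) {
  if (is.null(log) || nrow(log) == 0) stop("empty run log")
  bad <- (!is.na(log$sensitivity) & log$sensitivity < floor_sens) |
    (!is.na(log$specificity) & log$specificity < floor_spec)
  log$run_id[bad]
}

#' Read / write the screening run log
#'
#' Append-only CSV with one row per classifier run.
#'
#' @param path CSV path.
#' @return [read_runlog()] returns the log tibble.
#' @export
read_runlog <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("soles_runlog", class(tibble::tibble()))
  out
}

#' @rdname read_runlog
#' @param log run-log tibble.
#' @export
write_runlog <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
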