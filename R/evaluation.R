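# Tagging validation: confusion metrics, sampling, method scoring, and
# optimal-policy selection.

TAG_METHODS <- c("tiabkw", "fulltext_gt0", "fulltext_gt1", "fulltext_gt2",
                 "model_sentence")

# Methods applicable per category. The intervention dictionary is only ever
# applied to tiabkw (non-specific drug synonyms make full text unusable);
# outcomes have no model-sentence surface.
methods_for_category <- function(category) {
  switch(category,
    intervention = "tiabkw",
    outcome = c("fulltext_gt0", "fulltext_gt1", "fulltext_gt2", "tiabkw"),
    c("fulltext_gt0", "fulltext_gt1", "fulltext_gt2", "tiabkw", "model_sentence")
  )
}

# Does a candidate tagging method fire on the stored evidence counts?
# "full text > n" means strictly more than n matches. NA (surface absent)
# never fires.
method_fires <- function(method, tiabkw, fulltext, model_sentence) {
  thr <- function(x, min) !is.na(x) & x >= min
  switch(method,
    tiabkw = thr(tiabkw, 1),
    fulltext_gt0 = thr(fulltext, 1),
    fulltext_gt1 = thr(fulltext, 2),
    fulltext_gt2 = thr(fulltext, 3),
    model_sentence = thr(model_sentence, 1),
    stop("unknown method: ", method)
  )
}

#' Derive performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP) and
#' F1 (harmonic mean of precision and sensitivity, equivalently
#' 2TP/(2TP+FP+FN)). Reported values are rounded half-up to 3 decimals; the
#' unrounded fractions are retained in the `"raw"` attribute. A metric whose
#' denominator is zero is undefined (`NA`); the others are still computed.
#'
#' Vectorised: the four count arguments may be equal-length vectors.
#'
#' @param tp,fp,tn,fn non-negative integer counts; alternatively `tp` may be
#'   a list with elements `tp`, `fp`, `tn`, `fn`.
#' @return a tibble with columns `sensitivity`, `specificity`, `precision`,
#'   `f1` (3-decimal, half-up), with the unrounded fractions in
#'   `attr(, "raw")`.
#' @export
#' @examples
#' compute_metrics(104, 14, 195, 39)  # sensitivity 0.727, specificity 0.933
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  stopifnot(all(tp >= 0, na.rm = TRUE), all(fp >= 0, na.rm = TRUE),
            all(tn >= 0, na.rm = TRUE), all(fn >= 0, na.rm = TRUE))
  if (any(tp + fp + tn + fn == 0, na.rm = TRUE)) {
    stop("metric computation requires tp+fp+tn+fn > 0")
  }
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  raw <- tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn)
  )
  out <- tibble::as_tibble(lapply(raw, round_half_up, digits = 3))
  attr(out, "raw") <- raw
  out
}

#' Sample tagged records for manual validation
#'
#' Draws a uniform sample without replacement from the eligible stratum:
#' records carrying at least one tag in every required category under *every*
#' method applicable to that category (so the manual check can score all
#' methods on every sampled record). Reproducible given the seed.
#'
#' @param tagged a `soles_tags` tibble.
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @param require categories every sampled record must be fully tagged in.
#' @return character vector of sampled uids, with the eligible-stratum size
#'   in the `"stratum_size"` attribute.
#' @export
sample_for_validation <- function(tagged, n, seed = 1L,
                                  require = c("model", "sex", "species", "outcome")) {
  stopifnot(n >= 1)
  ev <- tagged[tagged$label != UNTAGGED_LABEL, ]
  eligible <- Reduce(intersect, lapply(require, function(cat) {
    rows <- ev[ev$category == cat, ]
    if (nrow(rows) == 0) return(character())
    ok_per_uid <- vapply(split(rows, rows$uid), function(g) {
      all(vapply(methods_for_category(cat), function(m) {
        any(method_fires(m, g$tiabkw_count, g$fulltext_count, g$model_sentence_count))
      }, logical(1)))
    }, logical(1))
    names(ok_per_uid)[ok_per_uid]
  }))
  if (length(eligible) < n) {
    stop("eligible stratum has only ", length(eligible),
         " records; cannot sample ", n)
  }
  out <- with_seed(seed, sample(sort(eligible), n))
  attr(out, "stratum_size") <- length(eligible)
  out
}

#' Read validation annotations
#'
#' CSV columns `uid,category,label,method,verdict,skip`; `verdict` is the
#' human TRUE/FALSE decision on the tag, `skip` marks records excluded from
#' validation (e.g. conference abstracts discovered during the manual check).
#'
#' @param path CSV path.
#' @return a tibble of annotations.
#' @export
read_annotations <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  df$verdict <- as.logical(df$verdict)
  if (!"skip" %in% names(df)) df$skip <- FALSE
  df$skip <- !is.na(df$skip) & as.logical(df$skip)
  df
}

#' Score tagging methods against human annotations
#'
#' For each (category, method) pair: a candidate tag is *proposed* by a
#' method when the method's rule fires on the stored match-count evidence
#' (replayed, never trusted from the annotation sheet). The union of
#' verdict-TRUE tags across all methods forms the reference set. Then
#' TP = proposed and verdict TRUE, FP = proposed and verdict FALSE,
#' FN = reference tags the method missed, and TN = verdict-FALSE candidates
#' the method did not propose — the "sensitivity versus all methods"
#' construction. Annotation rows flagged `skip` are excluded from all counts.
#'
#' @param annotations tibble from [read_annotations()] (the `method` column,
#'   if present, is ignored for counting: verdicts attach to the tag).
#' @param tagged the `soles_tags` evidence the annotations were drawn from.
#' @return a `soles_method_scores` tibble: one row per (category, method)
#'   with `tp`, `fp`, `tn`, `fn` and the derived metrics.
#' @export
score_methods <- function(annotations, tagged) {
  ann <- annotations[!annotations$skip, ]
  ann <- unique(ann[, c("uid", "category", "label", "verdict")])
  dup <- ann[duplicated(ann[, c("uid", "category", "label")]), ]
  if (nrow(dup) > 0) {
    stop("conflicting verdicts for: ",
         paste(paste(dup$uid, dup$category, dup$label, sep = "/"), collapse = ", "))
  }
  ev <- tagged[tagged$label != UNTAGGED_LABEL,
               c("uid", "category", "label", "tiabkw_count", "fulltext_count",
                 "model_sentence_count")]
  joined <- dplyr::left_join(ann, ev, by = c("uid", "category", "label"))
  orphan <- is.na(joined$tiabkw_count) & is.na(joined$fulltext_count) &
    is.na(joined$model_sentence_count)
  if (any(orphan)) {
    stop("annotations without evidence rows: ",
         paste(paste(joined$uid[orphan], joined$category[orphan],
                     joined$label[orphan], sep = "/"), collapse = ", "))
  }
  rows <- list()
  for (cat in sort(unique(joined$category))) {
    g <- joined[joined$category == cat, ]
    for (m in methods_for_category(cat)) {
      fired <- method_fires(m, g$tiabkw_count, g$fulltext_count,
                            g$model_sentence_count)
      tp <- sum(fired & g$verdict); fp <- sum(fired & !g$verdict)
      fn <- sum(!fired & g$verdict); tn <- sum(!fired & !g$verdict)
      met <- compute_metrics(tp, fp, tn, fn)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        category = cat, method = m, tp = tp, fp = fp, tn = tn, fn = fn,
        sensitivity = met$sensitivity, specificity = met$specificity,
        precision = met$precision, f1 = met$f1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("soles_method_scores", class(tibble::tibble()))
  out
}

#' Select the optimal tagging policy from method scores
#'
#' Per category: methods are *admitted* when their precision exceeds
#' `precision_floor - tolerance` (the tolerance makes the acceptance of
#' near-miss methods explicit and auditable — admitted methods at or below
#' the floor raise a warning). The tiabkw surface is enabled whenever
#' admitted. Among admitted non-tiabkw methods, those within
#' `sensitivity_window` of the best admitted precision are treated as having
#' "similar precision", and the one with the highest sensitivity is enabled
#' — precision is the primary criterion, sensitivity breaks near-ties. When
#' no method clears the floor and only a single method exists for the
#' category, that method is enabled with a warning rather than leaving the
#' category untaggable; otherwise selection stops with an error prompting a
#' manual choice.
#'
#' @param scores a `soles_method_scores` tibble (or any tibble with
#'   `category`, `method`, `precision`, `sensitivity`). Metrics are consumed
#'   as given.
#' @param precision_floor minimum precision for admission (default 0.80).
#' @param tolerance admission slack below the floor (default 0.01).
#' @param sensitivity_window precision band counted as "similar" when
#'   preferring sensitivity (default 0.05).
#' @param high_sensitivity passed through to the resulting policy.
#' @return a `soles_policy`; near-miss and fallback warnings are also
#'   collected in the `"warnings"` attribute.
#' @export
select_policy <- function(scores, precision_floor = 0.80, tolerance = 0.01,
                          sensitivity_window = 0.05, high_sensitivity = FALSE) {
  method_threshold <- list(
    tiabkw = c(field = "tiabkw_min", min = 1),
    fulltext_gt0 = c(field = "fulltext_min", min = 1),
    fulltext_gt1 = c(field = "fulltext_min", min = 2),
    fulltext_gt2 = c(field = "fulltext_min", min = 3),
    model_sentence = c(field = "model_sentence_min", min = 1)
  )
  cats <- list()
  warnings_out <- character()
  note <- function(msg) {
    warnings_out <<- c(warnings_out, msg)
    warning(msg, call. = FALSE)
  }
  for (cat in unique(scores$category)) {
    g <- scores[scores$category == cat, ]
    admitted <- !is.na(g$precision) & g$precision > (precision_floor - tolerance)
    for (k in which(admitted & g$precision <= precision_floor)) {
      note(sprintf("category '%s': method '%s' admitted as a near miss (precision %.3f <= floor %.2f)",
                   cat, g$method[k], g$precision[k], precision_floor))
    }
    entry <- list()
    if (any(admitted)) {
      adm <- g[admitted, ]
      if ("tiabkw" %in% adm$method) entry$tiabkw_min <- 1L
      non_tia <- adm[adm$method != "tiabkw", ]
      if (nrow(non_tia) > 0) {
        best_prec <- max(non_tia$precision)
        similar <- non_tia[non_tia$precision >= best_prec - sensitivity_window, ]
        pick <- similar[order(-similar$sensitivity, -similar$precision,
                              similar$method), ][1, ]
        th <- method_threshold[[pick$method]]
        entry[[th[["field"]]]] <- as.integer(th[["min"]])
      }
    } else if (nrow(g) == 1) {
      note(sprintf("category '%s': no method clears the precision floor; enabling the only available method '%s' (precision %.3f)",
                   cat, g$method[1], g$precision[1]))
      th <- method_threshold[[g$method[1]]]
      entry[[th[["field"]]]] <- as.integer(th[["min"]])
    } else {
      stop("no method admitted for category '", cat,
           "' (best precision ", max(g$precision, na.rm = TRUE),
           "); choose manually")
    }
    cats[[cat]] <- entry
  }
  pol <- tag_policy(cats, high_sensitivity = high_sensitivity)
  attr(pol, "warnings") <- warnings_out
  pol
}

#' Bundled tagging-validation method table
#'
#' The published validation of dictionary tagging in an Alzheimer's-disease
#' in-vivo evidence corpus: a single reviewer checked every candidate tag on
#' a random sample of studies (98 after excluding two conference abstracts),
#' yielding per-(category, method) confusion counts and metrics. Both the
#' printed metric values and the raw counts are carried; the printed
#' precision of a few rows differs in the third decimal from the value the
#' counts imply, so analyses state which they use.
#'
#' @return a tibble with columns `category`, `method`, `specificity`,
#'   `sensitivity`, `precision` (as printed; `NA` where undefined), and the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
tagging_validation_table <- function() {
  path <- system.file("extdata", "ad_tagging_validation.csv", package = "soles",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Export a method-score table as CSV
#'
#' @param scores a `soles_method_scores` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_method_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  invisible(path)
}
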