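# Scoring mapping outcomes against a curated gold standard: confusion
# matrices, precision, recall, coverage.
#
# Counting units are deliberately asymmetric. tp, tn and fn count query
# TERMS (a term is recovered, correctly left unmapped, or missed), while
# fp counts candidate PAIRS: every wrongly accepted (term, class) pair
# and, when proposals are counted, every wrong proposed pair. A
# proposal-generating matcher can emit tens of candidates per term, so
# fp can legitimately dwarf the term count; that regime is exactly what a
# curator faces when triaging sound-alike proposals, and it is the only
# accounting under which such confusion matrices are arithmetically
# coherent.

#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative counts (terms for tp/tn/fn, candidate
#'   pairs for fp; see the note on counting units in
#'   [compare_to_gold()]).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("confusion-matrix cells must be non-negative")
  }
  vals <- as.integer(vals)
  structure(list(tp = vals[[1]], fp = vals[[2]], tn = vals[[3]],
                 fn = vals[[4]]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Read a gold-standard mapping TSV
#'
#' Two columns, `term<TAB>ontology_id[;ontology_id...]`; an empty second
#' column marks a term that is correctly unmappable.
#'
#' @param path TSV path (no header).
#' @param config Normalizer applied to the term column so gold keys agree
#'   with the run's normalized queries.
#' @return Named list: normalized term -> character vector of class ids
#'   (possibly empty).
#' @export
read_gold_tsv <- function(path, config = normalizer_config()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1L), 1L)
  idcol <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else "",
                  character(1L))
  gold <- lapply(idcol, function(x) {
    ids <- strsplit(x, ";", fixed = TRUE)[[1]]
    ids[nzchar(trimws(ids))]
  })
  names(gold) <- vapply(terms,
                        function(x) normalize_text(x, config)$normalized,
                        character(1L), USE.NAMES = FALSE)
  gold
}

#' Score outcomes against a gold standard
#'
#' Confusion-matrix cells:
#' \itemize{
#'   \item tp: gold-mapped terms whose accepted set intersects their gold
#'     set;
#'   \item fn: gold-mapped terms with no such intersection;
#'   \item tn: gold-unmappable terms (empty gold set) with an empty
#'     accepted set;
#'   \item fp: accepted (term, class) pairs absent from gold, plus --
#'     when `count_proposals = TRUE` -- every proposed-but-unaccepted
#'     pair absent from gold. Proposal counting is how a
#'     proposal-generating phonetic matcher accrues false-positive counts
#'     far above the term total.
#' }
#'
#' @param result A `mapping_result` from [run_matcher()].
#' @param gold Named list (normalized term -> character vector of ids;
#'   empty vector = correctly unmappable), e.g. from [read_gold_tsv()].
#'   Every query in `result` must be present.
#' @param count_proposals Count unaccepted proposals as false positives
#'   (default `FALSE`).
#' @return A [confusion_matrix()].
#' @export
compare_to_gold <- function(result, gold, count_proposals = FALSE) {
  stopifnot(inherits(result, "mapping_result"), is.list(gold))
  queries <- result$outcomes$query
  missing <- setdiff(queries, names(gold))
  if (length(missing)) {
    stop("gold standard is missing these query terms: ",
         paste(missing, collapse = ", "))
  }
  cands <- result$candidates
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    g <- gold[[q]]
    qc <- cands[cands$query == q, , drop = FALSE]
    acc <- unique(qc$class_id[qc$accepted])
    prop <- setdiff(unique(qc$class_id[!qc$accepted]), acc)
    if (length(g)) {
      if (length(intersect(acc, g))) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (length(acc) == 0L) tn <- tn + 1L
    }
    fp <- fp + length(setdiff(acc, g))
    if (count_proposals) fp <- fp + length(setdiff(prop, g))
  }
  confusion_matrix(tp, fp, tn, fn)
}

# half-up rounding at the printed precision (base round() is half-even)
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Precision
#'
#' `tp / (tp + fp)`, reported at 3 decimals (half-up). An empty
#' denominator yields `NA` -- undefined, never silently zero or one.
#'
#' @param cm A [confusion_matrix()].
#' @param digits Decimals for reporting (default 3); `NULL` returns full
#'   precision.
#' @return A single number, or `NA` when `tp + fp == 0`.
#' @export
precision <- function(cm, digits = 3) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fp == 0L) return(NA_real_)
  v <- cm$tp / (cm$tp + cm$fp)
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Recall
#'
#' `tp / (tp + fn)`, reported at 3 decimals (half-up). An empty
#' denominator yields `NA`.
#'
#' @inheritParams precision
#' @return A single number, or `NA` when `tp + fn == 0`.
#' @export
recall <- function(cm, digits = 3) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0L) return(NA_real_)
  v <- cm$tp / (cm$tp + cm$fn)
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Ontology coverage of a term corpus
#'
#' Percentage of corpus terms found in an ontology:
#' `100 * matched / total`, reported at 2 decimals (half-up).
#'
#' @param matched Number of matched terms (0 <= matched <= total).
#' @param total Total number of terms (> 0).
#' @param digits Decimals for reporting (default 2); `NULL` returns full
#'   precision.
#' @return A percentage.
#' @examples
#' coverage(229, 1099)
#' coverage(277, 1099)
#' @export
coverage <- function(matched, total, digits = 2) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0) {
    stop("total must be a positive number")
  }
  if (!is.numeric(matched) || length(matched) != 1L ||
      matched < 0 || matched > total) {
    stop("matched must satisfy 0 <= matched <= total")
  }
  v <- 100 * matched / total
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Full metrics report for one run
#'
#' @param cm A [confusion_matrix()].
#' @param matched_count Number of matched terms (defaults to `cm$tp`).
#' @param total_terms Total terms in the corpus (defaults to
#'   `cm$tp + cm$fn + cm$tn`).
#' @return One-row tibble: tp, fp, tn, fn, precision, recall,
#'   coverage_percent, matched_count, total_terms.
#' @export
metrics_report <- function(cm, matched_count = cm$tp,
                           total_terms = cm$tp + cm$fn + cm$tn) {
  tibble::tibble(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                 precision = precision(cm),
                 recall = recall(cm),
                 coverage_percent = coverage(matched_count, total_terms),
                 matched_count = as.integer(matched_count),
                 total_terms = as.integer(total_terms))
}
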