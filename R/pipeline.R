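# End-to-end orchestration: preprocess -> index -> match (per run
# configuration) -> evaluate -> report, mirroring a tools-by-ontologies
# study grid. Output files carry a UTC timestamp in the FILENAME only;
# file contents are timestamp-free so runs diff cleanly.

#' Read an annotation term list TSV
#'
#' @param path Path to a UTF-8 TSV, `term<TAB>species` (species column
#'   optional).
#' @param header Does the file carry a header row (default `FALSE`)?
#' @return Tibble with `text` and `species` columns.
#' @export
read_terms_tsv <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, sep = "\t", quote = "",
                          comment.char = "", colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 1L) stop("term file has no columns: ", path)
  names(df)[1] <- "text"
  if (ncol(df) >= 2L) names(df)[2] <- "species" else df$species <- ""
  tibble::as_tibble(df[, c("text", "species")])
}

#' One run configuration of the study grid
#'
#' Bundles an ontology with a matcher configuration under a display name.
#'
#' @param name Short run label, e.g. `"exact/toy"`.
#' @param ontology An `ontology` object, or a path to an `.obo` file or
#'   2-column lexicon TSV.
#' @param mode `"exact"` or `"phonetic"` (see [match_config()]).
#' @param ... Stage toggles and tables forwarded to [match_config()].
#' @param count_proposals Whether evaluation counts unaccepted proposals
#'   as false positives; defaults to `TRUE` in phonetic mode, which is
#'   the accounting that makes proposal-generating matchers show their
#'   true curation cost.
#' @param curations Optional curation tibble (`term`, `class_id`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(name, ontology, mode = "exact", ...,
                       count_proposals = identical(mode, "phonetic"),
                       curations = NULL) {
  structure(list(name = name, ontology = ontology,
                 match = match_config(mode = mode, ...),
                 count_proposals = count_proposals,
                 curations = curations),
            class = "run_config")
}

load_ontology <- function(x) {
  if (inherits(x, "ontology")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("ontology file not found: ", x)
  if (grepl("\\.obo$", x, ignore.case = TRUE)) parse_obo(x)
  else read_lexicon_tsv(x)
}

utc_stamp <- function() format(Sys.time(), "%Y%m%dT%H%M%SZ", tz = "UTC")

#' Write accepted and proposed matches for one run
#'
#' @param result A `mapping_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(result, path) {
  cc <- result$candidates
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%s", cc$query, cc$class_id,
                   cc$match_kind, cc$evidence, cc$rank,
                   ifelse(cc$accepted, "accepted", "proposed"))
  writeLines(c("term\tclass_id\tmatch_kind\tevidence\trank\tdecision",
               lines), path, useBytes = TRUE)
  invisible(path)
}

#' Write matching failures for one run
#'
#' @param result A `mapping_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_failures <- function(result, path) {
  oc <- result$outcomes[result$outcomes$status != "matched", , drop = FALSE]
  writeLines(c("term\treason",
               sprintf("%s\t%s", oc$query,
                       ifelse(nzchar(oc$reason), oc$reason, oc$status))),
             path, useBytes = TRUE)
  invisible(path)
}

#' Run the full study grid
#'
#' Normalizes and deduplicates a raw term list once, then for every run
#' configuration builds the ontology index, runs the matching cascade,
#' and (when a gold standard is supplied) scores the outcome. The
#' summary table is the runs-by-metrics grid; per-run artefacts are
#' written under `outdir` when given (`matches_<UTC>.tsv`,
#' `failures_<UTC>.tsv` per run, plus `summary.tsv` and `summary.json`).
#'
#' @param terms Raw terms: a path to a `term<TAB>species` TSV, a tibble
#'   with `text`/`species` columns, or a character vector.
#' @param configs List of [run_config()] objects (at least one).
#' @param gold Optional gold standard: a named list (normalized term ->
#'   id vector) or a path to a gold TSV.
#' @param evaluate Score against gold (default: whenever `gold` is
#'   supplied); requesting evaluation without gold is an error.
#' @param outdir Optional output directory.
#' @param normalizer Shared [normalizer_config()].
#' @param lexicon Species lexicon for stripping (see [strip_species()]).
#' @return A `study_report`: list with `summary` (one row per run:
#'   matched/proposed_only/unmatched counts and, when evaluated,
#'   tp/fp/tn/fn, precision, recall, coverage_percent), `runs` (named
#'   list of per-run details), `terms` (the cleaned term table).
#' @export
run_study <- function(terms, configs, gold = NULL,
                      evaluate = !is.null(gold), outdir = NULL,
                      normalizer = normalizer_config(),
                      lexicon = species_lexicon()) {
  if (length(configs) == 0L) stop("at least one run_config is required")
  stopifnot(all(vapply(configs, inherits, logical(1L), "run_config")))
  if (evaluate && is.null(gold)) {
    stop("evaluation requested but no gold standard supplied")
  }

  if (is.character(terms) && length(terms) == 1L && file.exists(terms)) {
    terms <- read_terms_tsv(terms)
  } else if (is.character(terms)) {
    terms <- tibble::tibble(text = terms, species = "")
  }
  stopifnot(is.data.frame(terms), "text" %in% names(terms))
  if (nrow(terms) == 0L) stop("empty term list")
  if (!"species" %in% names(terms)) terms$species <- ""

  clean <- normalize_terms(terms$text, terms$species, normalizer, lexicon)
  clean <- deduplicate(clean)
  clean <- clean[clean$usable, , drop = FALSE]

  if (is.character(gold)) gold <- read_gold_tsv(gold, normalizer)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }

  ord <- order(vapply(configs, function(cf) cf$match$mode, character(1L)),
               vapply(configs, function(cf) cf$name, character(1L)))
  configs <- configs[ord]

  runs <- list()
  summary_rows <- list()
  for (cf in configs) {
    ont <- load_ontology(cf$ontology)
    index <- build_index(ont, normalizer)
    result <- run_matcher(clean, index, cf$match, curations = cf$curations)
    tab <- table(factor(result$outcomes$status,
                        levels = c("matched", "proposed_only", "unmatched")))
    row <- tibble::tibble(run = cf$name, mode = cf$match$mode,
                          n_terms = nrow(result$outcomes),
                          matched = as.integer(tab[["matched"]]),
                          proposed_only = as.integer(tab[["proposed_only"]]),
                          unmatched = as.integer(tab[["unmatched"]]))
    detail <- list(config = cf, result = result)
    if (evaluate) {
      cm <- compare_to_gold(result, gold, cf$count_proposals)
      met <- metrics_report(cm, matched_count = row$matched,
                            total_terms = row$n_terms)
      row <- tibble::as_tibble(cbind(row, met[, c("tp", "fp", "tn", "fn",
                                                  "precision", "recall",
                                                  "coverage_percent")]))
      detail$cm <- cm
      detail$metrics <- met
    }
    if (!is.null(outdir)) {
      safe <- gsub("[^A-Za-z0-9._-]+", "_", cf$name)
      ts <- utc_stamp()
      write_matches(result,
                    file.path(outdir, sprintf("%s_matches_%s.tsv", safe, ts)))
      write_failures(result,
                     file.path(outdir, sprintf("%s_failures_%s.tsv", safe, ts)))
    }
    runs[[cf$name]] <- detail
    summary_rows[[length(summary_rows) + 1L]] <- row
  }

  summary <- do.call(rbind, summary_rows)
  if (!is.null(outdir)) {
    utils::write.table(summary, file.path(outdir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(summary = summary, runs = runs, terms = clean),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$summary)
  invisible(x)
}
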