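# OBO reading and lexical indexing. Only the lexical surface of an
# ontology is modelled (ids, labels, synonyms with scope, obsolete flags);
# graph structure and reasoning are out of scope.

#' Construct an ontology object from class and synonym tables
#'
#' @param classes Data frame with columns `id`, `label`, `obsolete`.
#' @param synonyms Data frame with columns `id`, `text`, `scope`
#'   (scope one of EXACT, BROAD, NARROW, RELATED); may be empty.
#' @return An object of class `ontology`.
#' @export
as_ontology <- function(classes, synonyms = NULL) {
  classes <- tibble::as_tibble(classes)
  stopifnot(all(c("id", "label") %in% names(classes)))
  if (!"obsolete" %in% names(classes)) classes$obsolete <- FALSE
  classes$id <- as.character(classes$id)
  classes$label <- as.character(classes$label)
  if (any(!nzchar(classes$id))) stop("ontology class ids must be non-empty")
  if (anyDuplicated(classes$id)) {
    stop("duplicate ontology class ids: ",
         paste(unique(classes$id[duplicated(classes$id)]), collapse = ", "))
  }
  bad <- !classes$obsolete & !nzchar(trimws(classes$label))
  if (any(bad)) {
    stop("non-obsolete classes must have a label: ",
         paste(classes$id[bad], collapse = ", "))
  }
  if (is.null(synonyms)) {
    synonyms <- tibble::tibble(id = character(), text = character(),
                               scope = character())
  }
  synonyms <- tibble::as_tibble(synonyms)
  stopifnot(all(c("id", "text", "scope") %in% names(synonyms)))
  if (nrow(synonyms) &&
      !all(synonyms$scope %in% c("EXACT", "BROAD", "NARROW", "RELATED"))) {
    stop("synonym scope must be EXACT, BROAD, NARROW or RELATED")
  }
  structure(list(classes = classes[, c("id", "label", "obsolete")],
                 synonyms = synonyms[, c("id", "text", "scope")]),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d classes (%d obsolete), %d synonyms\n",
              nrow(x$classes), sum(x$classes$obsolete), nrow(x$synonyms)))
  invisible(x)
}

#' Parse an OBO flat file
#'
#' Reads the lexical surface of an OBO 1.2/1.4 flat file: one class per
#' `[Term]` stanza with its `id`, `name`, `synonym` tags (scope keyword
#' read from the tag, defaulting to RELATED when absent) and
#' `is_obsolete` flag. Everything else (relationships, xrefs, defs) is
#' ignored.
#'
#' @param path Path to an OBO file.
#' @return An `ontology` object (see [as_ontology()]).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  ids <- character(); labels <- character(); obs <- logical()
  syn_id <- character(); syn_text <- character(); syn_scope <- character()

  in_term <- FALSE
  cur <- NULL
  start_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id) || !nzchar(cur$id)) {
      stop(sprintf("OBO parse error: [Term] stanza at line %d has no id tag",
                   start_line))
    }
    ids <<- c(ids, cur$id)
    labels <<- c(labels, if (is.na(cur$name)) "" else cur$name)
    obs <<- c(obs, isTRUE(cur$obsolete))
    if (length(cur$syn_text)) {
      syn_id <<- c(syn_id, rep(cur$id, length(cur$syn_text)))
      syn_text <<- c(syn_text, cur$syn_text)
      syn_scope <<- c(syn_scope, cur$syn_scope)
    }
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "[")) {
      flush()
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NA_character_, name = NA_character_,
                    obsolete = FALSE,
                    syn_text = character(), syn_scope = character())
        start_line <- i
      }
      next
    }
    if (!in_term || !nzchar(ln) || startsWith(ln, "!")) next
    ln <- sub("\\s*!.*$", "", ln)            # trailing comments
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    } else if (startsWith(ln, "synonym:")) {
      body <- trimws(sub("^synonym:", "", ln))
      m <- regmatches(body, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]*)', body))[[1]]
      if (length(m) < 2L || !nzchar(m[[2]])) next
      text <- gsub('\\\\(.)', "\\1", m[[2]])
      scope <- m[[3]]
      if (!scope %in% c("EXACT", "BROAD", "NARROW", "RELATED")) scope <- "RELATED"
      cur$syn_text <- c(cur$syn_text, text)
      cur$syn_scope <- c(cur$syn_scope, scope)
    }
  }
  flush()

  as_ontology(
    tibble::tibble(id = ids, label = labels, obsolete = obs),
    tibble::tibble(id = syn_id, text = syn_text, scope = syn_scope)
  )
}

#' Read a two-column lexicon TSV as an ontology
#'
#' Accepts a minimal `id<TAB>label` file (no synonyms, nothing obsolete),
#' a convenient fixture format when a full OBO file is overkill.
#'
#' @param path Path to a headerless 2-column TSV.
#' @return An `ontology` object.
#' @export
read_lexicon_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          quote = "", comment.char = "",
                          col.names = c("id", "label"),
                          colClasses = "character", fileEncoding = "UTF-8")
  as_ontology(tibble::tibble(id = df$id, label = df$label, obsolete = FALSE))
}

#' Write an ontology as an OBO flat file
#'
#' @param ontology An `ontology` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "ontology"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology$classes))) {
    cl <- ontology$classes[i, ]
    out <- c("[Term]", paste0("id: ", cl$id))
    if (nzchar(cl$label)) out <- c(out, paste0("name: ", cl$label))
    syn <- ontology$synonyms[ontology$synonyms$id == cl$id, , drop = FALSE]
    if (nrow(syn)) {
      out <- c(out, sprintf('synonym: "%s" %s []', syn$text, syn$scope))
    }
    if (cl$obsolete) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Build a lexical and phonetic index over an ontology
#'
#' Normalizes every admissible label and synonym with the supplied
#' configuration and indexes the result two ways: a lexical map
#' (normalized string -> classes carrying it) and a phonetic map
#' (Double Metaphone codes per indexed string). By default only EXACT
#' synonyms are indexed and obsolete classes are excluded.
#'
#' @param ontology An `ontology` object.
#' @param config A [normalizer_config()]; stored in the index so matchers
#'   can verify both sides of a comparison used the same normalization.
#' @param synonym_scopes Synonym scopes to admit (default `"EXACT"`;
#'   `c("EXACT","BROAD","NARROW","RELATED")` widens to all).
#' @param include_obsolete Index obsolete classes too (default `FALSE`).
#' @return A `term_index`: list with `lexical` (tibble `key`, `id`,
#'   `origin`), `phonetic` (tibble `key`, `primary`, `alternate`, one row
#'   per distinct key), and the build `config`.
#' @export
build_index <- function(ontology, config = normalizer_config(),
                        synonym_scopes = "EXACT",
                        include_obsolete = FALSE) {
  stopifnot(inherits(ontology, "ontology"),
            inherits(config, "normalizer_config"))
  classes <- ontology$classes
  if (nrow(classes) == 0L) stop("cannot index an empty ontology")
  if (!include_obsolete) classes <- classes[!classes$obsolete, , drop = FALSE]
  syn <- ontology$synonyms
  syn <- syn[syn$scope %in% synonym_scopes & syn$id %in% classes$id, ,
             drop = FALSE]

  raw <- c(classes$label, syn$text)
  ids <- c(classes$id, syn$id)
  origin <- c(rep("label", nrow(classes)),
              if (nrow(syn)) paste0("synonym:", syn$scope) else character())
  keep <- nzchar(trimws(raw))
  raw <- raw[keep]; ids <- ids[keep]; origin <- origin[keep]

  key <- vapply(raw, function(x) normalize_text(x, config)$normalized,
                character(1L), USE.NAMES = FALSE)
  lexical <- tibble::tibble(key = key, id = ids, origin = origin)
  lexical <- unique(lexical)
  lexical <- lexical[order(lexical$key, lexical$id, lexical$origin), ,
                     drop = FALSE]

  uk <- unique(lexical$key)
  codes <- phonetic_encode(uk)
  phonetic <- tibble::tibble(key = codes$text, primary = codes$primary,
                             alternate = codes$alternate)
  phonetic <- phonetic[order(phonetic$key), , drop = FALSE]

  structure(list(lexical = lexical, phonetic = phonetic,
                 lookup = split(seq_len(nrow(lexical)), lexical$key),
                 config = config,
                 fingerprint = config_fingerprint(config),
                 synonym_scopes = synonym_scopes,
                 include_obsolete = include_obsolete),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat(sprintf(
    "<term_index> %d entries over %d distinct strings (%d classes)\n",
    nrow(x$lexical), length(unique(x$lexical$key)),
    length(unique(x$lexical$id))))
  invisible(x)
}

#' Index keys
#'
#' @param index A `term_index`.
#' @return Character vector of distinct normalized strings in the index.
#' @export
index_keys <- function(index) {
  stopifnot(inherits(index, "term_index"))
  unique(index$lexical$key)
}

#' Find labels shared by several classes
#'
#' Lexical QC: normalized primary labels carried by two or more distinct
#' non-obsolete classes. Large ontologies accumulate such duplications
#' (the same structure entered twice under different ids) and they are
#' worth reporting upstream.
#'
#' @param ontology An `ontology` object.
#' @param config A [normalizer_config()] used to normalize labels before
#'   comparison (detection is case-insensitive after normalization).
#' @return A tibble with `label` (normalized) and `ids` (list column of
#'   sorted class-id character vectors), ordered by label.
#' @export
find_duplicate_labels <- function(ontology, config = normalizer_config()) {
  stopifnot(inherits(ontology, "ontology"))
  classes <- ontology$classes[!ontology$classes$obsolete, , drop = FALSE]
  if (nrow(classes) == 0L) {
    return(tibble::tibble(label = character(), ids = list()))
  }
  key <- vapply(classes$label,
                function(x) normalize_text(x, config)$normalized,
                character(1L), USE.NAMES = FALSE)
  groups <- split(classes$id, key)
  groups <- lapply(groups, function(v) sort(unique(v)))
  groups <- groups[vapply(groups, length, integer(1L)) >= 2L]
  groups <- groups[order(names(groups))]
  tibble::tibble(label = names(groups), ids = unname(groups))
}

#' Write a duplicate-label QC report
#'
#' @param duplicates Output of [find_duplicate_labels()].
#' @param path Output TSV path (`label<TAB>comma-joined ids`).
#' @return `path`, invisibly.
#' @export
write_duplicate_report <- function(duplicates, path) {
  lines <- sprintf("%s\t%s", duplicates$label,
                   vapply(duplicates$ids, paste, character(1L),
                          collapse = ","))
  writeLines(c("label\tids", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Lexical overlap between two term indexes
#'
#' Jaccard overlap of the two indexes' normalized string sets, as a
#' percentage: `100 * |A intersect B| / |A union B|`. Symmetric by
#' construction. Both indexes must have been built with identical
#' normalizer configurations, otherwise string equality is meaningless.
#'
#' @param a,b `term_index` objects.
#' @return A single number in \[0, 100\].
#' @export
lexical_overlap <- function(a, b) {
  stopifnot(inherits(a, "term_index"), inherits(b, "term_index"))
  if (!identical(a$fingerprint, b$fingerprint)) {
    stop("indexes were built with different normalizer configurations")
  }
  ka <- index_keys(a); kb <- index_keys(b)
  u <- union(ka, kb)
  if (length(u) == 0L) return(100)
  100 * length(intersect(ka, kb)) / length(u)
}
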