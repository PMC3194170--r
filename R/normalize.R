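# Annotation-term normalization: the cleanup applied to free-text anatomy
# annotations before any matching, and equally to ontology labels/synonyms
# at index-build time so both sides of a comparison share one surface form.

#' Normalizer configuration
#'
#' Settings controlling text normalization. The same configuration object
#' must be used on both the annotation side and the index side of a run;
#' [build_index()] stores it and matchers check it.
#'
#' @param casefold Lower-case everything (default `TRUE`).
#' @param hyphen_policy What to do with hyphens: `"space"` (replace by a
#'   single space, the default), `"delete"`, or `"keep"`.
#' @param strip_control Remove control and other non-printing characters
#'   (default `TRUE`). Non-printing characters are a documented source of
#'   silent match failures: a matcher sees them, a curator does not.
#' @param americanize Apply the British-to-American spelling table
#'   (default `TRUE`).
#' @param anglicism_table Named character vector, `names` = British form,
#'   values = American form. Defaults to [default_anglicism_table()].
#' @return An object of class `normalizer_config`.
#' @export
normalizer_config <- function(casefold = TRUE,
                              hyphen_policy = c("space", "delete", "keep"),
                              strip_control = TRUE,
                              americanize = TRUE,
                              anglicism_table = default_anglicism_table()) {
  hyphen_policy <- match.arg(hyphen_policy)
  if (americanize && length(anglicism_table) &&
      is.null(names(anglicism_table))) {
    stop("anglicism_table must be a named character vector (British -> American)")
  }
  structure(
    list(casefold = casefold,
         hyphen_policy = hyphen_policy,
         strip_control = strip_control,
         americanize = americanize,
         anglicism_table = anglicism_table),
    class = "normalizer_config"
  )
}

#' @export
print.normalizer_config <- function(x, ...) {
  cat("<normalizer_config>",
      sprintf("  casefold: %s | hyphens: %s | control-strip: %s",
              x$casefold, x$hyphen_policy, x$strip_control),
      sprintf("  americanize: %s (%d word pairs)",
              x$americanize, length(x$anglicism_table)),
      sep = "\n")
  invisible(x)
}

# stable fingerprint used to refuse cross-config index comparisons
config_fingerprint <- function(config) {
  stopifnot(inherits(config, "normalizer_config"))
  tab <- config$anglicism_table
  tab <- tab[order(names(tab))]
  paste(config$casefold, config$hyphen_policy, config$strip_control,
        config$americanize,
        paste(names(tab), tab, sep = ">", collapse = ";"),
        sep = "|")
}

#' Default British-to-American spelling table
#'
#' Anatomy-relevant word pairs converting British spellings to the American
#' forms that the large anatomy ontologies use as primary labels. The table
#' is a plain named character vector and can be edited or replaced wholesale
#' in [normalizer_config()].
#'
#' @return Named character vector; names are British forms, values American.
#' @export
default_anglicism_table <- function() {
  c(oesophagus  = "esophagus",  oesophageal = "esophageal",
    oedema      = "edema",      oestrogen   = "estrogen",
    oestrus     = "estrus",     foetus      = "fetus",
    foetal      = "fetal",      coeliac     = "celiac",
    caecum      = "cecum",      caecal      = "cecal",
    haemal      = "hemal",      haematoma   = "hematoma",
    haemorrhage = "hemorrhage", haemopoietic = "hemopoietic",
    haematopoietic = "hematopoietic",
    anaemia     = "anemia",     leukaemia   = "leukemia",
    tumour      = "tumor",      colour      = "color",
    labour      = "labor",      behaviour   = "behavior",
    fibre       = "fiber",      centre      = "center",
    goitre      = "goiter",     calibre     = "caliber",
    litre       = "liter",      metre       = "meter",
    anaesthesia = "anesthesia", paediatric  = "pediatric",
    gynaecology = "gynecology", orthopaedic = "orthopedic",
    diarrhoea   = "diarrhea",   dyspnoea    = "dyspnea",
    homologue   = "homolog",    analogue    = "analog",
    grey        = "gray",       sulphur     = "sulfur",
    aetiology   = "etiology",   anaplastic  = "anaplastic",
    vapour      = "vapor")
}

#' Default species lexicon
#'
#' Binomial names and common vernaculars of the vertebrate species that
#' dominate functional-genomics annotation, used by [strip_species()] to
#' remove species words embedded in anatomical terms.
#'
#' @return Character vector of species names and vernaculars.
#' @export
species_lexicon <- function() {
  c("homo sapiens", "mus musculus", "rattus norvegicus", "bos taurus",
    "pan troglodytes", "gallus gallus", "danio rerio", "xenopus laevis",
    "macaca mulatta", "sus scrofa", "canis familiaris", "ovis aries",
    "oryctolagus cuniculus", "equus caballus",
    "human", "mouse", "murine", "rat", "bovine", "cow", "chimpanzee",
    "chicken", "zebrafish", "frog", "macaque", "pig", "porcine", "dog",
    "canine", "sheep", "rabbit", "horse")
}

#' Remove species names from annotation text
#'
#' Deletes whole-word occurrences of the paired species name (and of any
#' lexicon entry) from an annotation string, collapsing the surrounding
#' whitespace. Anatomy terms are matched species-agnostically, so "mouse
#' liver" and "liver" must reduce to the same query.
#'
#' @param text Character vector of annotation strings.
#' @param species Character vector (recycled) of paired species names; may
#'   be `""` when the annotation carries no species.
#' @param lexicon Extra species names/vernaculars always removed; defaults
#'   to [species_lexicon()].
#' @return Character vector, same length as `text`, with a `"stripped"`
#'   logical attribute marking elements that changed.
#' @examples
#' strip_species("mouse liver", "")
#' strip_species("annulus fibrosus", "Bos taurus")
#' @export
strip_species <- function(text, species = "", lexicon = species_lexicon()) {
  stopifnot(is.character(text), is.character(species))
  if (any(!nzchar(trimws(lexicon)))) stop("lexicon entries must be non-empty")
  species <- rep_len(species, length(text))
  esc <- function(p) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)
  alternation <- function(pats) {
    pats <- unique(trimws(pats))
    pats <- pats[nzchar(pats)]
    if (length(pats) == 0L) return(NULL)
    # longest first so "mus musculus" wins over any single-word entry
    pats <- pats[order(-nchar(pats))]
    paste0("(?i)\\b(", paste(esc(pats), collapse = "|"), ")\\b")
  }
  lex_re <- alternation(lexicon)

  out <- character(length(text))
  stripped <- logical(length(text))
  extra <- nzchar(trimws(species)) &
    !tolower(trimws(species)) %in% tolower(lexicon)
  for (i in seq_along(text)) {
    x <- text[[i]]
    if (extra[[i]]) {
      x <- gsub(alternation(species[[i]]), " ", x, perl = TRUE)
    }
    if (!is.null(lex_re)) x <- gsub(lex_re, " ", x, perl = TRUE)
    x <- trimws(gsub("\\s+", " ", x))
    stripped[[i]] <- !identical(x, trimws(gsub("\\s+", " ", text[[i]])))
    out[[i]] <- x
  }
  attr(out, "stripped") <- stripped
  out
}

#' Normalize one annotation string
#'
#' Applies, in a fixed order, the cleanup rules used before matching:
#' control-character removal, whitespace collapse and trim, case folding,
#' punctuation/hyphen unification, and British-to-American respelling.
#' The order is fixed so that the recorded provenance is deterministic.
#'
#' @param text A length-1 character vector.
#' @param config A [normalizer_config()].
#' @return A `clean_term` object: list with `original`, `normalized`, and
#'   `steps` (character vector of the transformation tags that fired, in
#'   application order; among `control_char_strip`, `whitespace`,
#'   `casefold`, `punctuation`, `americanize`).
#' @examples
#' normalize_text("Adrenal  Gland ")
#' normalize_text("oesophagus")
#' @export
normalize_text <- function(text, config = normalizer_config()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  stopifnot(inherits(config, "normalizer_config"))
  if (!nzchar(trimws(text))) stop_unusable(text)

  x <- text
  steps <- character()
  mark <- function(before, after, tag) {
    if (!identical(before, after)) steps <<- c(steps, tag)
    after
  }

  if (config$strip_control) {
    # ASCII controls plus the usual invisible troublemakers (NBSP,
    # zero-width space/joiner, BOM) that hide inside pasted annotations
    cleaned <- gsub("[\\x01-\\x1f\\x7f]|\u00a0|\u200b|\u200c|\u200d|\ufeff",
                    "", x, perl = TRUE)
    x <- mark(x, cleaned, "control_char_strip")
  }
  x <- mark(x, trimws(gsub("\\s+", " ", x)), "whitespace")
  if (config$casefold) {
    x <- mark(x, tolower(x), "casefold")
  }
  before <- x
  if (config$hyphen_policy == "space") {
    x <- gsub("[-_]+", " ", x)
  } else if (config$hyphen_policy == "delete") {
    x <- gsub("[-_]+", "", x)
  }
  x <- gsub("[.\"']", "", x)          # quotes/periods never carry meaning here
  x <- gsub("\\s*/\\s*", "/", x)       # tighten around composite delimiters
  x <- gsub("\\s*,\\s*", ", ", x)
  x <- trimws(gsub("\\s+", " ", x))
  x <- mark(before, x, "punctuation")
  if (config$americanize && length(config$anglicism_table)) {
    tab <- config$anglicism_table
    if (config$casefold) names(tab) <- tolower(names(tab))
    before <- x
    words <- strsplit(x, " ", fixed = TRUE)[[1]]
    hit <- words %in% names(tab)
    words[hit] <- unname(tab[words[hit]])
    x <- mark(before, paste(words, collapse = " "), "americanize")
  }

  if (!nzchar(x)) stop_unusable(text)
  structure(list(original = text, normalized = x, steps = steps),
            class = "clean_term")
}

stop_unusable <- function(text) {
  stop(structure(
    class = c("anatomap_unusable", "error", "condition"),
    list(message = sprintf("unusable annotation: %s",
                           deparse(substr(text, 1, 60))),
         call = sys.call(-1))))
}

#' @export
print.clean_term <- function(x, ...) {
  cat(sprintf("<clean_term> %s -> %s [%s]\n",
              deparse(x$original), deparse(x$normalized),
              paste(x$steps, collapse = ";")))
  invisible(x)
}

#' Normalize a batch of annotations
#'
#' Vectorized preprocessing of raw annotations: per row, species stripping
#' (using the paired species column plus the lexicon) followed by
#' [normalize_text()]. Rows whose text is empty after cleaning are retained
#' with `usable = FALSE` rather than dropped silently.
#'
#' @param text Character vector of raw annotation strings.
#' @param species Optional character vector of paired species names.
#' @param config A [normalizer_config()].
#' @param lexicon Species lexicon for [strip_species()]; `NULL` disables
#'   species stripping entirely.
#' @return A tibble with columns `original`, `species`, `normalized`,
#'   `steps` (semicolon-joined tags), `usable`.
#' @export
normalize_terms <- function(text, species = NULL,
                            config = normalizer_config(),
                            lexicon = species_lexicon()) {
  stopifnot(is.character(text))
  n <- length(text)
  species <- if (is.null(species)) rep("", n) else rep_len(species, n)

  if (!is.null(lexicon)) {
    strippedtxt <- strip_species(text, species, lexicon)
    was_stripped <- attr(strippedtxt, "stripped")
  } else {
    strippedtxt <- text
    was_stripped <- logical(n)
  }

  normalized <- character(n)
  steps <- character(n)
  usable <- logical(n)
  for (i in seq_len(n)) {
    pre <- if (was_stripped[[i]]) "species_strip" else character()
    ct <- tryCatch(normalize_text(strippedtxt[[i]], config),
                   anatomap_unusable = function(e) NULL,
                   error = function(e) {
                     if (!nzchar(trimws(strippedtxt[[i]]))) NULL else stop(e)
                   })
    if (is.null(ct)) {
      normalized[[i]] <- NA_character_
      steps[[i]] <- paste(c(pre, "unusable"), collapse = ";")
      usable[[i]] <- FALSE
    } else {
      normalized[[i]] <- ct$normalized
      steps[[i]] <- paste(c(pre, ct$steps), collapse = ";")
      usable[[i]] <- TRUE
    }
  }
  tibble::tibble(original = text, species = species,
                 normalized = normalized, steps = steps, usable = usable)
}

#' Collapse duplicate normalized terms
#'
#' Terms that were distinct only because they carried different species
#' names collapse to a single query after normalization; this keeps the
#' first occurrence of every normalized string (input order preserved) and
#' records the collapsed groups for logging.
#'
#' @param terms A tibble as returned by [normalize_terms()] (must have a
#'   `normalized` column).
#' @return The deduplicated tibble, with attribute `"collapsed"`: a tibble
#'   of `normalized`, `n` (group size) for every group of size >= 2.
#' @export
deduplicate <- function(terms) {
  stopifnot(is.data.frame(terms), "normalized" %in% names(terms))
  key <- terms$normalized
  keep <- !duplicated(key) | is.na(key)
  tab <- table(key[!is.na(key)])
  collapsed <- tibble::tibble(normalized = names(tab), n = as.integer(tab))
  collapsed <- collapsed[collapsed$n >= 2L, , drop = FALSE]
  out <- terms[keep, , drop = FALSE]
  attr(out, "collapsed") <- collapsed
  out
}

#' Conservative misspelling repair
#'
#' Replaces `text` by a vocabulary entry at Levenshtein distance exactly 1
#' when that entry is unique; ambiguous or distant inputs are returned
#' unchanged. Exact vocabulary members are returned unchanged. This stage
#' is off by default throughout the package: automated respelling is a
#' known false-positive amplifier, so it must be opted into.
#'
#' @param text Character vector of normalized terms.
#' @param vocabulary Character vector of known-good strings (typically the
#'   index keys).
#' @return Character vector: repaired where a unique distance-1 neighbour
#'   exists, otherwise the input.
#' @examples
#' spellfix("livr", c("liver", "kidney"))
#' @export
spellfix <- function(text, vocabulary) {
  stopifnot(is.character(text), is.character(vocabulary))
  if (length(vocabulary) == 0L) return(text)
  vapply(text, function(x) {
    if (x %in% vocabulary) return(x)
    d <- utils::adist(x, vocabulary)
    hits <- vocabulary[d == 1L]
    if (length(hits) == 1L) hits else x
  }, character(1L), USE.NAMES = FALSE)
}
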