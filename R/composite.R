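# Composite annotations: one free-text string packing several anatomical
# entities ("liver/kidney", "bone marrow, flushed from femur"). They are
# decomposed into components which are then matched independently as a
# cross-product.

#' Default process stop-phrase table
#'
#' Procedure words that imply an anatomical location without naming a
#' separate entity ("colon pinch biopsy" samples the colon); they are
#' stripped before decomposition and matching.
#'
#' @return Character vector of stop phrases.
#' @export
default_stop_phrases <- function() {
  c("pinch biopsy", "lavage", "biopsy")
}

#' Default composite separators and locative connectors
#'
#' @return List with `delimiters`, `conjunctions`, `locatives`. Plain "of"
#'   is deliberately absent: "left ventricle of heart" is one entity.
#' @export
default_composite_config <- function() {
  list(delimiters   = c("/", ",", ";", "+"),
       conjunctions = c(" and ", " & "),
       locatives    = c("flushed from", "derived from", "isolated from",
                        "from"))
}

#' Strip procedure stop-phrases from a term
#'
#' @param text A normalized term (length-1 character).
#' @param stop_phrases Phrases to delete; defaults to
#'   [default_stop_phrases()] (longest matched first).
#' @return The term with stop phrases removed and whitespace collapsed.
#' @examples
#' strip_process_phrases("colon pinch biopsy")
#' @export
strip_process_phrases <- function(text, stop_phrases = default_stop_phrases()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (length(stop_phrases) == 0L) return(text)
  x <- text
  for (p in stop_phrases[order(-nchar(stop_phrases))]) {
    re <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), "\\b")
    x <- gsub(re, " ", x)
  }
  trimws(gsub("\\s+", " ", x))
}

#' Decompose a composite annotation
#'
#' Splits a normalized annotation into component entity strings on
#' punctuation delimiters, conjunctions, and locative connector phrases
#' ("flushed from" marks the boundary between sample and source).
#' Parenthetical asides are consumed. A string in which nothing fires is
#' returned whole with `kind = "none"`.
#'
#' @param text A normalized term (length-1 character).
#' @param config Separator tables; defaults to
#'   [default_composite_config()].
#' @return A `decomposition`: list with `original`, `components` (ordered,
#'   trimmed, non-empty), `separators_used`, and `kind` in
#'   delimiter/conjunction/locative/none (locative wins over delimiter
#'   wins over conjunction when several fire).
#' @examples
#' split_composite("liver/kidney")
#' split_composite("bone marrow, flushed from femur")
#' @export
split_composite <- function(text, config = default_composite_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  used <- character()

  x <- text
  if (grepl("\\(", x)) {
    x2 <- trimws(gsub("\\s+", " ", gsub("\\([^)]*\\)", " ", x)))
    if (nzchar(x2) && !identical(x2, x)) {
      used <- c(used, "()")
      x <- x2
    }
  }

  pieces <- x
  kinds_hit <- character()
  split_on <- function(pieces, pattern, token, kind) {
    out <- unlist(lapply(pieces, function(p) {
      parts <- strsplit(p, pattern, perl = TRUE)[[1]]
      if (length(parts) > 1L) {
        used <<- c(used, token)
        kinds_hit <<- c(kinds_hit, kind)
      }
      parts
    }))
    out[nzchar(trimws(out))]
  }

  for (d in config$delimiters) {
    pat <- paste0("\\s*", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", d), "\\s*")
    pieces <- split_on(pieces, pat, d, "delimiter")
  }
  for (cj in config$conjunctions) {
    pat <- paste0("\\s*", gsub("([][{}()+*^$|\\\\?.&])", "\\\\\\1",
                               trimws(cj)), "\\s+")
    pieces <- split_on(pieces, paste0("\\s+", pat), trimws(cj), "conjunction")
  }
  for (lc in config$locatives[order(-nchar(config$locatives))]) {
    pat <- paste0("(\\s+|^)", gsub(" ", "\\\\s+", lc), "(\\s+|$)")
    pieces <- split_on(pieces, pat, lc, "locative")
  }

  components <- trimws(pieces)
  components <- components[nzchar(components)]
  if (length(components) <= 1L && length(kinds_hit) == 0L) {
    return(structure(list(original = text, components = text,
                          separators_used = character(), kind = "none"),
                     class = "decomposition"))
  }
  kind <- if ("locative" %in% kinds_hit) "locative"
          else if ("delimiter" %in% kinds_hit) "delimiter"
          else if ("conjunction" %in% kinds_hit) "conjunction"
          else "delimiter"
  structure(list(original = text, components = components,
                 separators_used = used, kind = kind),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition:%s> %s => [%s]\n", x$kind,
              deparse(x$original),
              paste(deparse(x$components), collapse = ", ")))
  invisible(x)
}

#' Match decomposition components as a cross-product
#'
#' Exact-matches every component of a decomposition independently. Under
#' `policy = "any"` each component hit yields candidates; under
#' `policy = "all"` candidates are emitted only when every component has
#' at least one hit. When one component's token set contains another's
#' (e.g. "adrenal cortex" next to "adrenal gland" sharing "adrenal"), a
#' redundancy flag is attached: the composite may name two entities or
#' one entity modified redundantly, and only a curator can decide.
#'
#' @param decomp A `decomposition` with `kind != "none"`.
#' @param index A `term_index`.
#' @param policy `"any"` (default) or `"all"`.
#' @return Candidate tibble (`query` = the original composite,
#'   `match_kind = "composite"`, `evidence` = the component that hit, plus
#'   the matched index string); attributes `redundant` (logical) and
#'   `matched_components` (character).
#' @export
cross_product_match <- function(decomp, index, policy = c("any", "all")) {
  stopifnot(inherits(decomp, "decomposition"), inherits(index, "term_index"))
  policy <- match.arg(policy)
  if (decomp$kind == "none") {
    stop("cross_product_match requires a real decomposition (kind != 'none')")
  }
  comp_hits <- lapply(decomp$components, exact_match, index = index)
  hit_mask <- vapply(comp_hits, nrow, integer(1L)) > 0L
  redundant <- components_redundant(decomp$components)

  emit <- if (policy == "all") all(hit_mask) else any(hit_mask)
  if (!emit) {
    out <- empty_candidates()
  } else {
    rows <- lapply(which(hit_mask), function(i) {
      h <- comp_hits[[i]]
      tibble::tibble(query = decomp$original, class_id = h$class_id,
                     match_kind = "composite",
                     evidence = sprintf("component '%s' = %s",
                                        decomp$components[[i]], h$evidence),
                     rank = NA_integer_)
    })
    out <- unique(do.call(rbind, rows))
    out$rank <- seq_len(nrow(out))
  }
  attr(out, "redundant") <- redundant
  attr(out, "matched_components") <- decomp$components[hit_mask]
  out
}

# token-subset relation between any component pair
components_redundant <- function(components) {
  toks <- lapply(components, function(x) strsplit(x, " ", fixed = TRUE)[[1]])
  n <- length(toks)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (length(intersect(toks[[i]], toks[[j]])) > 0L) return(TRUE)
    }
  }
  FALSE
}
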