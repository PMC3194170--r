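# Matchers: exact lexical lookup, phonetic (Double Metaphone) proposal
# generation, and the morphological variant stages (plural, adjectival,
# shorthand) implemented as query rewrites that re-enter the exact
# matcher, so every variant hit is auditable as an exact match on a
# rewritten string.

MATCH_KIND_ORDER <- c("exact_label", "exact_synonym", "plural_variant",
                      "adjectival", "shorthand", "spellfix", "composite",
                      "phonetic", "levenshtein")

#' Default adjective-to-noun table
#'
#' Whole-word substitutions turning anatomical adjectives into the noun
#' the ontologies actually name ("abdominal" -> "abdomen", "arterial" ->
#' "artery"). Annotators routinely write the adjective; ontology classes
#' are nouns.
#'
#' @return Named character vector (adjective -> noun).
#' @export
default_adjective_table <- function() {
  c(abdominal  = "abdomen",   arterial  = "artery",
    venous     = "vein",      renal     = "kidney",
    hepatic    = "liver",     cardiac   = "heart",
    pulmonary  = "lung",      gastric   = "stomach",
    splenic    = "spleen",    cerebral  = "cerebrum",
    cerebellar = "cerebellum", cortical = "cortex",
    vertebral  = "vertebra",  femoral   = "femur",
    tibial     = "tibia",     cranial   = "cranium",
    ocular     = "eye",       nasal     = "nose",
    dermal     = "skin",      muscular  = "muscle",
    glandular  = "gland",     ovarian   = "ovary",
    testicular = "testis",    uterine   = "uterus",
    intestinal = "intestine", colonic   = "colon",
    esophageal = "esophagus", tracheal  = "trachea",
    bronchial  = "bronchus",  pancreatic = "pancreas",
    thymic     = "thymus",    vesical   = "bladder",
    retinal    = "retina",    corneal   = "cornea",
    neural     = "nerve",     ureteric  = "ureter",
    thalamic   = "thalamus",  atrial    = "atrium",
    ventricular = "ventricle", ligamentous = "ligament")
}

#' Default shorthand expansion table
#'
#' Maps curator shorthand to the full class name(s) intended; one
#' shorthand may legitimately expand to several classes ("both
#' ventricles").
#'
#' @return Named list of character vectors (shorthand -> expansions).
#' @export
default_shorthand_table <- function() {
  list("antrum" = "pyloric antrum",
       "both ventricles" = c("left ventricle of heart",
                             "right ventricle of heart"),
       "both atria" = c("left atrium of heart", "right atrium of heart"))
}

# words ending in s that are singular; never singularized
PLURAL_EXCEPTIONS <- c("pancreas", "atlas", "meatus", "plexus", "sinus",
                       "ramus", "anus", "uterus", "esophagus", "corpus",
                       "pelvis", "testis", "epididymis", "penis", "iris",
                       "pubis", "fundus", "annulus", "nucleus", "humerus",
                       "radius", "biceps", "triceps", "glottis",
                       "epiglottis", "bronchus", "thymus", "thalamus",
                       "hippocampus", "villus", "alveolus", "glomerulus")

#' Candidate singular forms of a term
#'
#' Applies simple English singularization rules to the head (last) word:
#' `-ies -> -y`, `-es` stripped when the stem ends in a sibilant, plain
#' `-s` stripped otherwise; words on the exception list (singular Latin
#' forms ending in -s such as "pancreas") produce no variants.
#'
#' @param text A normalized term (length-1 character).
#' @param exceptions Words never singularized.
#' @return Character vector of candidate singular forms (possibly empty),
#'   never containing `text` itself.
#' @examples
#' plural_variants("kidneys")
#' plural_variants("arteries")
#' plural_variants("pancreas")
#' @export
plural_variants <- function(text, exceptions = PLURAL_EXCEPTIONS) {
  stopifnot(is.character(text), length(text) == 1L)
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  if (length(words) == 0L) return(character())
  w <- words[[length(words)]]
  if (w %in% exceptions || nchar(w) < 3L) return(character())
  out <- if (grepl("ies$", w) && nchar(w) > 4L) {
    sub("ies$", "y", w)
  } else if (grepl("(s|x|z|ch|sh)es$", w)) {
    sub("es$", "", w)
  } else if (grepl("s$", w) && !grepl("(ss|us|is)$", w)) {
    sub("s$", "", w)
  } else {
    character()
  }
  out <- setdiff(unique(out), w)
  if (length(out) == 0L) return(character())
  vapply(out, function(v) {
    paste(c(words[-length(words)], v), collapse = " ")
  }, character(1L), USE.NAMES = FALSE)
}

# inverse operation used by the synthetic generator
pluralize_word <- function(w, exceptions = PLURAL_EXCEPTIONS) {
  if (w %in% exceptions) return(NA_character_)
  if (grepl("[^aeiou]y$", w)) return(sub("y$", "ies", w))
  if (grepl("(s|x|z|ch|sh)$", w)) return(paste0(w, "es"))
  if (grepl("s$", w)) return(NA_character_)
  paste0(w, "s")
}

#' Rewrite anatomical adjectives to their nouns
#'
#' Single-pass whole-word substitution from an adjective-to-noun table.
#'
#' @param text A normalized term (length-1 character).
#' @param table Named character vector (adjective -> noun); defaults to
#'   [default_adjective_table()].
#' @return The rewritten string, or `text` unchanged when no word is in
#'   the table.
#' @examples
#' adjectival_to_noun("abdominal")
#' adjectival_to_noun("arterial")
#' @export
adjectival_to_noun <- function(text, table = default_adjective_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (length(table) == 0L) return(text)
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  hit <- words %in% names(table)
  if (!any(hit)) return(text)
  words[hit] <- unname(table[words[hit]])
  paste(words, collapse = " ")
}

#' Expand curator shorthand
#'
#' Whole-string lookup in a shorthand table; unknown input is returned as
#' itself (a length-1 expansion).
#'
#' @param text A normalized term (length-1 character).
#' @param table Named list of character vectors; defaults to
#'   [default_shorthand_table()].
#' @return Character vector of expansions (length >= 1).
#' @examples
#' expand_shorthand("both ventricles")
#' expand_shorthand("liver")
#' @export
expand_shorthand <- function(text, table = default_shorthand_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (text %in% names(table)) as.character(table[[text]]) else text
}

# lightweight candidate-tibble constructors for the hot matching path
CANDIDATE_COLS <- c("query", "class_id", "match_kind", "evidence", "rank")

new_candidates <- function(query, class_id, match_kind, evidence,
                           rank = NA_integer_) {
  n <- length(class_id)
  tibble::new_tibble(list(query = rep_len(query, n),
                          class_id = class_id,
                          match_kind = rep_len(match_kind, n),
                          evidence = rep_len(evidence, n),
                          rank = rep_len(as.integer(rank), n)),
                     nrow = n)
}

EMPTY_CANDIDATES <- new_candidates(character(), character(), character(),
                                   character(), integer())

as_query_string <- function(term) {
  if (inherits(term, "clean_term")) term$normalized else {
    stopifnot(is.character(term), length(term) == 1L)
    term
  }
}

#' Exact lexical match
#'
#' Returns a candidate for every class whose indexed (normalized) label
#' or synonym equals the query string. Label hits rank above synonym
#' hits; ties break by class id.
#'
#' @param term A `clean_term` or an already-normalized string.
#' @param index A `term_index` from [build_index()].
#' @return Candidate tibble: `query`, `class_id`, `match_kind`
#'   (`exact_label`/`exact_synonym`), `evidence` (the indexed string),
#'   `rank`.
#' @export
exact_match <- function(term, index) {
  stopifnot(inherits(index, "term_index"))
  q <- as_query_string(term)
  rows <- if (!is.null(index$lookup)) index$lookup[[q]] else
    which(index$lexical$key == q)
  hits <- index$lexical[rows, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(empty_candidates(q))
  }
  kind <- ifelse(hits$origin == "label", "exact_label", "exact_synonym")
  out <- new_candidates(q, hits$id, kind, hits$key)
  out$match_kind <- kind
  out <- unique(out)
  out <- out[order(match(out$match_kind, MATCH_KIND_ORDER), out$class_id), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

empty_candidates <- function(q = character()) {
  EMPTY_CANDIDATES
}

#' Phonetic match proposals
#'
#' Finds every indexed string sharing a Double Metaphone code with the
#' query: primary-code agreement forms the first tier, any agreement
#' involving an alternate code the second. Proposals are ranked by
#' (code tier, word-count difference, indexed string, class id) so output
#' order is deterministic. A string lexically equal to the query is
#' suppressed: the exact matcher already reports it.
#'
#' @param term A `clean_term` or an already-normalized string.
#' @param index A `term_index`.
#' @return Candidate tibble as in [exact_match()] with
#'   `match_kind = "phonetic"`; `evidence` holds `indexed string [code]`.
#' @export
phonetic_match <- function(term, index) {
  stopifnot(inherits(index, "term_index"))
  q <- as_query_string(term)
  qc <- phonetic_encode(q)
  if (!nzchar(qc$primary)) return(empty_candidates())
  ph <- index$phonetic
  tier1 <- ph$key[ph$primary == qc$primary]
  tier2 <- ph$key[ph$primary == qc$alternate |
                  ph$alternate == qc$primary |
                  ph$alternate == qc$alternate]
  tier2 <- setdiff(tier2, tier1)
  keys <- c(tier1, tier2)
  tiers <- c(rep(1L, length(tier1)), rep(2L, length(tier2)))
  keep <- keys != q
  keys <- keys[keep]; tiers <- tiers[keep]
  if (length(keys) == 0L) return(empty_candidates())

  ntok <- function(x) lengths(strsplit(x, " ", fixed = TRUE))
  qd <- abs(ntok(keys) - ntok(q))
  ord <- order(tiers, qd, keys)
  keys <- keys[ord]; tiers <- tiers[ord]

  rows <- lapply(seq_along(keys), function(i) {
    hits <- index$lexical[index$lexical$key == keys[[i]], , drop = FALSE]
    code <- ph[ph$key == keys[[i]], , drop = FALSE]
    new_candidates(q, sort(unique(hits$id)), "phonetic",
                   sprintf("%s [%s]", keys[[i]],
                           if (tiers[[i]] == 1L) code$primary[[1]]
                           else code$alternate[[1]]))
  })
  out <- do.call(rbind, rows)
  out$rank <- seq_len(nrow(out))
  out
}

#' Matcher configuration
#'
#' Controls the matching cascade: the base mode (exact only, or exact
#' plus phonetic proposals) and the optional variant stages. All variant
#' stages are off by default; each models one documented class of
#' annotation/ontology mismatch and can be toggled to quantify its
#' contribution.
#'
#' @param mode `"exact"` (exact matching only; the conservative
#'   zero-false-positive regime) or `"phonetic"` (additionally emit
#'   sound-alike proposals for curation).
#' @param plural,adjectival,shorthand,composite,spellfix,levenshtein
#'   Stage toggles (logical, all default `FALSE`).
#' @param adjective_table,shorthand_table,stop_phrases Tables used by the
#'   corresponding stages.
#' @param composite_policy `"any"` (each component hit is a candidate) or
#'   `"all"` (candidates only when every component hits).
#' @param levenshtein_max Maximum edit distance for the optional fuzzy
#'   stage (default 1).
#' @return An object of class `match_config`.
#' @export
match_config <- function(mode = c("exact", "phonetic"),
                         plural = FALSE, adjectival = FALSE,
                         shorthand = FALSE, composite = FALSE,
                         spellfix = FALSE, levenshtein = FALSE,
                         adjective_table = default_adjective_table(),
                         shorthand_table = default_shorthand_table(),
                         stop_phrases = default_stop_phrases(),
                         composite_policy = c("any", "all"),
                         levenshtein_max = 1L) {
  structure(list(mode = match.arg(mode),
                 plural = plural, adjectival = adjectival,
                 shorthand = shorthand, composite = composite,
                 spellfix = spellfix, levenshtein = levenshtein,
                 adjective_table = adjective_table,
                 shorthand_table = shorthand_table,
                 stop_phrases = stop_phrases,
                 composite_policy = match.arg(composite_policy),
                 levenshtein_max = levenshtein_max),
            class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  stages <- c("plural", "adjectival", "shorthand", "composite",
              "spellfix", "levenshtein")
  on <- stages[vapply(stages, function(s) isTRUE(x[[s]]), logical(1L))]
  cat(sprintf("<match_config> mode=%s stages=[%s]\n", x$mode,
              paste(on, collapse = ",")))
  invisible(x)
}

# one rewritten query re-entering the exact matcher
rewrite_hits <- function(q, rewritten, index, kind) {
  rewritten <- setdiff(unique(rewritten), q)
  if (length(rewritten) == 0L) return(empty_candidates())
  rows <- lapply(rewritten, function(r) {
    hits <- exact_match(r, index)
    if (nrow(hits) == 0L) return(NULL)
    new_candidates(q, hits$class_id, kind,
                   sprintf("%s -> %s", r, hits$evidence))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) empty_candidates() else unique(out)
}

match_one <- function(q, index, config, keys) {
  accepted_kinds <- character()
  cands <- exact_match(q, index)

  if (nrow(cands) == 0L) {
    if (config$plural) {
      cands <- rbind(cands,
                     rewrite_hits(q, plural_variants(q), index,
                                  "plural_variant"))
    }
    if (config$adjectival) {
      cands <- rbind(cands,
                     rewrite_hits(q, adjectival_to_noun(q, config$adjective_table),
                                  index, "adjectival"))
    }
    if (config$shorthand) {
      cands <- rbind(cands,
                     rewrite_hits(q, expand_shorthand(q, config$shorthand_table),
                                  index, "shorthand"))
    }
    if (config$spellfix) {
      cands <- rbind(cands,
                     rewrite_hits(q, spellfix(q, keys), index, "spellfix"))
    }
  }

  if (config$composite && nrow(cands) == 0L) {
    stripped <- strip_process_phrases(q, config$stop_phrases)
    dec <- split_composite(stripped)
    if (dec$kind == "none") {
      if (!identical(stripped, q)) {
        cands <- rbind(cands, rewrite_hits(q, stripped, index, "composite"))
      }
    } else {
      cc <- cross_product_match(dec, index, config$composite_policy)
      if (nrow(cc)) {
        cc$query <- q
        attributes(cc)[c("redundant", "components")] <- NULL
        cands <- rbind(cands, cc[, names(empty_candidates()), drop = FALSE])
      }
    }
  }

  proposals <- empty_candidates()
  if (config$mode == "phonetic") {
    proposals <- phonetic_match(q, index)
    proposals <- proposals[!proposals$class_id %in% cands$class_id, ,
                           drop = FALSE]
  }
  if (config$levenshtein && nrow(cands) == 0L) {
    d <- utils::adist(q, keys)
    near <- keys[d > 0 & d <= config$levenshtein_max]
    lev <- rewrite_hits(q, near, index, "levenshtein")
    lev <- lev[!lev$class_id %in% c(cands$class_id, proposals$class_id), ,
               drop = FALSE]
    proposals <- rbind(proposals, lev)
  }

  all <- rbind(cands, proposals)
  if (nrow(all)) {
    all <- all[order(match(all$match_kind, MATCH_KIND_ORDER),
                     ifelse(is.na(all$rank), 0L, all$rank), all$class_id), ,
               drop = FALSE]
    all$rank <- seq_len(nrow(all))
    all$accepted <- all$match_kind %in%
      setdiff(MATCH_KIND_ORDER, c("phonetic", "levenshtein"))
  } else {
    all$accepted <- logical()
  }
  all
}

#' Run the matching cascade over a term list
#'
#' For every usable term: exact match; if none, the enabled rewrite
#' stages (plural, adjectival, shorthand, spellfix) retried exactly; if
#' still none and composites are enabled, decomposition with component
#' cross-product matching; finally (in phonetic mode) sound-alike
#' proposals. Exact-tier hits (including variant and composite hits,
#' which are exact matches on rewritten strings or components) are
#' accepted; phonetic and fuzzy candidates are proposals and enter the
#' accepted set only through an explicit curation table.
#'
#' @param terms Tibble from [normalize_terms()] (columns `normalized`,
#'   `usable`), or a character vector of normalized strings.
#' @param index A `term_index`; must share the terms' normalizer
#'   configuration.
#' @param config A [match_config()].
#' @param curations Optional tibble (`term`, `class_id`) of curator
#'   decisions accepting proposed candidates; a curation naming a term
#'   absent from the run is an error.
#' @return A `mapping_result`: list with `outcomes` (tibble `query`,
#'   `status` in matched/proposed_only/unmatched, `accepted`
#'   semicolon-joined ids, `n_accepted`, `n_proposed`, `reason`) and
#'   `candidates` (all candidates, with `accepted` flag).
#' @export
run_matcher <- function(terms, index, config = match_config(),
                        curations = NULL) {
  stopifnot(inherits(index, "term_index"), inherits(config, "match_config"))
  if (is.character(terms)) {
    terms <- tibble::tibble(normalized = terms,
                            usable = !is.na(terms) & nzchar(terms))
  }
  stopifnot(is.data.frame(terms), "normalized" %in% names(terms))
  if (!"usable" %in% names(terms)) terms$usable <- !is.na(terms$normalized)

  queries <- terms$normalized[terms$usable]
  if (!is.null(curations)) {
    stopifnot(all(c("term", "class_id") %in% names(curations)))
    unknown <- setdiff(unique(curations$term), queries)
    if (length(unknown)) {
      stop("curation file references unknown terms: ",
           paste(unknown, collapse = ", "))
    }
  }

  keys <- index_keys(index)
  cand_list <- vector("list", length(queries))
  status <- character(length(queries))
  accepted <- character(length(queries))
  n_acc <- integer(length(queries))
  n_prop <- integer(length(queries))
  reason <- character(length(queries))

  for (i in seq_along(queries)) {
    q <- queries[[i]]
    cands <- match_one(q, index, config, keys)
    if (!is.null(curations)) {
      cur <- curations[curations$term == q, , drop = FALSE]
      if (nrow(cur)) {
        cands$accepted <- cands$accepted |
          cands$class_id %in% cur$class_id
      }
    }
    cand_list[[i]] <- cands
    acc <- unique(cands$class_id[cands$accepted])
    prop <- unique(cands$class_id[!cands$accepted])
    n_acc[[i]] <- length(acc)
    n_prop[[i]] <- length(prop)
    accepted[[i]] <- paste(sort(acc), collapse = ";")
    status[[i]] <- if (length(acc)) "matched"
                   else if (nrow(cands)) "proposed_only"
                   else "unmatched"
    reason[[i]] <- if (length(acc)) ""
                   else if (is_uninterpretable(q)) "uninterpretable"
                   else if (nrow(cands)) "proposals_only"
                   else "no_match"
  }

  outcomes <- tibble::tibble(query = queries, status = status,
                             accepted = accepted, n_accepted = n_acc,
                             n_proposed = n_prop, reason = reason)
  candidates <- do.call(rbind, cand_list)
  if (is.null(candidates)) {
    candidates <- empty_candidates()
    candidates$accepted <- logical()
  }
  structure(list(outcomes = outcomes, candidates = candidates,
                 config = config),
            class = "mapping_result")
}

# annotations no curator could interpret out of context: bare counts and
# enumerations ("11 different tissues"); routed to unmatched, no heuristics
is_uninterpretable <- function(q) {
  grepl("^[0-9]+\\b", q) || grepl("^[0-9]+%", q)
}

#' @export
print.mapping_result <- function(x, ...) {
  tab <- table(factor(x$outcomes$status,
                      levels = c("matched", "proposed_only", "unmatched")))
  cat(sprintf(
    "<mapping_result> %d terms: %d matched, %d proposed_only, %d unmatched\n",
    nrow(x$outcomes), tab[["matched"]], tab[["proposed_only"]],
    tab[["unmatched"]]))
  invisible(x)
}
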