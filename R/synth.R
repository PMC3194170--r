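# Synthetic benchmark generation: toy ontologies with an anatomy-like
# label grammar, plus annotation corpora corrupted according to the
# documented taxonomy of annotation/ontology mismatches (plurals,
# adjectives, British spellings, species suffixes, composites, shorthand,
# process phrases, misspellings, uninterpretable noise), each with a
# known gold mapping. Labels are generated from a template grammar, not
# scraped from any real ontology.

SYNTH_MODIFIERS <- c(
  "anterior", "posterior", "medial", "lateral", "dorsal", "ventral",
  "proximal", "distal", "superior", "inferior", "left", "right",
  "deep", "superficial", "internal", "external", "transverse",
  "accessory", "fetal", "celiac", "hemal", "primary")

SYNTH_ORGANS <- c(
  "abdomen", "artery", "kidney", "liver", "heart", "lung", "stomach",
  "spleen", "femur", "tibia", "cortex", "colon", "esophagus", "cecum",
  "gland", "duct", "vein", "nerve", "muscle", "node", "membrane",
  "tubule", "valve", "fossa", "septum", "ganglion", "follicle",
  "ligament", "ventricle", "atrium", "cornea", "retina", "ureter",
  "trachea", "bronchus", "pancreas", "thymus", "ovary", "testis",
  "uterus", "bladder", "cerebellum", "thalamus", "marrow", "larynx",
  "pharynx", "tongue", "tonsil", "palate", "clavicle", "scapula",
  "sternum", "ulna", "patella", "fibula", "ilium", "sacrum", "tendon",
  "cartilage", "diaphragm", "pleura", "peritoneum", "mesentery",
  "omentum", "aorta", "arteriole", "venule", "jejunum", "ileum",
  "duodenum", "rectum", "appendix", "gallbladder", "cochlea", "sclera",
  "prostate", "scrotum", "dermis", "epithelium", "endothelium",
  "myocardium", "pericardium")

CORRUPTION_CLASSES <- c(
  "identity", "synonym_use", "plural", "adjectival", "anglicism",
  "species_suffix", "whitespace_punct", "misspelling_ed1",
  "composite_delimiter", "composite_locative", "shorthand",
  "process_phrase", "uninterpretable")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Species mixture of a typical multi-species annotation corpus
#'
#' Proportions dominated by human, mouse and rat, with a long tail of
#' other vertebrates -- the composition typical of functional-genomics
#' annotation sets.
#'
#' @return Tibble with `species` (binomial) and `proportion` (sums to 1).
#' @export
default_species_mixture <- function() {
  tibble::tibble(
    species = c("Homo sapiens", "Mus musculus", "Rattus norvegicus",
                "Bos taurus", "Pan troglodytes", "Gallus gallus",
                "Danio rerio", "Xenopus laevis", "Macaca mulatta",
                "Sus scrofa", "Ovis aries"),
    proportion = c(0.5088, 0.2791, 0.1061, 0.0169, 0.0163, 0.0150,
                   0.0117, 0.0104, 0.0085, 0.0078, 0.0194))
}

#' Default corruption-class proportions
#'
#' Composites are the most frequent mismatch class; the remaining mass is
#' spread over the other documented classes. No published per-class
#' frequency exists, so these defaults are this package's own choice.
#'
#' @return Named numeric vector over the corruption classes, summing to 1.
#' @export
default_corruption_proportions <- function() {
  c(identity = 0.14, synonym_use = 0.08, plural = 0.10,
    adjectival = 0.08, anglicism = 0.06, species_suffix = 0.08,
    whitespace_punct = 0.10, misspelling_ed1 = 0.05,
    composite_delimiter = 0.12, composite_locative = 0.05,
    shorthand = 0.06, process_phrase = 0.04, uninterpretable = 0.04)
}

#' Corruption specification for a synthetic corpus
#'
#' @param n_terms Number of distinct annotation terms to generate (> 0).
#' @param proportions Named numeric vector over the corruption classes
#'   (see [default_corruption_proportions()]); must sum to 1.
#' @param duplicate_fraction Fraction of `n_terms` added again as
#'   cross-species duplicate rows (same term, different species), to
#'   exercise deduplication; `0.4` on 1000 terms yields a 1400-row raw
#'   corpus collapsing back to 1000.
#' @param seed Integer seed; regeneration with the same spec and seed is
#'   bit-identical.
#' @param species_mixture Tibble `species`/`proportion`; defaults to
#'   [default_species_mixture()].
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(n_terms = 200,
                            proportions = default_corruption_proportions(),
                            duplicate_fraction = 0,
                            seed = 1L,
                            species_mixture = default_species_mixture()) {
  stopifnot(n_terms > 0, duplicate_fraction >= 0)
  if (!all(names(proportions) %in% CORRUPTION_CLASSES)) {
    stop("unknown corruption class: ",
         paste(setdiff(names(proportions), CORRUPTION_CLASSES),
               collapse = ", "))
  }
  full <- stats::setNames(numeric(length(CORRUPTION_CLASSES)),
                          CORRUPTION_CLASSES)
  full[names(proportions)] <- proportions
  if (abs(sum(full) - 1) > 1e-9) {
    stop("corruption proportions must sum to 1 (got ", sum(full), ")")
  }
  structure(list(n_terms = as.integer(n_terms), proportions = full,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed),
                 species_mixture = species_mixture),
            class = "corruption_spec")
}

# integer class counts summing exactly to n (largest remainder)
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a toy anatomy-like ontology
#'
#' Labels are modifier + organ-noun phrases drawn from a template
#' grammar; a fixed fraction of classes carry one EXACT synonym, and a
#' requested number of label collisions (distinct ids sharing one label)
#' is injected for duplicate-detection exercises.
#'
#' @param n_classes Number of classes (>= 1).
#' @param synonym_rate Fraction of classes carrying one EXACT synonym;
#'   exactly `round(synonym_rate * n_classes)` classes get one.
#' @param duplicate_label_count Number of classes whose label duplicates
#'   another class's label (must be < `n_classes`).
#' @param seed Integer seed; generation is deterministic given the
#'   arguments.
#' @return An `ontology` object.
#' @export
generate_ontology <- function(n_classes, synonym_rate = 0.3,
                              duplicate_label_count = 0L, seed = 1L) {
  stopifnot(n_classes >= 1, synonym_rate >= 0, synonym_rate <= 1)
  if (duplicate_label_count >= n_classes) {
    stop("duplicate_label_count must be smaller than n_classes")
  }
  with_seed(seed, {
    grid2 <- as.vector(outer(SYNTH_MODIFIERS, SYNTH_ORGANS, paste))
    pool <- sample(grid2)
    if (n_classes - duplicate_label_count > length(pool)) {
      grid3 <- as.vector(outer(
        paste(SYNTH_MODIFIERS[1:8], SYNTH_MODIFIERS[9:16]),
        SYNTH_ORGANS, paste))
      pool <- c(pool, sample(grid3))
    }
    n_fresh <- n_classes - duplicate_label_count
    if (n_fresh > length(pool)) {
      stop("label grammar cannot produce ", n_fresh, " distinct labels")
    }
    labels <- pool[seq_len(n_fresh)]
    if (duplicate_label_count > 0L) {
      labels <- c(labels,
                  sample(labels, duplicate_label_count, replace = FALSE))
    }
    ids <- sprintf("TOY:%04d", seq_len(n_classes))
    classes <- tibble::tibble(id = ids, label = labels, obsolete = FALSE)

    k <- round(synonym_rate * n_classes)
    syn <- if (k > 0L) {
      pick <- sort(sample(n_classes, k))
      tibble::tibble(id = ids[pick],
                     text = paste(labels[pick], "region"),
                     scope = "EXACT")
    } else NULL
    as_ontology(classes, syn)
  })
}

# one random single-character edit on a letter position
edit1 <- function(x) {
  pos <- which(strsplit(x, "")[[1]] %in% letters)
  if (length(pos) < 4L) return(NA_character_)
  i <- sample(pos, 1L)
  op <- sample(c("del", "sub", "ins"), 1L)
  if (op == "del") {
    paste0(substr(x, 1, i - 1L), substr(x, i + 1L, nchar(x)))
  } else if (op == "sub") {
    l <- sample(setdiff(letters, substr(x, i, i)), 1L)
    paste0(substr(x, 1, i - 1L), l, substr(x, i + 1L, nchar(x)))
  } else {
    paste0(substr(x, 1, i), sample(letters, 1L), substr(x, i, nchar(x)))
  }
}

mangle_whitespace <- function(x) {
  words <- strsplit(x, " ", fixed = TRUE)[[1]]
  op <- sample(c("dspace", "title", "caps", "hyphen", "pad"), 1L)
  switch(op,
    dspace = paste(words, collapse = "  "),
    title = paste(vapply(words, function(w) {
      paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }, character(1L)), collapse = " "),
    caps = toupper(x),
    hyphen = if (length(words) >= 2L) {
      paste(c(paste(words[1:2], collapse = "-"),
              words[-(1:2)]), collapse = " ")
    } else paste0(x, " "),
    pad = paste0(" ", x, "  "))
}

britishize <- function(label, anglicisms) {
  inv <- stats::setNames(names(anglicisms), anglicisms)
  words <- strsplit(label, " ", fixed = TRUE)[[1]]
  hit <- words %in% names(inv)
  if (!any(hit)) return(NA_character_)
  words[hit] <- unname(inv[words[hit]])
  paste(words, collapse = " ")
}

#' Corrupt a toy ontology into a synthetic annotation corpus
#'
#' Draws `spec$n_terms` annotations by sampling ontology classes and
#' applying each annotation's assigned corruption rule, then appends
#' cross-species duplicate rows per `spec$duplicate_fraction`. Gold
#' mappings point at the source class(es); uninterpretable noise gets an
#' empty gold set. The generator shares its adjective, shorthand and
#' stop-phrase tables with the matcher via `$tables`, so closed-world
#' recovery experiments are possible; pass different tables to the
#' matcher to emulate the real-world table gap.
#'
#' @param ontology An `ontology`, e.g. from [generate_ontology()].
#' @param spec A [corruption_spec()].
#' @param config [normalizer_config()] used to compute the normalized
#'   form (and hence gold keys) of every annotation.
#' @return A `synthetic_corpus`: list with `ontology`, `annotations`
#'   (tibble `text`, `species`, `source`, `corruption`, `normalized`,
#'   `gold_ids`), `gold` (named list keyed by normalized term), `tables`
#'   (shorthand/adjective/stop-phrase tables used), `spec`, `config`.
#' @export
corrupt <- function(ontology, spec, config = normalizer_config()) {
  stopifnot(inherits(ontology, "ontology"),
            inherits(spec, "corruption_spec"))
  if (nrow(ontology$classes) == 0L) stop("ontology is empty")

  index <- build_index(ontology, config)
  keys <- index_keys(index)
  classes <- ontology$classes[!ontology$classes$obsolete, , drop = FALSE]
  syn <- ontology$synonyms[ontology$synonyms$scope == "EXACT", ,
                           drop = FALSE]
  adj_tab <- default_adjective_table()
  adj_inv <- stats::setNames(names(adj_tab), adj_tab)
  adj_inv <- adj_inv[!duplicated(names(adj_inv))]
  ang_tab <- config$anglicism_table
  stop_tab <- default_stop_phrases()
  counts <- apportion(spec$proportions, spec$n_terms)

  with_seed(spec$seed, {
    used <- new.env(parent = emptyenv())
    shorthand_tab <- list()
    rows <- list()

    claim <- function(norm) {
      if (is.null(norm) || is.na(norm) || !nzchar(norm)) return(FALSE)
      if (exists(norm, envir = used, inherits = FALSE)) return(FALSE)
      assign(norm, TRUE, envir = used)
      TRUE
    }
    norm_of <- function(text, species = "") {
      x <- strip_species(text, species)[[1]]
      normalize_text(x, config)$normalized
    }
    # every class carrying a given indexed string: a term equal to a label
    # shared by two classes is correctly mapped to both
    ids_of <- function(key) {
      sort(unique(index$lexical$id[index$lexical$key == key]))
    }
    head_word <- function(label) {
      w <- strsplit(label, " ", fixed = TRUE)[[1]]
      w[[length(w)]]
    }
    class_heads <- vapply(classes$label, head_word, character(1L),
                          USE.NAMES = FALSE)
    swap_head <- function(label, new) {
      w <- strsplit(label, " ", fixed = TRUE)[[1]]
      paste(c(w[-length(w)], new), collapse = " ")
    }

    species_pool <- spec$species_mixture
    draw_species <- function(n) {
      sample(species_pool$species, n, replace = TRUE,
             prob = species_pool$proportion)
    }

    # produce (text, gold ids) for one instance of one corruption class,
    # or NULL when the sampled material does not support the rule
    make_one <- function(cls, ci) {
      lab <- classes$label[[ci]]
      id <- classes$id[[ci]]
      sp <- draw_species(1L)
      switch(cls,
        identity = list(text = lab, species = sp, ids = ids_of(lab)),
        synonym_use = {
          s <- syn$text[syn$id == id]
          if (length(s) == 0L) return(NULL)
          list(text = s[[1]], species = sp, ids = ids_of(s[[1]]))
        },
        plural = {
          pl <- pluralize_word(head_word(lab))
          if (is.na(pl)) return(NULL)
          txt <- swap_head(lab, pl)
          if (txt %in% keys) return(NULL)
          if (!lab %in% plural_variants(txt)) return(NULL)
          list(text = txt, species = sp, ids = ids_of(lab))
        },
        adjectival = {
          hw <- head_word(lab)
          if (!hw %in% names(adj_inv)) return(NULL)
          txt <- swap_head(lab, adj_inv[[hw]])
          if (txt %in% keys) return(NULL)
          list(text = txt, species = sp, ids = ids_of(lab))
        },
        anglicism = {
          txt <- britishize(lab, ang_tab)
          if (is.na(txt) || txt %in% keys) return(NULL)
          list(text = txt, species = sp, ids = ids_of(lab))
        },
        species_suffix = {
          list(text = paste(lab, sp), species = sp, ids = ids_of(lab))
        },
        whitespace_punct = {
          txt <- mangle_whitespace(lab)
          if (identical(txt, lab)) return(NULL)
          list(text = txt, species = sp, ids = ids_of(lab))
        },
        misspelling_ed1 = {
          txt <- edit1(lab)
          if (is.na(txt) || txt %in% keys) return(NULL)
          d <- utils::adist(txt, keys)
          if (sum(d == 1L) != 1L || keys[d == 1L] != lab) return(NULL)
          # must be recoverable by edit-distance repair ONLY, not by the
          # morphological stages (keeps corruption classes separable)
          if (any(plural_variants(txt) %in% keys)) return(NULL)
          if (adjectival_to_noun(txt, adj_tab) %in% keys) return(NULL)
          list(text = txt, species = sp, ids = ids_of(lab))
        },
        composite_delimiter = {
          cj <- sample(nrow(classes), 1L)
          if (cj == ci) return(NULL)
          lab2 <- classes$label[[cj]]
          if (identical(lab2, lab)) return(NULL)
          sep <- sample(c("/", ", ", " and "), 1L)
          list(text = paste0(lab, sep, lab2), species = sp,
               ids = union(ids_of(lab), ids_of(lab2)))
        },
        composite_locative = {
          cj <- sample(nrow(classes), 1L)
          if (cj == ci) return(NULL)
          lab2 <- classes$label[[cj]]
          if (identical(lab2, lab)) return(NULL)
          conn <- sample(c(", flushed from ", " from ", " derived from "), 1L)
          list(text = paste0(lab, conn, lab2), species = sp,
               ids = union(ids_of(lab), ids_of(lab2)))
        },
        shorthand = {
          hw <- head_word(lab)
          if (hw %in% keys || hw %in% names(shorthand_tab)) return(NULL)
          if (length(strsplit(lab, " ")[[1]]) < 2L) return(NULL)
          # the shorthand stands for every class whose label ends in this
          # head noun (one shorthand may expand to several classes)
          expans <- sort(unique(classes$label[class_heads == hw]))
          shorthand_tab[[hw]] <<- expans
          list(text = hw, species = sp,
               ids = sort(unique(unlist(lapply(expans, ids_of)))))
        },
        process_phrase = {
          list(text = paste(lab, sample(stop_tab, 1L)), species = sp,
               ids = ids_of(lab))
        },
        uninterpretable = {
          k <- sample(2:40, 1L)
          noun <- sample(c("different tissues", "pooled samples",
                           "mixed regions", "unspecified sites"), 1L)
          list(text = paste(k, noun), species = sp, ids = character())
        })
    }

    # classes with the narrowest eligibility (anglicism needs a British-
    # respellable word; adjectival a table noun) draw first, before the
    # generic classes claim source labels
    generation_order <- c(
      "anglicism", "adjectival", "plural", "misspelling_ed1", "shorthand",
      "synonym_use", "composite_delimiter", "composite_locative",
      "uninterpretable", "identity", "species_suffix", "whitespace_punct",
      "process_phrase")
    for (cls in generation_order) {
      need <- counts[[cls]]
      made <- 0L
      tries <- 0L
      max_tries <- 200L * max(need, 1L)
      while (made < need) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop(sprintf(
            "could not generate %d '%s' annotations (ontology too small or rule inapplicable)",
            need, cls))
        }
        ci <- sample(nrow(classes), 1L)
        one <- make_one(cls, ci)
        if (is.null(one)) next
        norm <- tryCatch(norm_of(one$text, one$species),
                         error = function(e) NA_character_)
        # corrupted forms must not collide with each other, and must not
        # accidentally equal an index string of an unrelated class
        if (!is.na(norm) && cls %in% c("plural", "adjectival", "anglicism",
                                       "whitespace_punct", "misspelling_ed1",
                                       "shorthand", "process_phrase",
                                       "species_suffix")) {
          wrong <- setdiff(index$lexical$id[index$lexical$key == norm],
                           one$ids)
          if (length(wrong) &&
              !(norm %in% keys && cls %in% c("whitespace_punct",
                                             "species_suffix",
                                             "process_phrase"))) {
            if (cls == "shorthand") {
              shorthand_tab[[one$text]] <<- NULL
            }
            next
          }
        }
        if (is.na(norm) || !claim(norm)) {
          if (cls == "shorthand") shorthand_tab[[one$text]] <<- NULL
          next
        }
        made <- made + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          text = one$text, species = one$species, source = "synthetic",
          corruption = cls, normalized = norm,
          gold_ids = paste(sort(one$ids), collapse = ";"))
      }
    }

    ann <- do.call(rbind, rows)
    ann <- ann[sample(nrow(ann)), , drop = FALSE]

    n_dup <- round(spec$duplicate_fraction * spec$n_terms)
    if (n_dup > 0L) {
      src <- sample(nrow(ann), n_dup, replace = n_dup > nrow(ann))
      dups <- ann[src, , drop = FALSE]
      for (r in seq_len(nrow(dups))) {
        other <- setdiff(species_pool$species, dups$species[[r]])
        sp2 <- sample(other, 1L)
        if (dups$corruption[[r]] == "species_suffix") {
          base <- sub(paste0("\\s+", dups$species[[r]], "$"), "",
                      dups$text[[r]])
          dups$text[[r]] <- paste(base, sp2)
        }
        dups$species[[r]] <- sp2
      }
      ann <- rbind(ann, dups)
      ann <- ann[sample(nrow(ann)), , drop = FALSE]
    }

    gold <- split(ann$gold_ids, ann$normalized)
    gold <- lapply(gold, function(v) {
      ids <- unique(unlist(strsplit(v, ";", fixed = TRUE)))
      ids[nzchar(ids)]
    })

    structure(list(ontology = ontology, annotations = ann, gold = gold,
                   tables = list(shorthand = shorthand_tab,
                                 adjective = adj_tab,
                                 stop_phrases = stop_tab),
                   spec = spec, config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d annotations over %d classes (%d corruption classes)\n",
    nrow(x$annotations), nrow(x$ontology$classes),
    length(unique(x$annotations$corruption))))
  invisible(x)
}

#' Matcher configuration wired to a synthetic corpus
#'
#' Convenience constructor for [match_config()] that injects the
#' corpus-generated shorthand table and the shared adjective and
#' stop-phrase tables, with all variant stages switched on (the
#' closed-world recovery setting).
#'
#' @param corpus A `synthetic_corpus`.
#' @param ... Overrides passed through to [match_config()].
#' @return A `match_config`.
#' @export
corpus_match_config <- function(corpus, ...) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  args <- list(plural = TRUE, adjectival = TRUE, shorthand = TRUE,
               composite = TRUE, spellfix = TRUE,
               adjective_table = corpus$tables$adjective,
               shorthand_table = corpus$tables$shorthand,
               stop_phrases = corpus$tables$stop_phrases)
  args[names(list(...))] <- list(...)
  do.call(match_config, args)
}

#' Per-corruption-class recovery rates
#'
#' Runs are judged per annotation: a term is recovered when its accepted
#' class set intersects its gold set (uninterpretable terms are recovered
#' when correctly left unmatched).
#'
#' @param corpus A `synthetic_corpus`.
#' @param result A `mapping_result` from running the matcher on the
#'   corpus's (normalized, deduplicated) terms.
#' @return Tibble `corruption`, `n`, `recovered`, `rate`.
#' @export
recovery_by_class <- function(corpus, result) {
  stopifnot(inherits(corpus, "synthetic_corpus"),
            inherits(result, "mapping_result"))
  ann <- corpus$annotations[!duplicated(corpus$annotations$normalized), ,
                            drop = FALSE]
  oc <- result$outcomes
  acc <- strsplit(oc$accepted, ";", fixed = TRUE)
  names(acc) <- oc$query
  rec <- vapply(seq_len(nrow(ann)), function(i) {
    g <- strsplit(ann$gold_ids[[i]], ";", fixed = TRUE)[[1]]
    g <- g[nzchar(g)]
    a <- acc[[ann$normalized[[i]]]]
    a <- a[nzchar(a)]
    if (length(g) == 0L) length(a) == 0L else length(intersect(a, g)) > 0L
  }, logical(1L))
  agg <- split(rec, ann$corruption)
  tibble::tibble(
    corruption = names(agg),
    n = unname(vapply(agg, length, integer(1L))),
    recovered = unname(vapply(agg, sum, integer(1L))),
    rate = unname(vapply(agg, mean, numeric(1L))))
}

#' Write a synthetic corpus to disk
#'
#' Emits the fixture files: `ontology.obo`, `terms.tsv`
#' (`term<TAB>species`), `gold.tsv` (`term<TAB>id;id`), and `labels.tsv`
#' (`term<TAB>corruption class`).
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(corpus$ontology, file.path(dir, "ontology.obo"))
  ann <- corpus$annotations
  writeLines(sprintf("%s\t%s", ann$text, ann$species),
             file.path(dir, "terms.tsv"), useBytes = TRUE)
  writeLines(sprintf("%s\t%s", names(corpus$gold),
                     vapply(corpus$gold, paste, character(1L),
                            collapse = ";")),
             file.path(dir, "gold.tsv"), useBytes = TRUE)
  writeLines(sprintf("%s\t%s", ann$text, ann$corruption),
             file.path(dir, "labels.tsv"), useBytes = TRUE)
  invisible(dir)
}
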