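test_that("ontology generation is deterministic and exactly parameterized", {
  a <- generate_ontology(10, synonym_rate = 0.5, seed = 1)
  b <- generate_ontology(10, synonym_rate = 0.5, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$classes), 10L)
  expect_equal(length(unique(a$synonyms$id)), 5L)   # exactly half

  d <- generate_ontology(20, synonym_rate = 0.2, duplicate_label_count = 2,
                         seed = 7)
  expect_equal(nrow(find_duplicate_labels(d)), 2L)

  expect_error(generate_ontology(5, duplicate_label_count = 5),
               "duplicate_label_count")
})

test_that("corruption spec validates proportions", {
  expect_error(corruption_spec(proportions = c(identity = 0.5)),
               "sum to 1")
  expect_error(corruption_spec(proportions = c(bogus_class = 1)),
               "unknown corruption class")
  s <- corruption_spec(n_terms = 10, proportions = c(identity = 1))
  expect_equal(unname(s$proportions[["identity"]]), 1)
})

test_that("an all-identity corpus is perfectly recovered by exact matching", {
  ont <- generate_ontology(80, synonym_rate = 0, seed = 3)
  corpus <- corrupt(ont, corruption_spec(n_terms = 40,
                                         proportions = c(identity = 1),
                                         seed = 9))
  expect_true(all(corpus$annotations$text %in% ont$classes$label))
  idx <- build_index(ont)
  clean <- deduplicate(normalize_terms(corpus$annotations$text,
                                       corpus$annotations$species))
  res <- run_matcher(clean, idx, match_config(mode = "exact"))
  cm <- compare_to_gold(res, corpus$gold)
  expect_equal(cm$tp, 40L)
  expect_equal(cm$fp, 0L)
  expect_equal(precision(cm), 1)
})

test_that("an all-uninterpretable corpus is correctly left unmatched", {
  ont <- generate_ontology(30, seed = 3)
  corpus <- corrupt(ont, corruption_spec(
    n_terms = 15, proportions = c(uninterpretable = 1), seed = 4))
  idx <- build_index(ont)
  clean <- deduplicate(normalize_terms(corpus$annotations$text,
                                       corpus$annotations$species))
  res <- run_matcher(clean, idx, match_config(mode = "exact"))
  cm <- compare_to_gold(res, corpus$gold)
  expect_equal(cm$tn, 15L)
  expect_equal(cm$tp + cm$fp + cm$fn, 0L)
})

test_that("corpus regeneration under a fixed spec and seed is bit-identical", {
  ont <- generate_ontology(100, synonym_rate = 0.4, seed = 5)
  spec <- corruption_spec(n_terms = 80, seed = 11, duplicate_fraction = 0.25)
  a <- corrupt(ont, spec)
  b <- corrupt(ont, spec)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$gold, b$gold)
  expect_identical(a$tables, b$tables)
})

test_that("every corruption label matches the rule actually applied", {
  ont <- generate_ontology(150, synonym_rate = 0.5, seed = 5)
  labels <- ont$classes$label
  syns <- ont$synonyms$text
  corpus <- corrupt(ont, corruption_spec(n_terms = 130, seed = 2))
  ann <- corpus$annotations
  for (i in seq_len(nrow(ann))) {
    cls <- ann$corruption[[i]]
    txt <- ann$text[[i]]
    ok <- switch(cls,
      identity = txt %in% labels,
      synonym_use = txt %in% syns,
      plural = !txt %in% labels && length(plural_variants(txt)) > 0,
      species_suffix = grepl(" [A-Z][a-z]+ [a-z]+$", paste0(" ", txt)),
      composite_delimiter = grepl("/|,| and ", txt),
      composite_locative = grepl("from", txt),
      shorthand = txt %in% names(corpus$tables$shorthand),
      process_phrase = grepl("biopsy|lavage", txt),
      uninterpretable = grepl("^[0-9]+ ", txt),
      TRUE)  # remaining classes checked via recovery tests
    expect_true(ok, label = paste(cls, "->", txt))
  }
  # gold-mapped ids all exist in the ontology
  expect_true(all(unlist(corpus$gold) %in% ont$classes$id))
})

test_that("cross-species duplicates collapse to the requested unique count", {
  # a raw corpus of 1537 rows built as 1097 unique terms plus 440
  # cross-species duplicates collapses back to 1097 after normalization
  ont <- generate_ontology(700, synonym_rate = 0.4, seed = 13)
  spec <- corruption_spec(n_terms = 1097, duplicate_fraction = 440 / 1097,
                          seed = 17)
  corpus <- corrupt(ont, spec)
  expect_equal(nrow(corpus$annotations), 1537L)
  clean <- deduplicate(normalize_terms(corpus$annotations$text,
                                       corpus$annotations$species))
  expect_equal(nrow(clean), 1097L)
  # duplicates differ in species, not in normalized term
  collapsed <- attr(clean, "collapsed")
  expect_gt(nrow(collapsed), 0L)
})

test_that("species mixture follows the configured proportions", {
  ont <- generate_ontology(400, seed = 19)
  corpus <- corrupt(ont, corruption_spec(n_terms = 400, seed = 23))
  tab <- table(corpus$annotations$species)
  expect_gt(tab[["Homo sapiens"]] / sum(tab), 0.4)
  expect_gt(tab[["Mus musculus"]] / sum(tab), 0.18)
})

test_that("corpus fixture files are written as plain text", {
  ont <- generate_ontology(30, synonym_rate = 0.5, seed = 29)
  corpus <- corrupt(ont, corruption_spec(n_terms = 25, seed = 31))
  dir <- file.path(tempdir(), "corpus-fixture")
  write_corpus(corpus, dir)
  expect_true(all(file.exists(file.path(
    dir, c("ontology.obo", "terms.tsv", "gold.tsv", "labels.tsv")))))
  back <- parse_obo(file.path(dir, "ontology.obo"))
  expect_equal(back$classes, ont$classes)
  terms <- read_terms_tsv(file.path(dir, "terms.tsv"))
  expect_equal(terms$text, corpus$annotations$text)
  gold <- read_gold_tsv(file.path(dir, "gold.tsv"))
  expect_setequal(names(gold), names(corpus$gold))
})
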