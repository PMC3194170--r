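test_that("parse_obo reads ids, labels, synonym scopes and obsolete flags", {
  ont <- parse_obo(obo_fixture_path())
  expect_s3_class(ont, "ontology")
  expect_equal(nrow(ont$classes), 5L)
  expect_equal(sum(ont$classes$obsolete), 1L)
  expect_equal(ont$classes$label[ont$classes$id == "T:001"], "liver")

  syn <- ont$synonyms
  expect_equal(syn$text[syn$id == "T:001"], "hepatic tissue")
  expect_equal(syn$scope[syn$id == "T:001"], "EXACT")
  # scope keyword absent -> RELATED
  expect_equal(syn$scope[syn$id == "T:002"], "RELATED")
})

test_that("parse_obo errors name the offending input", {
  expect_error(parse_obo(file.path(tempdir(), "no-such-file.obo")),
               "cannot read")
  bad <- file.path(tempdir(), "bad.obo")
  writeLines(c("[Term]", "name: orphan", ""), bad)
  expect_error(parse_obo(bad), "line 1")
})

test_that("an ontology round-trips through write_obo/parse_obo", {
  ont <- parse_obo(obo_fixture_path())
  p <- file.path(tempdir(), "roundtrip.obo")
  write_obo(ont, p)
  back <- parse_obo(p)
  expect_equal(back$classes, ont$classes)
  expect_equal(back$synonyms[order(back$synonyms$id), ],
               ont$synonyms[order(ont$synonyms$id), ])
})

test_that("build_index normalizes and indexes labels and EXACT synonyms", {
  idx <- build_index(as_ontology(
    tibble::tibble(id = "T:001", label = "Liver", obsolete = FALSE)))
  expect_equal(idx$lexical$key, "liver")
  expect_equal(idx$lexical$id, "T:001")
  expect_equal(idx$lexical$origin, "label")

  ont <- parse_obo(obo_fixture_path())
  idx <- build_index(ont)
  # duplicated label (Ureter/ureter) collapses to one key with 2 members
  expect_equal(sort(idx$lexical$id[idx$lexical$key == "ureter"]),
               c("T:003", "T:004"))
  # obsolete class not indexed by default
  expect_false("old liver" %in% idx$lexical$key)
  expect_true("old liver" %in%
                index_keys(build_index(ont, include_obsolete = TRUE)))
  # RELATED synonym excluded by default, admitted when widened
  expect_false("renal organ" %in% index_keys(idx))
  wide <- build_index(ont, synonym_scopes = c("EXACT", "RELATED"))
  expect_true("renal organ" %in% index_keys(wide))

  expect_error(build_index(as_ontology(
    tibble::tibble(id = character(), label = character(),
                   obsolete = logical()))), "empty")
})

test_that("index key count equals independent enumeration of unique strings", {
  ont <- generate_ontology(20, synonym_rate = 0.4, seed = 11)
  idx <- build_index(ont)
  # oracle: enumerate and normalize every admissible string independently
  strings <- c(ont$classes$label[!ont$classes$obsolete],
               ont$synonyms$text[ont$synonyms$scope == "EXACT"])
  oracle_keys <- unique(vapply(strings, function(x) {
    normalize_text(x)$normalized
  }, character(1L), USE.NAMES = FALSE))
  expect_setequal(index_keys(idx), oracle_keys)
})

test_that("index building is deterministic field by field", {
  ont <- parse_obo(obo_fixture_path())
  a <- build_index(ont)
  b <- build_index(ont)
  expect_identical(a$lexical, b$lexical)
  expect_identical(a$phonetic, b$phonetic)
  expect_identical(a$fingerprint, b$fingerprint)
  # every phonetic key appears in the lexical map
  expect_true(all(a$phonetic$key %in% a$lexical$key))
})

test_that("find_duplicate_labels reports shared labels case-insensitively", {
  ont <- parse_obo(obo_fixture_path())
  dups <- find_duplicate_labels(ont)
  expect_equal(dups$label, "ureter")
  expect_equal(dups$ids[[1]], c("T:003", "T:004"))
  # every reported id resolves to a parsed class
  expect_true(all(unlist(dups$ids) %in% ont$classes$id))

  distinct <- as_ontology(tibble::tibble(
    id = c("A:1", "A:2"), label = c("liver", "kidney"), obsolete = FALSE))
  expect_equal(nrow(find_duplicate_labels(distinct)), 0L)

  triple <- as_ontology(tibble::tibble(
    id = c("A:1", "A:2", "A:3"), label = rep("ureter", 3),
    obsolete = FALSE))
  d3 <- find_duplicate_labels(triple)
  expect_equal(nrow(d3), 1L)
  expect_length(d3$ids[[1]], 3L)

  p <- file.path(tempdir(), "dups.tsv")
  write_duplicate_report(dups, p)
  expect_equal(readLines(p)[2], "ureter\tT:003,T:004")
})

test_that("lexical_overlap is the Jaccard percentage of index keys", {
  mk <- function(labels, prefix) {
    build_index(as_ontology(tibble::tibble(
      id = sprintf("%s:%03d", prefix, seq_along(labels)),
      label = labels, obsolete = FALSE)))
  }
  a <- mk(c("a fossa", "b fossa", "c fossa"), "A")
  b <- mk(c("b fossa", "c fossa", "d fossa"), "B")
  expect_equal(lexical_overlap(a, b), 50)            # 2 of 4
  expect_equal(lexical_overlap(a, a), 100)
  expect_equal(lexical_overlap(a, b), lexical_overlap(b, a))
  disjoint <- mk(c("x fossa", "y fossa"), "X")
  expect_equal(lexical_overlap(a, disjoint), 0)

  other_cfg <- build_index(
    as_ontology(tibble::tibble(id = "Z:1", label = "b fossa",
                               obsolete = FALSE)),
    normalizer_config(americanize = FALSE))
  expect_error(lexical_overlap(a, other_cfg), "config")
})
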