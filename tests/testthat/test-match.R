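test_that("exact matching hits labels and synonyms, misses composites", {
  idx <- build_index(toy_ontology())
  hit <- exact_match("liver", idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$class_id, "T:001")
  expect_equal(hit$match_kind, "exact_label")

  syn <- exact_match("hepatic tissue", idx)
  expect_equal(syn$match_kind, "exact_synonym")

  expect_equal(nrow(exact_match("liver/kidney", idx)), 0L)
})

test_that("duplicate labels yield two candidates ranked by id", {
  idx <- build_index(as_ontology(tibble::tibble(
    id = c("U:002", "U:001"), label = c("Ureter", "ureter"),
    obsolete = FALSE)))
  hits <- exact_match("ureter", idx)
  expect_equal(hits$class_id, c("U:001", "U:002"))
  expect_equal(hits$rank, 1:2)
})

test_that("every indexed label matches its own class (reflexivity)", {
  ont <- generate_ontology(40, synonym_rate = 0.3, seed = 2)
  idx <- build_index(ont)
  for (i in seq_len(nrow(ont$classes))) {
    q <- normalize_text(ont$classes$label[[i]])$normalized
    hits <- exact_match(q, idx)
    expect_true(ont$classes$id[[i]] %in% hits$class_id,
                label = ont$classes$label[[i]])
  }
})

test_that("phonetic proposal sets equal the exhaustive encode-and-compare oracle", {
  ont <- dense_phonetic_ontology()
  idx <- build_index(ont)
  keys <- index_keys(idx)
  key_codes <- phonetic_encode(keys)

  oracle <- function(q) {
    qc <- phonetic_encode(q)
    share <- key_codes$primary == qc$primary |
      key_codes$primary == qc$alternate |
      key_codes$alternate == qc$primary |
      key_codes$alternate == qc$alternate
    setdiff(keys[share], q)
  }

  queries <- c("bone marrow", "bane marrow", "liver lobe", "renal duct",
               "kidney")
  for (q in queries) {
    got <- phonetic_match(q, idx)
    got_keys <- unique(sub(" \\[[^]]*\\]$", "", got$evidence))
    expect_setequal(got_keys, oracle(q))
  }
})

test_that("phonetic proposals are deterministic, ranked, and suppress exact hits", {
  ont <- dense_phonetic_ontology()
  idx <- build_index(ont)
  a <- phonetic_match("bone marrow", idx)
  b <- phonetic_match("bone marrow", idx)
  expect_identical(a, b)
  expect_equal(a$rank, seq_len(nrow(a)))
  # the query string itself is never proposed (exact matcher owns it)
  expect_false(any(grepl("^bone marrow \\[", a$evidence)))
  expect_true(all(a$match_kind == "phonetic"))
})

test_that("singularization rules and exceptions", {
  expect_equal(plural_variants("kidneys"), "kidney")
  expect_equal(plural_variants("arteries"), "artery")
  expect_equal(plural_variants("branches"), "branch")
  expect_equal(plural_variants("pancreas"), character())
  expect_equal(plural_variants("left kidneys"), "left kidney")
})

test_that("adjectival and shorthand rewrites", {
  expect_equal(adjectival_to_noun("abdominal"), "abdomen")
  expect_equal(adjectival_to_noun("arterial"), "artery")
  expect_equal(adjectival_to_noun("hepatic portal vein",
                                  table = c(arterial = "artery")),
               "hepatic portal vein")

  expect_equal(expand_shorthand("both ventricles"),
               c("left ventricle of heart", "right ventricle of heart"))
  expect_equal(expand_shorthand("antrum"), "pyloric antrum")
  expect_equal(expand_shorthand("liver"), "liver")
})

test_that("the cascade matches exactly, then variants, never fewer with phonetics", {
  ont <- toy_ontology()
  idx <- build_index(ont)
  terms <- c("liver", "kidney", "bone marrow", "femur", "pyloric antrum",
             "left ventricle of heart",          # 6 exact
             "spleen", "cerebellum", "armpit", "elbow")  # 4 absent
  res <- run_matcher(terms, idx, match_config(mode = "exact"))
  expect_equal(sum(res$outcomes$status == "matched"), 6L)
  expect_equal(sum(res$outcomes$status == "unmatched"), 4L)

  resp <- run_matcher(terms, idx, match_config(mode = "phonetic"))
  expect_equal(sum(resp$outcomes$status == "matched"), 6L)
  expect_gte(sum(resp$outcomes$status != "unmatched"),
             sum(res$outcomes$status != "unmatched"))
  # outcome conservation
  expect_equal(nrow(resp$outcomes), length(terms))
})

test_that("variant stages recover plural, adjectival and shorthand queries", {
  idx <- build_index(toy_ontology())
  cfg <- match_config(plural = TRUE, adjectival = TRUE, shorthand = TRUE,
                      adjective_table = c(femoral = "femur"))
  res <- run_matcher(c("kidneys", "femoral", "antrum", "both ventricles"),
                     idx, cfg)
  expect_true(all(res$outcomes$status == "matched"))
  kinds <- res$candidates$match_kind
  expect_setequal(unique(kinds),
                  c("plural_variant", "adjectival", "shorthand"))
  # shorthand may map one query to one class here; evidence names rewrite
  expect_match(res$candidates$evidence[kinds == "plural_variant"][1],
               "kidney")

  off <- run_matcher(c("kidneys"), idx, match_config())
  expect_equal(off$outcomes$status, "unmatched")
})

test_that("phonetic proposals never enter accepted sets without curation", {
  idx <- build_index(dense_phonetic_ontology())
  res <- run_matcher("bane morrow", idx, match_config(mode = "phonetic"))
  expect_equal(res$outcomes$status, "proposed_only")
  expect_equal(res$outcomes$n_accepted, 0L)

  # a curation decision promotes a proposed pair
  pick <- res$candidates$class_id[[1]]
  cur <- tibble::tibble(term = "bane morrow", class_id = pick)
  res2 <- run_matcher("bane morrow", idx, match_config(mode = "phonetic"),
                      curations = cur)
  expect_equal(res2$outcomes$status, "matched")
  expect_equal(res2$outcomes$accepted, pick)

  expect_error(
    run_matcher("bane morrow", idx, match_config(mode = "phonetic"),
                curations = tibble::tibble(term = "nonexistent term",
                                           class_id = "X:1")),
    "unknown")
})

test_that("exact candidates always rank above phonetic candidates", {
  ont <- as_ontology(tibble::tibble(
    id = c("A:1", "A:2"), label = c("liver", "livor"), obsolete = FALSE))
  idx <- build_index(ont)
  res <- run_matcher("liver", idx, match_config(mode = "phonetic"))
  cc <- res$candidates
  expect_lt(max(cc$rank[cc$match_kind != "phonetic"]),
            min(cc$rank[cc$match_kind == "phonetic"]))
})

test_that("empty term list yields an empty outcome list", {
  idx <- build_index(toy_ontology())
  res <- run_matcher(character(), idx)
  expect_equal(nrow(res$outcomes), 0L)
  expect_equal(nrow(res$candidates), 0L)
})

test_that("optional edit-distance stage proposes near misses when enabled", {
  idx <- build_index(toy_ontology())
  off <- run_matcher("livr", idx, match_config())
  expect_equal(off$outcomes$status, "unmatched")
  on <- run_matcher("livr", idx, match_config(levenshtein = TRUE))
  expect_equal(on$outcomes$status, "proposed_only")
  expect_equal(unique(on$candidates$match_kind), "levenshtein")
})
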