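test_that("composite splitting on delimiters, conjunctions and locatives", {
  d <- split_composite("liver/kidney")
  expect_equal(d$components, c("liver", "kidney"))
  expect_equal(d$kind, "delimiter")

  d <- split_composite("acetabulum and pelvic soft tissues")
  expect_equal(d$components, c("acetabulum", "pelvic soft tissues"))
  expect_equal(d$kind, "conjunction")

  d <- split_composite("bone marrow, flushed from femur")
  expect_equal(d$components, c("bone marrow", "femur"))
  expect_equal(d$kind, "locative")

  d <- split_composite("bone marrow from femur")
  expect_equal(d$components, c("bone marrow", "femur"))
  expect_equal(d$kind, "locative")
})

test_that("atomic terms are not split: 'of' is not a separator", {
  d <- split_composite("left ventricle of heart")
  expect_equal(d$kind, "none")
  expect_equal(d$components, "left ventricle of heart")
  expect_length(d$separators_used, 0L)
})

test_that("decomposition is idempotent on its own components", {
  d <- split_composite("liver/kidney, spleen")
  for (comp in d$components) {
    expect_equal(split_composite(comp)$kind, "none", label = comp)
  }
})

test_that("no non-separator characters are lost in decomposition", {
  inputs <- c("liver/kidney", "bone marrow, flushed from femur",
              "acetabulum and pelvic soft tissues", "a, b and c/d")
  for (x in inputs) {
    d <- split_composite(x)
    # every letter of the components appears in the original
    leftover <- gsub("[ /,]", "", paste(d$components, collapse = ""))
    orig <- gsub("[ /,]", "", x)
    for (comp in d$components) {
      expect_true(grepl(gsub(" ", ".*", comp), x), label = comp)
    }
    expect_lte(nchar(leftover), nchar(orig))
  }
})

test_that("process stop-phrases are stripped before matching", {
  expect_equal(strip_process_phrases("colon pinch biopsy"), "colon")
  expect_equal(strip_process_phrases("ba lavage"), "ba")
  expect_equal(strip_process_phrases("liver"), "liver")
})

test_that("cross-product matching under any/all policies", {
  idx <- build_index(toy_ontology())

  d <- split_composite("bone marrow, flushed from femur")
  any_hits <- cross_product_match(d, idx, policy = "any")
  all_hits <- cross_product_match(d, idx, policy = "all")
  expect_setequal(any_hits$class_id, c("T:003", "T:004"))
  expect_setequal(all_hits$class_id, any_hits$class_id)

  # only one component indexed: any keeps it, all drops everything
  d2 <- split_composite("femur and pelvic soft tissues")
  expect_equal(cross_product_match(d2, idx, policy = "any")$class_id,
               "T:004")
  expect_equal(nrow(cross_product_match(d2, idx, policy = "all")), 0L)

  # policy=all candidates are always a subset of policy=any
  for (q in c("liver/kidney", "liver/armpit", "armpit/elbow")) {
    dd <- split_composite(q)
    a <- cross_product_match(dd, idx, policy = "any")$class_id
    l <- cross_product_match(dd, idx, policy = "all")$class_id
    expect_true(all(l %in% a), label = q)
  }

  expect_error(cross_product_match(split_composite("liver"), idx),
               "kind")
})

test_that("token-sharing components raise the redundancy flag for curation", {
  ont <- as_ontology(tibble::tibble(
    id = c("A:1", "A:2"), label = c("adrenal cortex", "adrenal gland"),
    obsolete = FALSE))
  idx <- build_index(ont)
  d <- split_composite("adrenal cortex, adrenal gland")
  hits <- cross_product_match(d, idx)
  expect_equal(nrow(hits), 2L)
  expect_true(attr(hits, "redundant"))

  d2 <- split_composite("liver/kidney")
  idx2 <- build_index(toy_ontology())
  expect_false(attr(cross_product_match(d2, idx2), "redundant"))
})

test_that("the composite stage recovers component matches in the cascade", {
  idx <- build_index(toy_ontology())
  cfg <- match_config(composite = TRUE)
  res <- run_matcher(c("liver/kidney", "bone marrow, flushed from femur",
                       "liver pinch biopsy"), idx, cfg)
  expect_true(all(res$outcomes$status == "matched"))
  expect_setequal(
    strsplit(res$outcomes$accepted[res$outcomes$query == "liver/kidney"],
             ";")[[1]],
    c("T:001", "T:002"))

  # uninterpretable numeric annotations are routed to unmatched
  res2 <- run_matcher("11 different tissues", idx, cfg)
  expect_equal(res2$outcomes$status, "unmatched")
  expect_equal(res2$outcomes$reason, "uninterpretable")
})
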