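test_that("confusion matrix cells follow the term/pair counting rules", {
  ont <- toy_ontology()
  idx <- build_index(ont)

  # empty run
  res <- run_matcher(character(), idx)
  cm <- compare_to_gold(res, list())
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 0L, fp = 0L, tn = 0L, fn = 0L))

  # 3 correct accepts + 1 correctly unmatched unmappable term
  res <- run_matcher(c("liver", "kidney", "femur", "mystery tissue"), idx,
                     match_config(mode = "exact"))
  gold <- list("liver" = "T:001", "kidney" = "T:002", "femur" = "T:004",
               "mystery tissue" = character())
  cm <- compare_to_gold(res, gold)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 3L, fp = 0L, tn = 1L, fn = 0L))

  # hand-enumerated mixed fixture: 5 gold-mapped terms, 4 recovered,
  # 2 spurious accepted pairs, 1 missed
  gold2 <- list("liver" = "T:001", "kidney" = "T:002", "femur" = "T:004",
                "bone marrow" = "T:003", "armpit" = "T:999")
  res2 <- run_matcher(names(gold2), idx, match_config(mode = "exact"))
  # spurious pairs injected via curation-style misassignment in gold:
  # pretend "liver" maps to a different class so its accept is wrong
  gold2$liver <- "T:777"
  cm2 <- compare_to_gold(res2, gold2)
  # tp: kidney, femur, bone marrow; fn: liver (wrong class) + armpit
  expect_equal(cm2$tp, 3L)
  expect_equal(cm2$fn, 2L)
  expect_equal(cm2$fp, 1L)     # the wrongly-accepted liver pair

  expect_error(compare_to_gold(res2, gold2["liver"]), "missing")
})

test_that("proposal counting multiplies false positives", {
  idx <- build_index(dense_phonetic_ontology())
  res <- run_matcher("bane morrow", idx, match_config(mode = "phonetic"))
  gold <- list("bane morrow" = character())
  cm_terms <- compare_to_gold(res, gold, count_proposals = FALSE)
  cm_pairs <- compare_to_gold(res, gold, count_proposals = TRUE)
  expect_equal(cm_terms$fp, 0L)
  expect_gt(cm_pairs$fp, 1L)
  expect_equal(cm_pairs$fp, res$outcomes$n_proposed)
})

test_that("precision and recall with undefined markers", {
  expect_equal(precision(confusion_matrix(277, 9, 813, 0)), 0.969)
  expect_equal(precision(confusion_matrix(229, 83, 787, 0)), 0.734)
  expect_equal(precision(confusion_matrix(229, 32485, 702, 0)), 0.007)
  expect_equal(recall(confusion_matrix(277, 9, 813, 0)), 1.000)
  expect_equal(recall(confusion_matrix(5, 0, 0, 5)), 0.5)
  expect_true(is.na(precision(confusion_matrix(0, 0, 10, 5))))
  expect_true(is.na(recall(confusion_matrix(0, 3, 10, 0))))
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("coverage arithmetic and input validation", {
  expect_equal(coverage(229, 1099), 20.84)
  expect_equal(coverage(277, 1099), 25.20)
  expect_equal(coverage(0, 50), 0)
  expect_error(coverage(5, 0), "positive")
  expect_error(coverage(-1, 10), "matched")
  expect_error(coverage(11, 10), "matched")
})

test_that("rounding is half-up at report precision, full internally", {
  # 0.9685... must round UP to 0.969, not bankers-round down
  expect_equal(precision(confusion_matrix(277, 9, 0, 0)), 0.969)
  expect_equal(precision(confusion_matrix(277, 9, 0, 0), digits = NULL),
               277 / 286)
  expect_equal(coverage(277, 1099, digits = NULL), 100 * 277 / 1099)
})

test_that("metrics_report assembles the full per-run row", {
  cm <- confusion_matrix(277, 9, 813, 0)
  rep <- metrics_report(cm, matched_count = 277, total_terms = 1099)
  expect_equal(rep$precision, 0.969)
  expect_equal(rep$recall, 1.000)
  expect_equal(rep$coverage_percent, 25.20)
  expect_equal(rep$total_terms, 1099L)
})

test_that("gold TSV round-trips with normalized keys", {
  p <- file.path(tempdir(), "gold.tsv")
  writeLines(c("Liver\tT:001", "Liver/Kidney\tT:001;T:002",
               "mystery  tissue\t"), p)
  gold <- read_gold_tsv(p)
  expect_equal(gold[["liver"]], "T:001")
  expect_equal(gold[["liver/kidney"]], c("T:001", "T:002"))
  expect_length(gold[["mystery tissue"]], 0L)
})
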