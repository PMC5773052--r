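nrel <- function(doc, ac, go) {
  tibble::tibble(doc_id = doc, uniprot_ac = ac, go_id = go)
}

test_that("relation matching honors the asymmetric GO-descendant rule", {
  ont <- test_ontology()
  pol <- match_policy()
  # predicting the more specific child of the annotated term is correct
  expect_true(match_relation(nrel("d", "P07225", "GO:0005886"),
                             nrel("d", "P07225", "GO:0016328"),
                             pol, ont))
  # predicting the less specific ancestor is not
  expect_false(match_relation(nrel("d", "P07225", "GO:0016328"),
                              nrel("d", "P07225", "GO:0005886"),
                              pol, ont))
  expect_false(match_relation(nrel("d", "P07225", "GO:0005886"),
                              nrel("d", "P04637", "GO:0005886"),
                              pol, ont))
  expect_false(match_relation(nrel("d1", "P07225", "GO:0005886"),
                              nrel("d2", "P07225", "GO:0005886"),
                              pol, ont))
  # pluggable equivalence provider can accept near-identical accessions
  pol2 <- match_policy(protein_equivalence_provider = function(a, b) {
    sort(c(a, b))[1] == "P07225" && sort(c(a, b))[2] == "Q00001"
  })
  expect_true(match_relation(nrel("d", "P07225", "GO:0005886"),
                             nrel("d", "Q00001", "GO:0005886"),
                             pol2, ont))
})

test_that("relation evaluation counts per gold relation", {
  ont <- test_ontology()
  gold <- dplyr::bind_rows(nrel("d", "P07225", "GO:0005886"),
                           nrel("d", "P04637", "GO:0005634"),
                           nrel("d", "P39968", "GO:0005773"))
  pred <- dplyr::bind_rows(nrel("d", "P07225", "GO:0016328"),  # matches 1
                           nrel("d", "P04637", "GO:0005634"),  # matches 2
                           nrel("d", "P17302", "GO:0005739"))  # spurious
  ev <- evaluate_relations(gold, pred, ontology = ont)
  expect_equal(ev$counts$tp, 2)
  expect_equal(ev$counts$fp, 1)
  expect_equal(ev$counts$fn, 1)
  expect_equal(ev$counts$precision, 200 / 3, tolerance = 1e-9)
  expect_equal(ev$counts$recall, 200 / 3, tolerance = 1e-9)

  # two predictions matching one gold relation: one tp, no fp
  pred2 <- dplyr::bind_rows(nrel("d", "P07225", "GO:0005886"),
                            nrel("d", "P07225", "GO:0016328"))
  ev2 <- evaluate_relations(gold[1, ], pred2, ontology = ont)
  expect_equal(ev2$counts$tp, 1)
  expect_equal(ev2$counts$fp, 0)

  # degenerate: no predictions
  ev3 <- evaluate_relations(gold, gold[0, ], ontology = ont)
  expect_equal(ev3$counts$precision, 0)
  expect_equal(ev3$counts$recall, 0)
  expect_true(ev3$counts$degenerate)
})

test_that("gold scored against itself is perfect on random corpora", {
  ont <- test_ontology()
  for (seed in 1:100) {
    co <- generate_fixture_corpus(seed = seed, n_docs = 2)
    gold_u <- unique_relations(co, ontology = ont)
    ev <- evaluate_relations(gold_u, gold_u, ontology = ont)
    if (nrow(gold_u) == 0) {
      # corpora whose planted units are all distractors have no gold
      # relations; self-evaluation is vacuous (degenerate zero counts)
      expect_equal(ev$counts$tp + ev$counts$fp + ev$counts$fn, 0)
      next
    }
    expect_equal(ev$counts$precision, 100)
    expect_equal(ev$counts$recall, 100)
    expect_equal(ev$counts$f_measure, 100)
  }
})

test_that("a non-matching prediction lowers precision, never recall", {
  ont <- test_ontology()
  gold <- dplyr::bind_rows(nrel("d", "P07225", "GO:0005886"))
  pred <- gold
  before <- evaluate_relations(gold, pred, ontology = ont)$counts
  pred2 <- dplyr::bind_rows(pred, nrel("d", "P17302", "GO:0005739"))
  after <- evaluate_relations(gold, pred2, ontology = ont)$counts
  expect_lt(after$precision, before$precision)
  expect_equal(after$recall, before$recall)
})

test_that("precision/recall/F agree with a from-scratch oracle", {
  set.seed(123)
  for (i in 1:1000) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    got <- prf(tp, fp, fn)
    p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(got$precision, p)
    expect_equal(got$recall, r)
    expect_equal(got$f_measure, f)
  }
  expect_equal(unlist(prf(1, 0, 0)[, c("precision", "recall",
                                       "f_measure")]),
               c(precision = 100, recall = 100, f_measure = 100))
})

test_that("entity evaluation requires span overlap and id compatibility", {
  ont <- test_ontology()
  gold <- tibble::tibble(
    doc_id = "d", entity_id = c("T1", "T2"),
    class = c("location", "location"),
    start = c(0L, 50L), end = c(10L, 60L), surface = "x",
    norm_ids = list("GO:0005886", "GO:0005634"))
  # exact span + exact id; overlapping span + descendant id
  pred_good <- tibble::tibble(
    doc_id = "d", entity_id = c("N1", "N2"),
    class = c("location", "location"),
    start = c(0L, 55L), end = c(10L, 65L), surface = "x",
    norm_ids = list("GO:0005886", "GO:0005634"))
  tot <- evaluate_ner(gold, pred_good, ontology = ont)
  loc <- tot[tot$class == "location", ]
  expect_equal(loc$tp, 2)
  expect_equal(loc$fp, 0)
  expect_equal(loc$fn, 0)
  # overlapping span but wrong GO branch: fp + fn
  pred_bad <- pred_good
  pred_bad$norm_ids <- list("GO:0005739", "GO:0005739")
  tot2 <- evaluate_ner(gold, pred_bad, ontology = ont)
  loc2 <- tot2[tot2$class == "location", ]
  expect_equal(loc2$tp, 0)
  expect_equal(loc2$fp, 2)
  expect_equal(loc2$fn, 2)
  # child GO id on an overlapping span is a tp
  pred_child <- gold[1, ]
  pred_child$norm_ids <- list("GO:0016328")
  loc3 <- evaluate_ner(gold[1, ], pred_child, ontology = ont)
  expect_equal(loc3$tp[loc3$class == "location"], 1)
  # disjoint span never matches
  pred_far <- gold[1, ]
  pred_far$start <- 90L; pred_far$end <- 99L
  loc4 <- evaluate_ner(gold[1, ], pred_far, ontology = ont)
  expect_equal(loc4$tp[loc4$class == "location"], 0)
  # totals pool the classes
  expect_equal(tot$tp[tot$class == "total"], sum(tot$tp[tot$class !=
                                                          "total"]))
})

test_that("bootstrap spread follows the printed formula", {
  # hand oracle: replicates [1, 2, 3] around overall 2
  expect_equal(locrex:::eq1_sigma(c(1, 2, 3), 2), 1)
  expect_equal(1 / sqrt(3), 0.5774, tolerance = 1e-4)

  # all replicates equal to the overall value -> zero error
  units <- tibble::tibble(tp = rep(1, 10), fp = 0, fn = 0)
  bs <- bootstrap_stderr(units, function(u) {
    prf(sum(u$tp), sum(u$fp), sum(u$fn))$precision
  }, n = 50, fraction = 0.5, seed = 3)
  expect_equal(bs$stderr, 0)
  expect_equal(bs$overall, 100)

  # determinism
  units2 <- tibble::tibble(tp = rep(c(1, 0), 10), fp = rep(c(0, 1), 10),
                           fn = 0)
  s1 <- bootstrap_stderr(units2, function(u) {
    prf(sum(u$tp), sum(u$fp), sum(u$fn))$precision
  }, n = 100, seed = 7)
  s2 <- bootstrap_stderr(units2, function(u) {
    prf(sum(u$tp), sum(u$fp), sum(u$fn))$precision
  }, n = 100, seed = 7)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$stderr, s2$stderr)

  # with the sample mean substituted for the overall value, the formula
  # reduces to the classic standard error of the mean
  x <- c(2.3, 4.1, 0.5, 3.3, 5.9, 1.1)
  expect_equal(locrex:::eq1_sigma(x, mean(x)) / sqrt(length(x)),
               stats::sd(x) / sqrt(length(x)))
})
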