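# reference tokenizer: explicit per-character class walk
reference_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  cls <- ifelse(grepl("[A-Za-z]", chars), "L",
                ifelse(grepl("[0-9]", chars), "D",
                       ifelse(grepl("\\s", chars), "S", "O")))
  out <- character(); buf <- ""; prev <- ""
  for (i in seq_along(chars)) {
    if (cls[i] == "S") {
      if (nzchar(buf)) out <- c(out, buf)
      buf <- ""; prev <- ""
    } else if (cls[i] == "O") {
      if (nzchar(buf)) out <- c(out, buf)
      out <- c(out, chars[i]); buf <- ""; prev <- ""
    } else if (cls[i] == prev) {
      buf <- paste0(buf, chars[i])
    } else {
      if (nzchar(buf)) out <- c(out, buf)
      buf <- chars[i]; prev <- cls[i]
    }
  }
  if (nzchar(buf)) out <- c(out, buf)
  out
}

test_that("tokenizer splits letter/digit boundaries", {
  expect_equal(lx_tokenize("P53")$token, c("P", "53"))
  expect_equal(nrow(lx_tokenize("")), 0L)
  expect_equal(lx_tokenize("GFP-tagged2")$token,
               c("GFP", "-", "tagged", "2"))
  texts <- c("IL-2R alpha3", "a1b2c3", "x  y\tz", "...", "Na+/K+-ATPase")
  for (t in texts) {
    expect_equal(lx_tokenize(t)$token, reference_tokenize(t), info = t)
  }
  # offsets slice back to the token
  tk <- lx_tokenize("Na+/K+-ATPase p53")
  expect_equal(substr(rep("Na+/K+-ATPase p53", nrow(tk)),
                      tk$start + 1, tk$end), tk$token)
})

test_that("linear n-grams trace the tokens between the pair", {
  co <- tiny_corpus()
  cand <- generate_candidates(co, 0)
  res <- fitted_resources(co, cand)
  fv <- featurize(cand[1, ], co, res)
  expect_true("lin|lem|3|SOURCE|be|localize" %in% names(fv))
  expect_true("lin|lem|3|to|the|TARGET" %in% names(fv))
  expect_true("lin|lem|1|localize" %in% names(fv))
  expect_false(any(grepl("lin\\|lem\\|1\\|SOURCE", names(fv))))
  expect_true("lin|pos|2|SOURCE|AUX" %in% names(fv))
  # dependency path SOURCE -> localized -> to -> TARGET
  expect_true("dep|lem|3|SOURCE|localize|to" %in% names(fv))
  expect_true("dep|edge|2|prep|pobj" %in% names(fv))
})

test_that("adjacent mentions yield only the SOURCE|TARGET bigram", {
  text <- "CAT2 tonoplast."
  co <- lx_corpus(
    documents = tibble::tibble(doc_id = "d", text = text),
    sentences = tibble::tibble(doc_id = "d", sent_idx = 1L, start = 0L,
                               end = nchar(text)),
    entities = tibble::tibble(
      doc_id = "d", entity_id = c("T1", "T2"),
      class = c("protein", "location"),
      start = c(0L, 5L), end = c(4L, 14L),
      surface = c("CAT2", "tonoplast"),
      norm_ids = list("P52569", "GO:0009705")),
    parses = tibble::tibble(
      doc_id = "d", sent_idx = 1L, token_idx = 1:3,
      surface = c("CAT2", "tonoplast", "."),
      lemma = c("cat2", "tonoplast", "."),
      pos = c("PROPN", "NOUN", "PUNCT"),
      head = c(2L, 2L, 2L), dep = c("compound", "ROOT", "punct"),
      start = c(0L, 5L, 14L), end = c(4L, 14L, 15L)))
  cand <- generate_candidates(co, 0, labeled = FALSE)
  res <- fitted_resources(co, cand)
  fv <- linear_ngrams(cand[1, ], co, res)
  lem <- grep("^lin\\|lem", names(fv), value = TRUE)
  expect_equal(lem, "lin|lem|2|SOURCE|TARGET")
})

test_that("numbers and third entities are masked in the gap", {
  text <- "AAA binds 42 CCC near the nucleus."
  co <- lx_corpus(
    documents = tibble::tibble(doc_id = "d", text = text),
    sentences = tibble::tibble(doc_id = "d", sent_idx = 1L, start = 0L,
                               end = nchar(text)),
    entities = tibble::tibble(
      doc_id = "d", entity_id = c("T1", "T2", "T3"),
      class = c("protein", "protein", "location"),
      start = c(0L, 13L, 26L), end = c(3L, 16L, 33L),
      surface = c("AAA", "CCC", "nucleus"),
      norm_ids = list("P04637", "P07225", "GO:0005634")),
    parses = tibble::tibble(
      doc_id = "d", sent_idx = 1L, token_idx = 1:8,
      surface = c("AAA", "binds", "42", "CCC", "near", "the", "nucleus",
                  "."),
      lemma = c("aaa", "bind", "42", "ccc", "near", "the", "nucleus", "."),
      pos = c("PROPN", "VERB", "NUM", "PROPN", "ADP", "DET", "NOUN",
              "PUNCT"),
      head = c(2L, 2L, 2L, 2L, 2L, 7L, 5L, 2L),
      dep = c("nsubj", "ROOT", "nummod", "dobj", "prep", "det", "pobj",
              "punct"),
      start = c(0L, 4L, 10L, 13L, 17L, 22L, 26L, 33L),
      end = c(3L, 9L, 12L, 16L, 21L, 25L, 33L, 34L)))
  cand <- generate_candidates(co, 0, labeled = FALSE)
  res <- fitted_resources(co, cand)
  # the (AAA, nucleus) pair has gap: binds 42 CCC near the
  row <- cand[cand$protein_id == "T1", ]
  fv <- linear_ngrams(row, co, res)
  expect_true("lin|lem|1|NUM" %in% names(fv))
  expect_true("lin|lem|1|PROTEIN" %in% names(fv))
  expect_false("lin|lem|1|ccc" %in% names(fv))
  # masking totality: every unit is one of mask/lemma, never empty
  units <- unlist(strsplit(sub("^lin\\|lem\\|[0-9]\\|", "",
                               grep("^lin\\|lem", names(fv), value = TRUE)),
                           "|", fixed = TRUE))
  expect_true(all(nzchar(units)))
})

test_that("shortest dependency path matches an independent oracle", {
  # deterministic small chains first
  chain <- random_tree_parse(3)
  chain$head <- c(1L, 1L, 2L)  # A -> B -> C
  expect_equal(dep_path(chain, 1L, 3L), c(1L, 2L, 3L))
  expect_equal(dep_path(chain, 3L, 1L), c(3L, 2L, 1L))
  expect_equal(dep_path(chain, 2L, 2L), 2L)

  set.seed(42)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    parse <- random_tree_parse(n)
    ends <- sample.int(n, 2)
    got <- dep_path(parse, ends[1], ends[2])
    oracle <- igraph_path_oracle(parse, ends[1], ends[2])
    expect_identical(got, oracle)
  }
})

test_that("dependency-path features ignore traversal direction", {
  co <- generate_fixture_corpus(seed = 17, n_docs = 4)
  cand <- generate_candidates(co, 0)
  res_lin <- fitted_resources(co, cand, mask_mode = "linear")
  res_role <- fitted_resources(co, cand, mask_mode = "role")
  # a "destination of" template has the location left of the protein:
  # linear mode masks location as SOURCE, role mode masks protein as
  # SOURCE. The two orientations traverse the same undirected path, so
  # the feature sets must coincide after swapping SOURCE and TARGET and
  # reversing each n-gram.
  swap_rev <- function(nms) {
    vapply(nms, function(nm) {
      parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
      content <- rev(parts[-(1:3)])
      content[content == "SOURCE"] <- ".swap."
      content[content == "TARGET"] <- "SOURCE"
      content[content == ".swap."] <- "TARGET"
      paste(c(parts[1:3], content), collapse = "|")
    }, character(1), USE.NAMES = FALSE)
  }
  found_reversed <- FALSE
  for (i in seq_len(nrow(cand))) {
    a <- dep_path_ngrams(cand[i, ], co, res_lin)
    b <- dep_path_ngrams(cand[i, ], co, res_role)
    ents <- co$entities[co$entities$doc_id == cand$doc_id[i], ]
    p <- ents[ents$entity_id == cand$protein_id[i], ]
    l <- ents[ents$entity_id == cand$location_id[i], ]
    if (p$start > l$start) {
      found_reversed <- TRUE
      # same path walked in opposite directions
      sw <- sort(unname(swap_rev(names(a))))
      expect_equal(sw, sort(names(b)))
    } else {
      expect_equal(sort(names(a)), sort(names(b)))
    }
  }
  expect_true(found_reversed)
})

test_that("entity counts scale by the training maximum", {
  co <- tiny_corpus()
  cand <- generate_candidates(co, 0)
  scaler <- fit_count_scaler(cand, co, "pair")
  # tiny corpus sentence 1 has 1 protein + 1 location
  expect_equal(unname(unclass(scaler)["cnt|sent|1|protloc"]), 2)
  res <- fitted_resources(co, cand)
  v <- entity_count_features(cand[1, ], co, res)
  expect_equal(unname(v["cnt|sent|1|protloc"]), 1.0)
  # a count above the training maximum scales above 1 (max 10 -> 11/10)
  res$scaler <- structure(c("cnt|sent|1|protloc" = 10,
                            "cnt|sent|1|total" = 10),
                          class = "lx_count_scaler")
  v2 <- entity_count_features(cand[1, ], co, res)
  expect_equal(unname(v2["cnt|sent|1|protloc"]), 2 / 10)
  fake <- c("cnt|sent|1|protloc" = 11, "cnt|sent|1|total" = 11)
  expect_equal(unname(fake / unclass(res$scaler)), c(1.1, 1.1))
})

test_that("marker and annotation-table features fire as specified", {
  text <- "GFP accumulates in the tonoplast. VAC8 sits in the tonoplast."
  co <- lx_corpus(
    documents = tibble::tibble(doc_id = "d", text = text),
    sentences = tibble::tibble(doc_id = "d", sent_idx = 1:2,
                               start = c(0L, 34L), end = c(33L, 61L)),
    entities = tibble::tibble(
      doc_id = "d", entity_id = c("T1", "T2", "T3", "T4"),
      class = c("protein", "location", "protein", "location"),
      start = c(0L, 23L, 34L, 51L), end = c(3L, 32L, 38L, 60L),
      surface = c("GFP", "tonoplast", "VAC8", "tonoplast"),
      norm_ids = list("P42212", "GO:0009705", "P39968", "GO:0009705")))
  cand <- generate_candidates(co, 0, labeled = FALSE)
  res <- fitted_resources(co, cand)
  gfp_row <- cand[cand$protein_id == "T1", ]
  vac_row <- cand[cand$protein_id == "T3", ]
  expect_equal(unname(marker_feature(gfp_row, co, res)), 1)
  expect_length(marker_feature(vac_row, co, res), 0L)
  # long-form marker name matches after tokenization, case-insensitively
  res2 <- res
  res2$markers <- c("green fluorescent protein")
  co2 <- co
  co2$entities$surface[1] <- "GFP"
  expect_length(marker_feature(gfp_row, co2, res2), 0L)

  # VAC8 is tabled at vacuole (GO:0005773); tonoplast is a descendant
  expect_equal(unname(swissprot_feature(vac_row, co, res)), 1)
  # GFP (P42212) has no annotation
  expect_length(swissprot_feature(gfp_row, co, res), 0L)
})

test_that("featurize is pure and degrades without a parse", {
  co <- generate_fixture_corpus(seed = 19, n_docs = 3)
  cand <- generate_candidates(co, 0)
  res <- fitted_resources(co, cand)
  a <- featurize(cand[1, ], co, res)
  b <- featurize(cand[1, ], co, res)
  expect_identical(a, b)
  expect_false(attr(a, "degraded"))
  expect_true(all(unlist(a) != 0))

  bare <- co
  bare$parses <- bare$parses[0, ]
  resb <- fitted_resources(bare, cand)
  fv <- featurize(cand[1, ], bare, resb)
  expect_true(attr(fv, "degraded"))
  expect_false(any(grepl("^dep\\|", names(fv))))
  expect_true(any(grepl("^lin\\|lem", names(fv))))
})

test_that("L1 selection keeps separating features and sparsifies as C drops", {
  set.seed(7)
  n <- 80
  y <- rep(c("related", "unrelated"), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("noise", 1:20)))
  X <- cbind(X, signal = ifelse(y == "related", 1, 0))
  sel <- select_features_l1(X, y, C = 2)
  expect_true("signal" %in% sel$kept)
  # C -> 0: regularization dominates, kept set (near) empty
  sel0 <- select_features_l1(X, y, C = 1e-4)
  expect_lte(length(sel0$kept), 1L)
  # kept-set size non-decreasing over an order-of-magnitude C grid
  sizes <- vapply(c(0.01, 0.1, 1, 10), function(C) {
    length(select_features_l1(X, y, C = C)$kept)
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(select_features_l1(X, rep("related", n), C = 2),
               regexp = "both classes")
})
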