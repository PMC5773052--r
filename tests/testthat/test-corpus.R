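test_that("corpus container round-trips through the JSON format", {
  co <- generate_fixture_corpus(seed = 11, n_docs = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(co, path)
  co2 <- read_corpus(path)
  for (part in c("documents", "sentences", "entities", "relations",
                 "parses")) {
    expect_equal(as.data.frame(co2[[part]]), as.data.frame(co[[part]]),
                 info = part)
  }
  expect_equal(co2$provenance, co$provenance)

  # empty corpus round-trips too
  empty <- lx_corpus(documents = tibble::tibble(doc_id = character(),
                                                text = character()))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_corpus(empty, p2)
  expect_equal(nrow(read_corpus(p2)$documents), 0L)
})

test_that("offset/surface mismatches are integrity errors naming the entity", {
  expect_error(
    lx_corpus(
      documents = tibble::tibble(doc_id = "d1", text = "CAT2 binds."),
      sentences = tibble::tibble(doc_id = "d1", sent_idx = 1L,
                                 start = 0L, end = 11L),
      entities = tibble::tibble(doc_id = "d1", entity_id = "T1",
                                class = "protein", start = 0L, end = 4L,
                                surface = "CAT9", norm_ids = list("P52569"))),
    regexp = "integrity error.*T1")
  expect_error(
    lx_corpus(
      documents = tibble::tibble(doc_id = "d1", text = "short"),
      entities = tibble::tibble(doc_id = "d1", entity_id = "T1",
                                class = "protein", start = 2L, end = 99L,
                                surface = "x", norm_ids = list(character()))),
    regexp = "integrity error")
})

test_that("malformed normalization ids are pruned on read with a warning", {
  co <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(co, path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw$documents[[1]]$entities[[2]]$norm_ids <- list("GO:0009705", "GO:bad")
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  expect_warning(co2 <- read_corpus(path), regexp = "pruned.*GO:bad")
  expect_equal(co2$entities$norm_ids[[2]], "GO:0009705")
})

test_that("fixture generation is deterministic and seed-sensitive", {
  a <- generate_fixture_corpus(seed = 5, n_docs = 6)
  b <- generate_fixture_corpus(seed = 5, n_docs = 6)
  c <- generate_fixture_corpus(seed = 6, n_docs = 6)
  expect_identical(a$documents, b$documents)
  expect_identical(a$entities, b$entities)
  expect_identical(a$relations, b$relations)
  expect_false(identical(a$documents$text, c$documents$text))
})

test_that("distance mix of planted relations matches the request", {
  co <- generate_fixture_corpus(seed = 2, n_docs = 10,
                                distance_mix = c(D0 = 1.0),
                                negative_rate = 0.3)
  d <- vapply(seq_len(nrow(co$relations)), function(i) {
    sentence_distance(co, co$relations$doc_id[i],
                      co$relations$protein_id[i],
                      co$relations$location_id[i])
  }, integer(1))
  expect_true(all(d == 0L))

  mix <- c(D0 = 0.66, D1 = 0.15, D2 = 0.19)
  co2 <- generate_fixture_corpus(seed = 3, n_docs = 120,
                                 distance_mix = mix, negative_rate = 0)
  d2 <- vapply(seq_len(nrow(co2$relations)), function(i) {
    sentence_distance(co2, co2$relations$doc_id[i],
                      co2$relations$protein_id[i],
                      co2$relations$location_id[i])
  }, integer(1))
  n <- length(d2)
  emp <- c(mean(d2 == 0), mean(d2 == 1), mean(d2 == 2))
  # each fraction within ~4 binomial standard errors of the requested mix
  tol <- 4 * sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(emp - mix) < tol))
})

test_that("entity and relation counts are reported per class", {
  empty <- lx_corpus(documents = tibble::tibble(doc_id = character(),
                                                text = character()))
  expect_equal(unlist(stats_entities(empty)),
               c(protein = 0L, location = 0L, organism = 0L,
                 relations = 0L))
  co <- tiny_corpus()
  s <- stats_entities(co)
  expect_equal(s$protein, 2L)
  expect_equal(s$location, 1L)
  expect_equal(s$organism, 0L)
  expect_equal(s$relations, 1L)
})

test_that("sentence spans straddled by an entity are merged", {
  # sentence splitter wrongly cut inside the entity span [10, 21)
  expect_message(
    co <- lx_corpus(
      documents = tibble::tibble(doc_id = "d1",
                                 text = "Protein in S. cerevisiae cells."),
      sentences = tibble::tibble(doc_id = "d1", sent_idx = 1:2,
                                 start = c(0L, 14L), end = c(13L, 31L)),
      entities = tibble::tibble(doc_id = "d1", entity_id = "T1",
                                class = "organism", start = 11L, end = 24L,
                                surface = "S. cerevisiae",
                                norm_ids = list("4932"))),
    regexp = "merged")
  expect_equal(nrow(co$sentences), 1L)
  expect_equal(co$sentences$end, 31L)
})

test_that("relations must reference in-document entities of the right class", {
  co <- tiny_corpus()
  bad <- co$relations
  bad$location_id <- "T9"
  expect_error(
    lx_corpus(documents = co$documents, sentences = co$sentences,
              entities = co$entities, relations = bad, parses = co$parses),
    regexp = "unknown entity")
  swapped <- tibble::tibble(doc_id = "d1", protein_id = "T2",
                            location_id = "T1")
  expect_error(
    lx_corpus(documents = co$documents, sentences = co$sentences,
              entities = co$entities, relations = swapped,
              parses = co$parses),
    regexp = "protein")
})
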