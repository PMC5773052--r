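test_that("OBO reading loads terms and edges, skipping obsolete ones", {
  expect_warning(ont <- read_obo(system.file("extdata", "cc_fixture.obo",
                                             package = "locrex")),
                 regexp = "obsolete")
  expect_gt(nrow(ont$terms), 20)
  expect_false("GO:0008372" %in% ont$terms$go_id)
  expect_true(all(c("is_a", "part_of") %in% ont$edges$rel))
})

test_that("cyclic ontologies are rejected", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000001", "name: a", "is_a: GO:0000002",
               "", "[Term]", "id: GO:0000002", "name: b",
               "is_a: GO:0000001"), path)
  expect_error(read_obo(path), regexp = "cycle")
})

test_that("descendant test is reflexive, transitive, and sibling-safe", {
  ont <- test_ontology()
  expect_true(go_is_descendant(ont, "GO:0005886", "GO:0005886"))
  # grandchild via part_of + is_a chain: tonoplast -> vacuolar membrane
  # -> vacuole
  expect_true(go_is_descendant(ont, "GO:0009705", "GO:0005773"))
  expect_true(go_is_descendant(ont, "GO:0016328", "GO:0016020"))
  expect_false(go_is_descendant(ont, "GO:0005634", "GO:0005739"))
  expect_false(go_is_descendant(ont, "GO:0005773", "GO:0009705"))
})

test_that("descendant closure agrees with a graph-reachability oracle", {
  ont <- test_ontology()
  g <- igraph::graph_from_data_frame(ont$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = ont$terms$go_id)
  ids <- ont$terms$go_id
  for (anc in ids) {
    reach <- names(igraph::subcomponent(g, anc, mode = "in"))
    got <- ids[go_is_descendant(ont, ids, anc)]
    expect_setequal(got, reach)
  }
})

rel_corpus <- function(entities, relations, text_len = 200L) {
  text <- paste(rep("x", text_len), collapse = "")
  n_sent <- 4L
  bounds <- seq(0L, text_len, length.out = n_sent + 1L)
  lx_corpus(
    documents = tibble::tibble(doc_id = "d", text = text),
    sentences = tibble::tibble(doc_id = "d", sent_idx = seq_len(n_sent),
                               start = as.integer(bounds[-(n_sent + 1)]),
                               end = as.integer(bounds[-1])),
    entities = entities, relations = relations)
}

test_that("unique relations collapse repeated and synonymous mentions", {
  ont <- test_ontology()
  ents <- tibble::tibble(
    doc_id = "d", entity_id = paste0("T", 1:4),
    class = c("protein", "location", "protein", "location"),
    start = c(0L, 10L, 60L, 70L), end = c(4L, 14L, 64L, 74L),
    surface = "xxxx",
    norm_ids = list("P52569", "GO:0009705", "P52569", "GO:0009705"))
  rels <- tibble::tibble(doc_id = "d", protein_id = c("T1", "T3"),
                         location_id = c("T2", "T4"))
  co <- rel_corpus(ents, rels)
  u <- unique_relations(co, ontology = ont)
  expect_equal(nrow(u), 1L)
  expect_equal(u$n_supports, 2L)
  expect_equal(u$min_distance, 0L)
})

test_that("hierarchy collapsing keeps the most specific term per protein", {
  ont <- test_ontology()
  ents <- tibble::tibble(
    doc_id = "d", entity_id = paste0("T", 1:4),
    class = c("protein", "location", "protein", "location"),
    start = c(0L, 10L, 60L, 70L), end = c(4L, 14L, 64L, 74L),
    surface = "xxxx",
    norm_ids = list("P07225", "GO:0005886", "P07225", "GO:0016328"))
  rels <- tibble::tibble(doc_id = "d", protein_id = c("T1", "T3"),
                         location_id = c("T2", "T4"))
  co <- rel_corpus(ents, rels)
  collapsed <- unique_relations(co, ontology = ont)
  expect_equal(collapsed$go_id, "GO:0016328")
  flat <- unique_relations(co, collapse_hierarchy = FALSE)
  expect_setequal(flat$go_id, c("GO:0005886", "GO:0016328"))

  # collapsing never increases the count; edgeless ontology is identity
  empty_ont <- new_ontology(ont$terms,
                            ont$edges[0, ])
  expect_equal(unique_relations(co, ontology = empty_ont),
               flat)
  expect_lte(nrow(collapsed), nrow(flat))
})

test_that("unique relations are idempotent and order-independent", {
  ont <- test_ontology()
  co <- generate_fixture_corpus(seed = 53, n_docs = 8)
  u1 <- unique_relations(co, ontology = ont)
  shuffled <- co$relations[locrex:::with_seed(3,
                                              sample(nrow(co$relations))), ]
  u2 <- unique_relations(co, relations = shuffled, ontology = ont)
  expect_equal(u2, u1)
  # feeding the unique set's supports back in reproduces the set
  again <- unique_relations(
    co, relations = dplyr::bind_rows(u1$supports) |>
      dplyr::mutate(doc_id = rep(u1$doc_id, vapply(u1$supports, nrow,
                                                   integer(1)))),
    ontology = ont)
  expect_equal(again[, c("doc_id", "uniprot_ac", "go_id")],
               u1[, c("doc_id", "uniprot_ac", "go_id")])
})

test_that("distance histogram fractions sum to one", {
  ont <- test_ontology()
  co <- generate_fixture_corpus(seed = 59, n_docs = 10,
                                distance_mix = c(D0 = 1.0))
  h <- distance_histogram(co, ontology = ont)
  expect_equal(h$distance, 0L)
  expect_equal(h$fraction, 1.0)
  co2 <- generate_fixture_corpus(seed = 59, n_docs = 20)
  h2 <- distance_histogram(co2, ontology = ont)
  expect_equal(sum(h2$fraction), 1, tolerance = 1e-9)
  h3 <- distance_histogram(co2, collapse_hierarchy = FALSE)
  expect_equal(sum(h3$fraction), 1, tolerance = 1e-9)
})

test_that("recall ceilings follow the harmonic-mean arithmetic", {
  h <- tibble::tibble(distance = c(0L, 1L), fraction = c(0.74, 0.26))
  rc <- recall_ceiling(h, 0)
  expect_equal(rc$max_recall, 74)
  expect_equal(round(rc$max_f), 85)
  rc2 <- recall_ceiling(tibble::tibble(distance = 0L, fraction = 1),
                        0)
  expect_equal(rc2$max_recall, 100)
  expect_equal(rc2$max_f, 100)
  h3 <- tibble::tibble(distance = c(0L, 1L, 2L),
                       fraction = c(0.74, 0.15, 0.11))
  rc3 <- recall_ceiling(h3, 1)
  expect_equal(rc3$max_recall, 89)
  expect_equal(round(rc3$max_f), 94)
})
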