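# Hand-built fixtures shared across test files. Everything is constructed
# in code; nothing is read from outside the package.

# One document, two sentences, with a known parse for sentence 1:
#   "CAT2 is localized to the tonoplast. PROS1 was seen."
tiny_corpus <- function() {
  text <- "CAT2 is localized to the tonoplast. PROS1 was seen."
  parse1 <- tibble::tibble(
    doc_id = "d1", sent_idx = 1L, token_idx = 1:7,
    surface = c("CAT2", "is", "localized", "to", "the", "tonoplast", "."),
    lemma = c("cat2", "be", "localize", "to", "the", "tonoplast", "."),
    pos = c("PROPN", "AUX", "VERB", "ADP", "DET", "NOUN", "PUNCT"),
    head = c(3L, 3L, 3L, 3L, 6L, 4L, 3L),
    dep = c("nsubjpass", "auxpass", "ROOT", "prep", "det", "pobj", "punct"),
    start = c(0L, 5L, 8L, 18L, 21L, 25L, 34L),
    end = c(4L, 7L, 17L, 20L, 24L, 34L, 35L))
  lx_corpus(
    documents = tibble::tibble(doc_id = "d1", text = text),
    sentences = tibble::tibble(doc_id = "d1", sent_idx = 1:2,
                               start = c(0L, 36L), end = c(35L, 51L)),
    entities = tibble::tibble(
      doc_id = "d1",
      entity_id = c("T1", "T2", "T3"),
      class = c("protein", "location", "protein"),
      start = c(0L, 25L, 36L), end = c(4L, 34L, 41L),
      surface = c("CAT2", "tonoplast", "PROS1"),
      norm_ids = list("P52569", "GO:0009705", "P07225")),
    relations = tibble::tibble(doc_id = "d1", protein_id = "T1",
                               location_id = "T2"),
    parses = parse1)
}

# A random dependency tree over n tokens (token i > 1 attaches to a random
# earlier token; token 1 is the root), as a minimal parse tibble.
random_tree_parse <- function(n) {
  head <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  tibble::tibble(
    doc_id = "t", sent_idx = 1L, token_idx = seq_len(n),
    surface = paste0("w", seq_len(n)), lemma = paste0("w", seq_len(n)),
    pos = "X", head = head, dep = "dep",
    start = (seq_len(n) - 1L) * 3L, end = (seq_len(n) - 1L) * 3L + 2L)
}

# Independent shortest-path oracle over the same tree, via igraph.
igraph_path_oracle <- function(parse, from, to) {
  edges <- parse[parse$head != parse$token_idx, c("token_idx", "head")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = parse$token_idx)
  p <- igraph::shortest_paths(g, from = as.character(from),
                              to = as.character(to))$vpath[[1]]
  as.integer(names(p))
}

test_ontology <- function() fixture_ontology()

fitted_resources <- function(corpus, candidates,
                             ontology = test_ontology(), ...) {
  res <- feature_resources(ontology = ontology, ...)
  res$scaler <- fit_count_scaler(candidates, corpus, res$count_mode)
  res
}
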