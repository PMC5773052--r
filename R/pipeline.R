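#' End-to-end extraction on a corpus
#'
#' The full pipeline from text to curator-facing annotations: obtain
#' entities (gold annotations, the built-in dictionary tagger, or a
#' caller-supplied entity table), generate same-sentence candidate pairs,
#' classify them with a trained model (or the co-mention baseline),
#' collapse predictions into document-level unique normalized relations,
#' and attach the supporting source sentences. Every extracted relation is
#' linked to at least one source sentence — the curation requirement that
#' separates text-mined suggestions from unreviewable guesses.
#'
#' @param corpus An `lx_corpus` (for raw text, build one with a single
#'   `documents` table and sentence spans, or use [tag_corpus()]).
#' @param model An `lx_model`, or `NULL` to use the co-mention baseline.
#' @param entities `"gold"` (use the corpus entity table), `"tagger"`
#'   (run [tag_corpus()] with `tagger_cfg`, then [filter_locations()]), or
#'   an entity tibble to substitute.
#' @param ontology An `lx_ontology`.
#' @param tagger_cfg A [tagger_config()] (for `entities = "tagger"`).
#' @param filter_policy A [go_filter_policy()] applied to tagged locations.
#' @param max_distance Candidate sentence-distance cap.
#' @param collapse_hierarchy Collapse GO-ancestor duplicates.
#' @return A tibble of extracted annotations: `doc_id`, `uniprot_ac`,
#'   `go_id`, `n_supports`, `min_distance`, `source_sentences` (supporting
#'   sentence texts, collapsed with `" | "`).
#' @export
extract_relations <- function(corpus, model = NULL, entities = "gold",
                              ontology = NULL,
                              tagger_cfg = tagger_config(),
                              filter_policy = go_filter_policy(),
                              max_distance = 0,
                              collapse_hierarchy = TRUE) {
  work <- corpus
  if (is.character(entities) && length(entities) == 1) {
    if (entities == "tagger") {
      work <- tag_corpus(corpus, tagger_cfg)
      work$entities <- filter_locations(work$entities, ontology,
                                        filter_policy)
    } else if (entities != "gold") {
      abort("entities must be \"gold\", \"tagger\", or an entity tibble")
    }
  } else {
    work <- lx_corpus(documents = corpus$documents,
                      sentences = corpus$sentences,
                      entities = entities, relations = NULL,
                      parses = corpus$parses,
                      provenance = corpus$provenance)
  }
  cand <- generate_candidates(work, max_distance, labeled = FALSE)
  if (is.null(model)) {
    pred_rel <- cand
    pred_rel$predicted <- "related"
  } else {
    pred <- predict_relations(model, cand, work)
    pred_rel <- pred[pred$predicted == "related", , drop = FALSE]
  }
  uniq <- unique_relations(work,
                           relations = pred_rel[, c("doc_id", "protein_id",
                                                    "location_id")],
                           collapse_hierarchy = collapse_hierarchy,
                           ontology = ontology)
  if (nrow(uniq) == 0) {
    uniq$source_sentences <- character(0)
    return(uniq)
  }
  uniq$source_sentences <- map_chr(seq_len(nrow(uniq)), function(i) {
    sup <- uniq$supports[[i]]
    doc <- uniq$doc_id[i]
    text <- work$documents$text[work$documents$doc_id == doc]
    sents <- unique(unlist(map(seq_len(nrow(sup)), function(j) {
      c(entity_sentence_index(work, doc, sup$protein_id[j]),
        entity_sentence_index(work, doc, sup$location_id[j]))
    })))
    spans <- work$sentences[work$sentences$doc_id == doc &
                              work$sentences$sent_idx %in% sents, ,
                            drop = FALSE]
    paste(slice_text(text, spans$start, spans$end), collapse = " | ")
  })
  uniq
}

#' Write extracted annotations as a curator-facing TSV
#'
#' @param annotations Tibble from [extract_relations()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- annotations[, c("doc_id", "uniprot_ac", "go_id", "n_supports",
                         "min_distance", "source_sentences")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable provenance record for a run
#'
#' @param path Output JSON path.
#' @param config Named list of run parameters (must include any seed).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config) {
  rec <- list(package = "locrex",
              version = as.character(utils::packageVersion("locrex")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a minimal corpus from raw text
#'
#' Convenience for the predict path: wraps plain abstracts into an
#' `lx_corpus` with naive sentence splitting (at `.`, `!`, `?` followed by
#' whitespace and an upper-case letter or digit). No entities, relations
#' or parses are attached; spans straddled by later-added entities are
#' merged by the corpus constructor.
#'
#' @param texts Character vector of documents.
#' @param doc_ids Optional ids (default `doc1`, `doc2`, ...).
#' @return An `lx_corpus`.
#' @export
corpus_from_texts <- function(texts, doc_ids = NULL) {
  doc_ids <- doc_ids %||% paste0("doc", seq_along(texts))
  sent_rows <- bind_rows(map2(texts, doc_ids, function(text, id) {
    bounds <- gregexpr("[.!?](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
    cuts <- if (bounds[1] == -1L) integer() else as.integer(bounds)
    starts <- c(0L, cuts)
    ends <- c(cuts, nchar(text))
    # trim leading whitespace of each span
    for (k in seq_along(starts)) {
      while (starts[k] < ends[k] &&
               grepl("^\\s", substr(text, starts[k] + 1, starts[k] + 1))) {
        starts[k] <- starts[k] + 1L
      }
    }
    keep <- starts < ends
    tibble(doc_id = id, sent_idx = seq_len(sum(keep)),
           start = starts[keep], end = ends[keep])
  }))
  lx_corpus(documents = tibble(doc_id = doc_ids, text = texts),
            sentences = sent_rows)
}
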