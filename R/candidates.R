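#' Sentence distance between two entity mentions
#'
#' The number of sentences separating two mentions: 0 when both lie in the
#' same sentence (`D0`), 1 for adjacent sentences (`D1`), and so on.
#'
#' @param corpus An `lx_corpus`.
#' @param doc_id Document id.
#' @param entity_id1,entity_id2 Entity ids within that document.
#' @return Non-negative integer.
#' @export
sentence_distance <- function(corpus, doc_id, entity_id1, entity_id2) {
  i1 <- entity_sentence_index(corpus, doc_id, entity_id1)
  i2 <- entity_sentence_index(corpus, doc_id, entity_id2)
  abs(i1 - i2)
}

#' Generate labeled candidate instances
#'
#' Enumerates every (protein mention, location mention) pair within
#' `max_distance` sentences of each other — the binary-classification
#' instances of the relation extractor. With `labeled = TRUE` a pair is
#' `"related"` exactly when that mention pair (at exact character offsets)
#' is a gold relation; repeated attestations of the same normalized
#' relation at different offsets therefore yield distinct instances. Gold
#' relations at larger sentence distances yield no instance and become
#' irrecoverable false negatives at evaluation — the recall ceiling of a
#' same-sentence extractor. Duplicate pairs (from duplicated mention tags)
#' are collapsed; output is ordered by document, protein offset, location
#' offset.
#'
#' @param corpus An `lx_corpus`.
#' @param max_distance Maximum sentence distance, 0 or 1.
#' @param docs Optional character vector restricting to these `doc_id`s.
#' @param labeled Label pairs against the gold relation layer (default);
#'   with `FALSE` every instance gets label `"unknown"` (for tagged,
#'   unannotated text).
#' @return A tibble with one row per instance: `doc_id`, `protein_id`,
#'   `location_id`, `prot_start`, `loc_start`, `prot_sent`, `loc_sent`,
#'   `distance`, `label` (`"related"`, `"unrelated"` or `"unknown"`).
#' @export
generate_candidates <- function(corpus, max_distance = 0, docs = NULL,
                                labeled = TRUE) {
  stopifnot(inherits(corpus, "lx_corpus"), max_distance %in% c(0L, 1L))
  ents <- corpus$entities
  if (!is.null(docs)) ents <- ents[ents$doc_id %in% docs, , drop = FALSE]
  if (nrow(ents) == 0) return(empty_candidates())
  # sentence index per entity
  sent_idx <- integer(nrow(ents))
  for (i in seq_len(nrow(ents))) {
    s <- corpus$sentences[corpus$sentences$doc_id == ents$doc_id[i], ,
                          drop = FALSE]
    hit <- which(s$start <= ents$start[i] & ents$end[i] <= s$end)
    sent_idx[i] <- s$sent_idx[hit[1]]
  }
  ents$.sent <- sent_idx
  prot <- ents[ents$class == "protein", , drop = FALSE]
  loc <- ents[ents$class == "location", , drop = FALSE]
  if (nrow(prot) == 0 || nrow(loc) == 0) return(empty_candidates())

  pairs <- inner_join(
    select(prot, doc_id = "doc_id", protein_id = "entity_id",
           prot_start = "start", prot_sent = ".sent"),
    select(loc, doc_id = "doc_id", location_id = "entity_id",
           loc_start = "start", loc_sent = ".sent"),
    by = "doc_id", relationship = "many-to-many")
  pairs <- mutate(pairs, distance = abs(.data$prot_sent - .data$loc_sent))
  pairs <- filter(pairs, .data$distance <= max_distance)
  pairs <- distinct(pairs, .data$doc_id, .data$protein_id, .data$location_id,
                    .keep_all = TRUE)
  if (nrow(pairs) == 0) return(empty_candidates())

  if (labeled) {
    gold <- mutate(corpus$relations, .rel = TRUE)
    pairs <- left_join(pairs, gold,
                       by = c("doc_id", "protein_id", "location_id"))
    pairs$label <- ifelse(!is.na(pairs$.rel), "related", "unrelated")
    pairs$.rel <- NULL
  } else {
    pairs$label <- "unknown"
  }
  arrange(pairs, .data$doc_id, .data$prot_start, .data$loc_start)[
    , c("doc_id", "protein_id", "location_id", "prot_start", "loc_start",
        "prot_sent", "loc_sent", "distance", "label")]
}

empty_candidates <- function() {
  tibble(doc_id = character(), protein_id = character(),
         location_id = character(), prot_start = integer(),
         loc_start = integer(), prot_sent = integer(), loc_sent = integer(),
         distance = integer(), label = character())
}

#' Co-mention baseline predictions
#'
#' The heuristic competitor: every protein--location pair co-mentioned in
#' the same sentence is predicted to be a relation. Returns the same shape
#' as [predict_relations()] so it runs through the identical aggregation
#' and evaluation path as the learned extractor.
#'
#' @param corpus An `lx_corpus`.
#' @param docs Optional `doc_id` restriction.
#' @return A tibble of predicted mention-level relations: candidate columns
#'   plus `margin` (all `1`) and `predicted` (all `"related"`).
#' @export
baseline_predict <- function(corpus, docs = NULL) {
  cand <- generate_candidates(corpus, max_distance = 0, docs = docs,
                              labeled = FALSE)
  cand$margin <- 1
  cand$predicted <- "related"
  cand
}
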