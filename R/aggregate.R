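#' Collapse mention-level relations into unique normalized relations
#'
#' Reduces mention-level protein--location relations (gold annotations or
#' extractor predictions) to the document-level set of distinct normalized
#' pairs (UniProtKB accession, GO id) — the unit at which extraction is
#' evaluated and delivered to curators. Ambiguous mentions expand over all
#' their normalized ids; mentions with no id contribute nothing. Each
#' unique relation records its supporting mention pairs and the minimum
#' sentence distance among them (the easiest extractable evidence).
#'
#' With `collapse_hierarchy`, a relation whose GO term is a strict ancestor
#' of another retained relation's term for the same protein is dropped:
#' child identifiers are more exact than their parents, so the more
#' detailed annotation overshadows the less detailed one. With a flat
#' (edgeless) ontology this is the identity. Output order is deterministic
#' (`doc_id`, `uniprot_ac`, `go_id`); the result does not depend on input
#' order, and the operation is idempotent.
#'
#' @param corpus An `lx_corpus` supplying entities and sentence spans.
#' @param relations Mention-level relation tibble (`doc_id`, `protein_id`,
#'   `location_id`); defaults to the corpus gold relations.
#' @param collapse_hierarchy Drop strict-ancestor duplicates per protein
#'   (default `TRUE`).
#' @param ontology An `lx_ontology`; required when `collapse_hierarchy`.
#' @return A tibble: `doc_id`, `uniprot_ac`, `go_id`, `n_supports`,
#'   `min_distance`, `supports` (list-column of mention-pair tibbles).
#' @export
unique_relations <- function(corpus, relations = NULL,
                             collapse_hierarchy = TRUE, ontology = NULL) {
  stopifnot(inherits(corpus, "lx_corpus"))
  if (collapse_hierarchy && is.null(ontology)) {
    abort("collapse_hierarchy = TRUE requires an ontology")
  }
  relations <- relations %||% corpus$relations
  if (nrow(relations) == 0) {
    return(tibble(doc_id = character(), uniprot_ac = character(),
                  go_id = character(), n_supports = integer(),
                  min_distance = integer(), supports = list()))
  }
  ents <- corpus$entities
  ent_key <- paste(ents$doc_id, ents$entity_id)
  norm_of <- stats::setNames(ents$norm_ids, ent_key)

  expanded <- bind_rows(map(seq_len(nrow(relations)), function(i) {
    doc <- relations$doc_id[i]
    pid <- relations$protein_id[i]
    lid <- relations$location_id[i]
    acs <- norm_of[[paste(doc, pid)]]
    gos <- norm_of[[paste(doc, lid)]]
    if (length(acs) == 0 || length(gos) == 0) return(NULL)
    dist <- sentence_distance(corpus, doc, pid, lid)
    tidyr::expand_grid(uniprot_ac = acs, go_id = gos) |>
      mutate(doc_id = doc, protein_id = pid, location_id = lid,
             distance = dist)
  }))
  if (is.null(expanded) || nrow(expanded) == 0) {
    return(tibble(doc_id = character(), uniprot_ac = character(),
                  go_id = character(), n_supports = integer(),
                  min_distance = integer(), supports = list()))
  }
  out <- expanded |>
    group_by(.data$doc_id, .data$uniprot_ac, .data$go_id) |>
    summarise(
      n_supports = n(),
      min_distance = min(.data$distance),
      supports = list(tibble(protein_id = protein_id,
                             location_id = location_id,
                             distance = distance)),
      .groups = "drop")

  if (collapse_hierarchy && nrow(out) > 1) {
    drop <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      same <- which(out$doc_id == out$doc_id[i] &
                      out$uniprot_ac == out$uniprot_ac[i] &
                      out$go_id != out$go_id[i])
      # drop i if some sibling's GO term is a strict descendant of i's
      if (any(map_lgl(same, function(j) {
        go_is_descendant(ontology, out$go_id[j], out$go_id[i])
      }))) {
        drop[i] <- TRUE
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  arrange(out, .data$doc_id, .data$uniprot_ac, .data$go_id)
}

#' Sentence-distance histogram of unique relations
#'
#' The fraction of document-level unique normalized relations at each
#' sentence distance `Dn`, each relation contributing the minimum distance
#' among its supporting mention pairs. Collapsing the GO hierarchy first
#' shifts mass towards `D0`, because less specific duplicates annotated in
#' distant sentences are absorbed by their more specific same-sentence
#' versions.
#'
#' @inheritParams unique_relations
#' @param all_supports Count every supporting mention pair's distance
#'   instead of the per-relation minimum (default `FALSE`).
#' @return A tibble `distance`, `n`, `fraction`; fractions sum to 1.
#' @export
distance_histogram <- function(corpus, collapse_hierarchy = TRUE,
                               ontology = NULL, all_supports = FALSE) {
  uniq <- unique_relations(corpus, collapse_hierarchy = collapse_hierarchy,
                           ontology = ontology)
  if (nrow(uniq) == 0) {
    return(tibble(distance = integer(), n = integer(), fraction = double()))
  }
  d <- if (all_supports) {
    unlist(map(uniq$supports, function(s) s$distance))
  } else {
    uniq$min_distance
  }
  tb <- tibble(distance = as.integer(names(table(d))),
               n = as.integer(table(d)))
  tb$fraction <- tb$n / sum(tb$n)
  tb
}

#' Recall ceiling of a distance-limited extractor
#'
#' A method that only considers entity pairs up to `max_distance` sentences
#' apart can recall at most the cumulative fraction of unique relations at
#' those distances; at perfect precision its F-measure is the harmonic mean
#' of 100 and that ceiling.
#'
#' @param histogram A tibble as from [distance_histogram()].
#' @param max_distance Maximum sentence distance considered.
#' @return A one-row tibble: `max_recall`, `max_f` (percentages).
#' @export
recall_ceiling <- function(histogram, max_distance = 0) {
  stopifnot(all(c("distance", "fraction") %in% names(histogram)))
  r <- 100 * sum(histogram$fraction[histogram$distance <= max_distance])
  tibble(max_recall = r, max_f = f_measure(100, r))
}

#' Plot a sentence-distance histogram
#'
#' @param histogram A tibble as from [distance_histogram()].
#' @return A ggplot: fraction of unique relations per sentence distance.
#' @export
plot_distance_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$distance,
                                          levels = sort(unique(.data$distance))),
                               y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "sentence distance (Dn)",
                  y = "% of unique relations") +
    ggplot2::theme_minimal()
}
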