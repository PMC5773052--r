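#' Tagger configuration
#'
#' Options honored by any implementation of the tagging contract (see
#' [tag_document()]): which organism-specific protein dictionaries to
#' enable, whether to tag proteins of other organisms too, a stopword
#' blacklist of names never to annotate, and an opaque option string passed
#' through to external taggers.
#'
#' @param organism_dictionaries Integer/character vector of NCBI taxids
#'   whose protein dictionaries are enabled.
#' @param autodetect_other_organisms Also tag proteins outside the enabled
#'   taxid set (default `TRUE`).
#' @param stopwords Character vector of names to skip (case-sensitive);
#'   defaults to the shipped stopword list.
#' @param entity_type_codes Opaque pass-through string for external taggers.
#' @return A list of class `lx_tagger_config`.
#' @export
tagger_config <- function(organism_dictionaries = c(9606, 4932, 3702),
                          autodetect_other_organisms = TRUE,
                          stopwords = NULL,
                          entity_type_codes = "") {
  taxids <- as.character(organism_dictionaries)
  if (!all(is_taxid(taxids))) abort("taxids must be positive integers")
  if (is.null(stopwords)) {
    stopwords <- lx_default_dictionaries()$stopwords
  }
  structure(list(organism_dictionaries = taxids,
                 autodetect_other_organisms = isTRUE(autodetect_other_organisms),
                 stopwords = as.character(stopwords),
                 entity_type_codes = as.character(entity_type_codes)),
            class = "lx_tagger_config")
}

#' Tag entities in raw text (naive dictionary tagger)
#'
#' The built-in implementation of the tagging contract: case-insensitive,
#' longest-match dictionary lookup over protein, location and organism name
#' lists, at token boundaries, skipping surfaces on the stopword list.
#' Protein dictionaries are restricted to the configured taxids unless
#' `autodetect_other_organisms` is set. Any implementation of the contract
#' must return offset-sound, normalized mentions satisfying the
#' entity-table invariants; external taggers (e.g. a dictionary tagger
#' behind a web service) plug in by producing the same table.
#'
#' @param text A single document string.
#' @param config An [tagger_config()] object.
#' @param dictionaries Dictionaries as from [lx_default_dictionaries()].
#' @return An entity tibble (`entity_id`, `class`, `start`, `end`,
#'   `surface`, `norm_ids`) without `doc_id`; empty for empty text.
#' @examples
#' tag_document("CAT2 is localized to the tonoplast", tagger_config())
#' @export
tag_document <- function(text, config = tagger_config(),
                         dictionaries = lx_default_dictionaries()) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(config, "lx_tagger_config"))
  if (is.na(text) || nchar(text) == 0L) return(empty_entities()[, -1])

  prot <- dictionaries$proteins
  if (!config$autodetect_other_organisms) {
    prot <- prot[as.character(prot$taxid) %in% config$organism_dictionaries, ,
                 drop = FALSE]
  }
  lexicon <- bind_rows(
    tibble(name = prot$name, norm_id = as.character(prot$norm_id),
           class = "protein"),
    tibble(name = dictionaries$locations$name,
           norm_id = as.character(dictionaries$locations$norm_id),
           class = "location"),
    tibble(name = dictionaries$organisms$name,
           norm_id = as.character(dictionaries$organisms$norm_id),
           class = "organism"))

  hits <- list()
  for (nm in unique(lexicon$name)) {
    pat <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", nm),
                  "(?![A-Za-z0-9])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    start <- as.integer(m) - 1L
    end <- start + attr(m, "match.length")
    rows <- lexicon[lexicon$name == nm, , drop = FALSE]
    for (k in seq_along(start)) {
      surface <- slice_text(text, start[k], end[k])
      if (surface %in% config$stopwords || nm %in% config$stopwords) next
      hits[[length(hits) + 1L]] <- tibble(
        start = start[k], end = end[k], surface = surface,
        class = rows$class[1], norm_ids = list(unique(rows$norm_id)))
    }
  }
  if (length(hits) == 0) return(empty_entities()[, -1])
  hits <- bind_rows(hits)
  # longest-match resolution: prefer longer spans, then leftmost
  hits <- hits[order(-(hits$end - hits$start), hits$start), , drop = FALSE]
  taken <- logical(nrow(hits))
  covered <- rep(FALSE, nchar(text))
  for (i in seq_len(nrow(hits))) {
    span <- (hits$start[i] + 1L):hits$end[i]
    if (!any(covered[span])) {
      covered[span] <- TRUE
      taken[i] <- TRUE
    }
  }
  out <- hits[taken, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$entity_id <- paste0("N", seq_len(nrow(out)))
  out[, c("entity_id", "class", "start", "end", "surface", "norm_ids")]
}

#' Tag every document of a corpus
#'
#' Applies [tag_document()] per document and returns a copy of the corpus
#' whose entity table is the tagger output (gold relations are dropped, as
#' they reference gold mentions).
#'
#' @inheritParams tag_document
#' @param corpus An `lx_corpus`.
#' @return An `lx_corpus` with predicted entities and no relations.
#' @export
tag_corpus <- function(corpus, config = tagger_config(),
                       dictionaries = lx_default_dictionaries()) {
  ents <- bind_rows(map(seq_len(nrow(corpus$documents)), function(i) {
    e <- tag_document(corpus$documents$text[i], config, dictionaries)
    if (nrow(e) == 0) return(NULL)
    mutate(e, doc_id = corpus$documents$doc_id[i])
  }))
  lx_corpus(documents = corpus$documents,
            sentences = corpus$sentences,
            entities = if (!is.null(ents) && nrow(ents)) {
              ents[, c("doc_id", "entity_id", "class", "start", "end",
                       "surface", "norm_ids")]
            } else NULL,
            relations = NULL,
            parses = corpus$parses,
            provenance = paste0(corpus$provenance, " [tagged]"))
}

#' Rewrite STRING identifiers to UniProtKB accessions
#'
#' Protein mentions normalized to STRING ids are rewritten through a
#' mapping table; ids with no mapping are dropped from `norm_ids` with a
#' warning (the mention itself is retained, possibly unnormalized).
#'
#' @param entities An entity tibble.
#' @param mapping A tibble with columns `string_id`, `uniprot_ac`, or a
#'   path to such a TSV.
#' @return The entity tibble with rewritten `norm_ids`.
#' @export
map_string_ids_to_uniprot <- function(entities, mapping) {
  if (is.character(mapping)) {
    mapping <- read_tsv_table(mapping, c("string_id", "uniprot_ac"))
  }
  lut <- stats::setNames(mapping$uniprot_ac, mapping$string_id)
  entities$norm_ids <- map2(entities$norm_ids, entities$class,
                            function(ids, cl) {
    if (cl != "protein" || length(ids) == 0) return(ids)
    mapped <- unname(lut[ids])
    if (anyNA(mapped)) {
      warn(paste0("no UniProtKB mapping for: ",
                  paste(ids[is.na(mapped)], collapse = ", ")))
    }
    unique(mapped[!is.na(mapped)])
  })
  entities
}

#' GO location filter policy
#'
#' Location mentions are kept only when normalized inside whitelisted
#' branches of the Cellular Component hierarchy — by default organelles,
#' membranes and the extracellular region — and dropped when inside a
#' blacklisted branch, by default macromolecular (protein-containing)
#' complexes, `GO:0032991`, which overlap the other GO hierarchies rather
#' than describing a compartment. The blacklist overrides the whitelist,
#' since complex terms can sit under whitelisted parents. The whitelist is
#' expressed as ontology roots plus descendant closure; the default root
#' ids are this package's reading of "organelles, membranes, extracellular
#' region", not an authoritative list.
#'
#' @param whitelist_roots GO ids whose descendant closure (and selves) pass.
#' @param blacklist_roots GO ids whose descendant closure (and selves) are
#'   removed.
#' @return A list of class `lx_go_filter_policy`.
#' @export
go_filter_policy <- function(whitelist_roots = c("GO:0043226", "GO:0016020",
                                                 "GO:0005576"),
                             blacklist_roots = "GO:0032991") {
  stopifnot(all(is_go_id(whitelist_roots)), all(is_go_id(blacklist_roots)))
  structure(list(whitelist_roots = whitelist_roots,
                 blacklist_roots = blacklist_roots),
            class = "lx_go_filter_policy")
}

#' Filter location mentions by GO branch
#'
#' Applies a [go_filter_policy()]: a location mention is removed when every
#' one of its normalized GO ids fails the whitelist, or when any of its ids
#' falls under a blacklist root. Ids absent from the ontology fail the
#' whitelist (with a warning). Non-location mentions pass through
#' untouched. Idempotent.
#'
#' @param entities An entity tibble.
#' @param ontology An `lx_ontology`.
#' @param policy A [go_filter_policy()].
#' @return The filtered entity tibble.
#' @export
filter_locations <- function(entities, ontology,
                             policy = go_filter_policy()) {
  stopifnot(inherits(ontology, "lx_ontology"),
            inherits(policy, "lx_go_filter_policy"))
  if (nrow(entities) == 0) return(entities)
  white <- go_descendants(ontology, policy$whitelist_roots)
  black <- go_descendants(ontology, policy$blacklist_roots)
  keep <- map_lgl(seq_len(nrow(entities)), function(i) {
    if (entities$class[i] != "location") return(TRUE)
    ids <- entities$norm_ids[[i]]
    if (length(ids) == 0) return(FALSE)
    unknown <- setdiff(ids, ontology$terms$go_id)
    if (length(unknown) > 0) {
      warn(paste0("GO id(s) not in ontology treated as filtered: ",
                  paste(unknown, collapse = ", ")))
    }
    if (any(ids %in% black)) return(FALSE)
    any(ids %in% white)
  })
  entities[keep, , drop = FALSE]
}
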