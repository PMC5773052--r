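#' Annotated-document corpus container
#'
#' An `lx_corpus` holds a collection of abstracts with character-offset
#' entity annotations, gold protein--location relations, sentence spans and
#' (optionally) per-sentence dependency parses. It is the common currency of
#' the pipeline: taggers produce its entity table, the candidate generator
#' consumes it, and the evaluation harness scores against its relation table.
#'
#' All character offsets are 0-based and half-open over the raw document
#' text. Component tibbles:
#'
#' * `documents`: `doc_id`, `text`.
#' * `sentences`: `doc_id`, `sent_idx` (1-based), `start`, `end`. Spans are
#'   ordered and non-overlapping; no entity straddles a span (straddled
#'   spans are merged at construction, since sentence splitters err on
#'   abbreviations and same-sentence logic needs each entity in exactly one
#'   sentence).
#' * `entities`: `doc_id`, `entity_id`, `class` (one of `"protein"`,
#'   `"location"`, `"organism"`), `start`, `end`, `surface`, `norm_ids`
#'   (list-column of character: UniProtKB accessions for proteins, `GO:`
#'   ids for locations, NCBI taxids for organisms; possibly empty when a
#'   mention could not be normalized, possibly several when ambiguous).
#' * `relations`: `doc_id`, `protein_id`, `location_id` — gold
#'   protein-localization relations referencing `entity_id`s.
#' * `parses`: `doc_id`, `sent_idx`, `token_idx` (1-based within sentence),
#'   `surface`, `lemma`, `pos`, `head` (1-based within sentence; equal to
#'   `token_idx` for the root), `dep`, `start`, `end`.
#'
#' @param documents,sentences,entities,relations,parses Component tibbles as
#'   described above; missing optional parts default to empty.
#' @param provenance Free-text metadata string.
#' @param repair_sentences Merge sentence spans straddled by an entity
#'   (default `TRUE`, with a message).
#' @return A validated object of class `lx_corpus`.
#' @seealso [read_corpus()], [write_corpus()], [generate_fixture_corpus()]
#' @export
lx_corpus <- function(documents,
                      sentences = NULL,
                      entities = NULL,
                      relations = NULL,
                      parses = NULL,
                      provenance = "",
                      repair_sentences = TRUE) {
  x <- structure(
    list(
      documents = as_tibble(documents),
      sentences = as_tibble(sentences %||% empty_sentences()),
      entities  = normalize_entities(entities %||% empty_entities()),
      relations = as_tibble(relations %||% empty_relations()),
      parses    = as_tibble(parses %||% empty_parses()),
      provenance = as.character(provenance)
    ),
    class = "lx_corpus"
  )
  if (repair_sentences) {
    x <- merge_straddled_sentences(x)
  }
  validate_corpus(x)
  x
}

empty_sentences <- function() {
  tibble(doc_id = character(), sent_idx = integer(),
         start = integer(), end = integer())
}

empty_entities <- function() {
  tibble(doc_id = character(), entity_id = character(), class = character(),
         start = integer(), end = integer(), surface = character(),
         norm_ids = list())
}

empty_relations <- function() {
  tibble(doc_id = character(), protein_id = character(),
         location_id = character())
}

empty_parses <- function() {
  tibble(doc_id = character(), sent_idx = integer(), token_idx = integer(),
         surface = character(), lemma = character(), pos = character(),
         head = integer(), dep = character(),
         start = integer(), end = integer())
}

normalize_entities <- function(entities) {
  entities <- as_tibble(entities)
  if (nrow(entities) == 0 && !("norm_ids" %in% names(entities))) {
    return(empty_entities())
  }
  entities$start <- as.integer(entities$start)
  entities$end <- as.integer(entities$end)
  entities$norm_ids <- lapply(entities$norm_ids, as.character)
  entities
}

#' @export
print.lx_corpus <- function(x, ...) {
  cat(sprintf(
    "<lx_corpus> %d document(s), %d entities, %d relations, %d parsed tokens\n",
    nrow(x$documents), nrow(x$entities), nrow(x$relations), nrow(x$parses)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

# Merge consecutive sentence spans until no entity straddles a boundary.
merge_straddled_sentences <- function(corpus) {
  ents <- corpus$entities
  sent <- corpus$sentences
  if (nrow(ents) == 0 || nrow(sent) == 0) return(corpus)
  merged_any <- FALSE
  for (doc in unique(ents$doc_id)) {
    spans <- sent[sent$doc_id == doc, , drop = FALSE]
    spans <- spans[order(spans$start), , drop = FALSE]
    e <- ents[ents$doc_id == doc, , drop = FALSE]
    repeat {
      # entity straddles iff no single span contains it
      bad <- NULL
      for (i in seq_len(nrow(e))) {
        inside <- spans$start <= e$start[i] & e$end[i] <= spans$end
        if (!any(inside)) { bad <- i; break }
      }
      if (is.null(bad)) break
      # merge the span containing the entity start with its successor
      j <- max(which(spans$start <= e$start[bad]))
      if (j >= nrow(spans)) {
        abort(sprintf("entity %s in document %s extends past the last sentence",
                      e$entity_id[bad], doc))
      }
      spans$end[j] <- spans$end[j + 1L]
      spans <- spans[-(j + 1L), , drop = FALSE]
      merged_any <- TRUE
    }
    spans$sent_idx <- seq_len(nrow(spans))
    sent <- bind_rows(sent[sent$doc_id != doc, , drop = FALSE], spans)
  }
  if (merged_any) {
    inform("merged sentence spans straddled by an entity")
  }
  corpus$sentences <- arrange(sent, .data$doc_id, .data$sent_idx)
  corpus
}

#' Validate an annotated corpus
#'
#' Enforces the container invariants: unique document ids; offsets within
#' the text with `surface` equal to the text slice; well-formed normalized
#' identifiers per entity class; ordered non-overlapping sentence spans with
#' every entity inside exactly one span; relations referencing in-document
#' entities of the stated classes; parse head indices in range with exactly
#' one root per sentence.
#'
#' @param corpus An `lx_corpus`.
#' @return The corpus, invisibly; errors describe the offending document and
#'   field.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "lx_corpus"))
  docs <- corpus$documents
  if (anyDuplicated(docs$doc_id)) {
    abort(paste0("duplicate doc_id: ",
                 paste(unique(docs$doc_id[duplicated(docs$doc_id)]),
                       collapse = ", ")))
  }
  text_of <- stats::setNames(docs$text, docs$doc_id)

  ents <- corpus$entities
  if (nrow(ents) > 0) {
    unknown <- setdiff(ents$doc_id, docs$doc_id)
    if (length(unknown) > 0) {
      abort(paste0("entities reference unknown document(s): ",
                   paste(unknown, collapse = ", ")))
    }
    bad_class <- setdiff(unique(ents$class),
                         c("protein", "location", "organism"))
    if (length(bad_class) > 0) {
      abort(paste0("invalid entity class: ", paste(bad_class, collapse = ", ")))
    }
    n <- nchar(text_of[ents$doc_id])
    ok_span <- ents$start >= 0L & ents$start < ents$end & ents$end <= n
    if (!all(ok_span)) {
      i <- which(!ok_span)[1]
      abort(sprintf("integrity error: entity %s in %s has offsets [%d,%d) outside text",
                    ents$entity_id[i], ents$doc_id[i], ents$start[i], ents$end[i]))
    }
    slices <- slice_text(text_of[ents$doc_id], ents$start, ents$end)
    mism <- slices != ents$surface
    if (any(mism)) {
      i <- which(mism)[1]
      abort(sprintf(
        "integrity error: entity %s in %s: surface %s != text slice %s",
        ents$entity_id[i], ents$doc_id[i],
        dQuote(ents$surface[i]), dQuote(slices[i])))
    }
    key <- paste(ents$doc_id, ents$entity_id)
    if (anyDuplicated(key)) {
      abort(paste0("duplicate entity_id within document: ",
                   key[duplicated(key)][1]))
    }
    for (i in seq_len(nrow(ents))) {
      ids <- ents$norm_ids[[i]]
      ok <- switch(ents$class[i],
                   protein = grepl("^[A-Z][A-Z0-9]{5,9}$", ids),
                   location = is_go_id(ids),
                   organism = is_taxid(ids))
      if (length(ids) > 0 && !all(ok)) {
        abort(sprintf("entity %s in %s has malformed norm id(s): %s",
                      ents$entity_id[i], ents$doc_id[i],
                      paste(ids[!ok], collapse = ", ")))
      }
    }
  }

  sent <- corpus$sentences
  if (nrow(sent) > 0) {
    for (doc in unique(sent$doc_id)) {
      s <- sent[sent$doc_id == doc, , drop = FALSE]
      s <- s[order(s$sent_idx), , drop = FALSE]
      if (!identical(s$sent_idx, seq_len(nrow(s)))) {
        abort(paste0("sentence indices of ", doc, " are not 1..n"))
      }
      if (any(s$start[-1] < s$end[-nrow(s)])) {
        abort(paste0("overlapping or unordered sentence spans in ", doc))
      }
      e <- ents[ents$doc_id == doc, , drop = FALSE]
      for (i in seq_len(nrow(e))) {
        inside <- s$start <= e$start[i] & e$end[i] <= s$end
        if (!any(inside)) {
          abort(sprintf("entity %s in %s straddles a sentence boundary",
                        e$entity_id[i], doc))
        }
      }
    }
  }

  rel <- corpus$relations
  if (nrow(rel) > 0) {
    ent_key <- paste(ents$doc_id, ents$entity_id)
    ent_class <- stats::setNames(ents$class, ent_key)
    pk <- paste(rel$doc_id, rel$protein_id)
    lk <- paste(rel$doc_id, rel$location_id)
    if (!all(pk %in% ent_key) || !all(lk %in% ent_key)) {
      missing <- c(pk, lk)[!(c(pk, lk) %in% ent_key)][1]
      abort(paste0("relation references unknown entity: ", missing))
    }
    if (!all(ent_class[pk] == "protein")) {
      abort("relation protein_id does not reference a protein mention")
    }
    if (!all(ent_class[lk] == "location")) {
      abort("relation location_id does not reference a location mention")
    }
  }

  par <- corpus$parses
  if (nrow(par) > 0) {
    grp <- split(par, paste(par$doc_id, par$sent_idx))
    for (g in grp) {
      n <- nrow(g)
      g <- g[order(g$token_idx), , drop = FALSE]
      if (!identical(as.integer(g$token_idx), seq_len(n))) {
        abort(sprintf("parse tokens of %s sentence %d are not 1..n",
                      g$doc_id[1], g$sent_idx[1]))
      }
      if (any(g$head < 1L | g$head > n)) {
        abort(sprintf("parse head out of range in %s sentence %d",
                      g$doc_id[1], g$sent_idx[1]))
      }
      if (sum(g$head == g$token_idx) != 1L) {
        abort(sprintf("parse of %s sentence %d must have exactly one root",
                      g$doc_id[1], g$sent_idx[1]))
      }
    }
  }
  invisible(corpus)
}

#' Corpus entity and relation counts
#'
#' @param corpus An `lx_corpus`.
#' @return A one-row tibble with integer counts: `protein`, `location`,
#'   `organism` mention totals and `relations` (gold protein-localization
#'   relation annotations, mention-level).
#' @export
stats_entities <- function(corpus) {
  stopifnot(inherits(corpus, "lx_corpus"))
  cls <- corpus$entities$class
  tibble(
    protein = sum(cls == "protein"),
    location = sum(cls == "location"),
    organism = sum(cls == "organism"),
    relations = nrow(corpus$relations)
  )
}

#' Read a corpus container file
#'
#' Reads the package's versioned JSON corpus format (see [write_corpus()]).
#' Malformed normalized identifiers are pruned from `norm_ids` with a
#' warning; structural violations (offset/surface mismatch, dangling
#' relation references) are errors naming the document and field.
#'
#' @param path Path to a corpus `.json` file.
#' @return An `lx_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) abort(paste0("no such corpus file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$format, "locrex-corpus")) {
    abort(paste0("parse error: ", path, " is not a locrex-corpus file"))
  }
  if (!identical(as.integer(raw$version %||% 0L), 1L)) {
    abort(paste0("parse error: unsupported corpus format version in ", path))
  }
  docs <- raw$documents %||% list()
  doc_tbl <- tibble(
    doc_id = map_chr(docs, function(d) d$doc_id %||%
                       abort("parse error: document without doc_id")),
    text = map_chr(docs, function(d) d$text %||%
                     abort(paste0("parse error: document ",
                                  d$doc_id %||% "?", " lacks field text")))
  )
  sent_tbl <- bind_rows(map(docs, function(d) {
    spans <- d$sentences %||% list()
    if (length(spans) == 0) return(NULL)
    tibble(doc_id = d$doc_id,
           sent_idx = seq_along(spans),
           start = map_int(spans, function(s) as.integer(s[[1]])),
           end = map_int(spans, function(s) as.integer(s[[2]])))
  }))
  ent_tbl <- bind_rows(map(docs, function(d) {
    es <- d$entities %||% list()
    if (length(es) == 0) return(NULL)
    tibble(doc_id = d$doc_id,
           entity_id = map_chr(es, function(e) e$entity_id %||%
                                 abort(paste0("parse error: entity without ",
                                              "entity_id in ", d$doc_id))),
           class = map_chr(es, function(e) e$class %||% "?"),
           start = map_int(es, function(e) as.integer(e$start)),
           end = map_int(es, function(e) as.integer(e$end)),
           surface = map_chr(es, function(e) e$surface %||% ""),
           norm_ids = map(es, function(e) as.character(unlist(e$norm_ids))))
  }))
  if (nrow(ent_tbl) > 0) {
    ent_tbl$norm_ids <- map2(ent_tbl$norm_ids, ent_tbl$class, function(ids, cl) {
      ok <- switch(cl,
                   protein = grepl("^[A-Z][A-Z0-9]{5,9}$", ids),
                   location = is_go_id(ids),
                   organism = is_taxid(ids),
                   rep(FALSE, length(ids)))
      if (length(ids) > 0 && !all(ok)) {
        warn(paste0("pruned malformed norm id(s): ",
                    paste(ids[!ok], collapse = ", ")))
      }
      ids[ok]
    })
  } else {
    ent_tbl <- empty_entities()
  }
  rel_tbl <- bind_rows(map(docs, function(d) {
    rs <- d$relations %||% list()
    if (length(rs) == 0) return(NULL)
    tibble(doc_id = d$doc_id,
           protein_id = map_chr(rs, function(r) r$protein_id),
           location_id = map_chr(rs, function(r) r$location_id))
  }))
  par_tbl <- bind_rows(map(docs, function(d) {
    ps <- d$parses %||% list()
    if (length(ps) == 0) return(NULL)
    bind_rows(map(ps, function(p) {
      toks <- p$tokens %||% list()
      tibble(doc_id = d$doc_id,
             sent_idx = as.integer(p$sent_idx),
             token_idx = seq_along(toks),
             surface = map_chr(toks, function(t) t$surface),
             lemma = map_chr(toks, function(t) t$lemma),
             pos = map_chr(toks, function(t) t$pos),
             head = map_int(toks, function(t) as.integer(t$head)),
             dep = map_chr(toks, function(t) t$dep),
             start = map_int(toks, function(t) as.integer(t$start)),
             end = map_int(toks, function(t) as.integer(t$end)))
    }))
  }))
  lx_corpus(documents = doc_tbl,
            sentences = if (nrow(sent_tbl)) sent_tbl else NULL,
            entities = if (nrow(ent_tbl)) ent_tbl else NULL,
            relations = if (nrow(rel_tbl)) rel_tbl else NULL,
            parses = if (nrow(par_tbl)) par_tbl else NULL,
            provenance = raw$provenance %||% "",
            repair_sentences = FALSE)
}

#' Write a corpus container file
#'
#' Serializes an `lx_corpus` to the package's JSON container format
#' (format tag `"locrex-corpus"`, version 1): one file per corpus holding,
#' per document, the raw text, sentence spans, standoff entities with
#' normalized ids, gold relations and optional token-level parses.
#' Re-reading the file yields an equal corpus.
#'
#' @param corpus An `lx_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  docs <- map(seq_len(nrow(corpus$documents)), function(i) {
    doc <- corpus$documents$doc_id[i]
    s <- corpus$sentences[corpus$sentences$doc_id == doc, , drop = FALSE]
    s <- s[order(s$sent_idx), , drop = FALSE]
    e <- corpus$entities[corpus$entities$doc_id == doc, , drop = FALSE]
    r <- corpus$relations[corpus$relations$doc_id == doc, , drop = FALSE]
    p <- corpus$parses[corpus$parses$doc_id == doc, , drop = FALSE]
    list(
      doc_id = doc,
      text = corpus$documents$text[i],
      sentences = map2(s$start, s$end, function(a, b) c(a, b)),
      entities = map(seq_len(nrow(e)), function(j) {
        list(entity_id = e$entity_id[j], class = e$class[j],
             start = e$start[j], end = e$end[j], surface = e$surface[j],
             norm_ids = as.list(e$norm_ids[[j]]))
      }),
      relations = map(seq_len(nrow(r)), function(j) {
        list(protein_id = r$protein_id[j], location_id = r$location_id[j])
      }),
      parses = map(sort(unique(p$sent_idx)), function(si) {
        tk <- p[p$sent_idx == si, , drop = FALSE]
        tk <- tk[order(tk$token_idx), , drop = FALSE]
        list(sent_idx = si,
             tokens = map(seq_len(nrow(tk)), function(j) {
               list(surface = tk$surface[j], lemma = tk$lemma[j],
                    pos = tk$pos[j], head = tk$head[j], dep = tk$dep[j],
                    start = tk$start[j], end = tk$end[j])
             }))
      })
    )
  })
  out <- list(format = "locrex-corpus", version = 1L,
              provenance = corpus$provenance, documents = docs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

# Sentence index (1-based) containing each entity; entities joined by
# doc_id + entity_id.
entity_sentence_index <- function(corpus, doc_id, entity_id) {
  idx <- integer(length(entity_id))
  for (i in seq_along(entity_id)) {
    e <- corpus$entities[corpus$entities$doc_id == doc_id[i] &
                           corpus$entities$entity_id == entity_id[i], ,
                         drop = FALSE]
    if (nrow(e) != 1L) {
      abort(paste0("unknown entity ", entity_id[i], " in ", doc_id[i]))
    }
    s <- corpus$sentences[corpus$sentences$doc_id == doc_id[i], , drop = FALSE]
    hit <- which(s$start <= e$start & e$end <= s$end)
    if (length(hit) == 0) {
      abort(paste0("entity ", entity_id[i], " outside all sentence spans"))
    }
    idx[i] <- s$sent_idx[hit[1]]
  }
  idx
}
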