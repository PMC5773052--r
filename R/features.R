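# Sparse feature extraction for candidate instances.
#
# Five feature families over a candidate (protein, location) pair:
#   cnt  scaled entity counts in the covering sentence(s)
#   dom  domain knowledge: protein-marker lexicon, Swiss-Prot annotation
#   lin  n-grams (n = 1..3) of tokens linearly between the pair, over a
#        masked-lemma stream and a POS stream
#   dep  n-grams along the shortest dependency-parse path between the
#        pair's head tokens, over masked-lemma, POS and edge-label streams
# Feature names are structured strings "<family>|<stream>|<n>|<content>";
# values are binary presence for n-grams and [0, 1]-scaled counts for the
# count family. Zero-valued entries are never stored.

#' Feature-extraction resources
#'
#' Bundles everything [featurize()] needs beyond the corpus: the fitted
#' count scaler, the marker lexicon, the protein-to-GO annotation table
#' with its ontology, and the masking/count configuration.
#'
#' @param scaler A scaler from [fit_count_scaler()], or `NULL` before
#'   fitting.
#' @param markers Character vector of marker protein names.
#' @param swissprot Tibble (`uniprot_ac`, `go_id`) of known annotations.
#' @param ontology An `lx_ontology` (for annotation-descendant lookup).
#' @param count_mode `"pair"` (2 features: protein+location count, total
#'   entity count) or `"full"` (4 features: per-class counts and total).
#' @param mask_mode `"linear"` (the left mention of the pair is `SOURCE`,
#'   the right `TARGET`) or `"role"` (protein is `SOURCE`, location
#'   `TARGET`).
#' @return A list of class `lx_feature_resources`.
#' @export
feature_resources <- function(scaler = NULL,
                              markers = lx_default_dictionaries()$markers,
                              swissprot = lx_default_dictionaries()$swissprot,
                              ontology = NULL,
                              count_mode = c("pair", "full"),
                              mask_mode = c("linear", "role")) {
  structure(list(scaler = scaler, markers = markers, swissprot = swissprot,
                 ontology = ontology,
                 count_mode = match.arg(count_mode),
                 mask_mode = match.arg(mask_mode)),
            class = "lx_feature_resources")
}

get_parse <- function(corpus, doc_id, sent_idx) {
  p <- corpus$parses[corpus$parses$doc_id == doc_id &
                       corpus$parses$sent_idx == sent_idx, , drop = FALSE]
  if (nrow(p) == 0) return(NULL)
  p[order(p$token_idx), , drop = FALSE]
}

is_numeric_token <- function(surface) {
  grepl("^[0-9]+([.,][0-9]+)*$", surface)
}

# Masked lemma with precedence SOURCE/TARGET > entity class > NUM > lemma.
# SOURCE/TARGET handling happens at the unit level in the callers; this
# resolves class/NUM/lemma for one token.
mask_token <- function(surface, lemma, start, end, doc_entities) {
  if (nrow(doc_entities) > 0) {
    hit <- doc_entities$start < end & start < doc_entities$end
    if (any(hit)) {
      return(toupper(doc_entities$class[which(hit)[1]]))
    }
  }
  if (is_numeric_token(surface)) return("NUM")
  tolower(lemma)
}

ngram_names <- function(family, stream, units, ns = 1:3) {
  out <- character()
  for (n in ns) {
    if (length(units) < n) next
    for (i in seq_len(length(units) - n + 1L)) {
      out <- c(out, paste(family, stream, n,
                          paste(units[i:(i + n - 1L)], collapse = "|"),
                          sep = "|"))
    }
  }
  out
}

source_target <- function(instance, corpus_ents, mask_mode) {
  p <- corpus_ents[corpus_ents$entity_id == instance$protein_id, ,
                   drop = FALSE]
  l <- corpus_ents[corpus_ents$entity_id == instance$location_id, ,
                   drop = FALSE]
  if (mask_mode == "role" || p$start <= l$start) {
    list(source = p, target = l)
  } else {
    list(source = l, target = p)    # leftmost mention is SOURCE
  }
}

#' Linear between-entity n-gram features
#'
#' n-grams (n = 1, 2, 3) over the tokens strictly between the two mentions
#' of a candidate pair, in two streams: masked lowercase lemmas (numbers as
#' `NUM`, tokens of other entity mentions as their class) and POS tags.
#' In n-grams of length 2 or 3 the pair's own mentions contribute the
#' placeholders `SOURCE` and `TARGET` (assignment per the resources'
#' `mask_mode`); 1-grams cover the gap only, so adjacent mentions produce
#' just the 2-gram `SOURCE|TARGET`. Tokens of a multi-token entity mention
#' in the gap collapse into one unit. Values are binary presence.
#'
#' @param instance One candidate row (see [generate_candidates()]).
#' @param corpus An `lx_corpus`.
#' @param resources An [feature_resources()].
#' @return Named numeric vector of 1s.
#' @export
linear_ngrams <- function(instance, corpus, resources) {
  doc <- instance$doc_id
  ents <- corpus$entities[corpus$entities$doc_id == doc, , drop = FALSE]
  st <- source_target(instance, ents, resources$mask_mode)
  left_end <- min(st$source$end, st$target$end)
  right_start <- max(st$source$start, st$target$start)

  sents <- sort(unique(c(instance$prot_sent, instance$loc_sent)))
  toks <- bind_rows(map(sents, function(si) get_parse(corpus, doc, si)))
  degraded <- FALSE
  if (nrow(toks) == 0) {
    # no parse: fall back to raw tokenization, lemma = lowercase surface
    degraded <- TRUE
    span <- corpus$sentences[corpus$sentences$doc_id == doc &
                               corpus$sentences$sent_idx %in% sents, ,
                             drop = FALSE]
    raw <- lx_tokenize(slice_text(corpus$documents$text[
      corpus$documents$doc_id == doc], min(span$start), max(span$end)))
    toks <- tibble(surface = raw$token, lemma = tolower(raw$token),
                   pos = NA_character_,
                   start = raw$start + min(span$start),
                   end = raw$end + min(span$start))
  }
  gap <- toks[toks$start >= left_end & toks$end <= right_start, ,
              drop = FALSE]
  other_ents <- ents[!(ents$entity_id %in% c(instance$protein_id,
                                             instance$location_id)), ,
                     drop = FALSE]
  lem_units <- character(); pos_units <- character()
  i <- 1L
  while (i <= nrow(gap)) {
    hit <- which(other_ents$start < gap$end[i] &
                   gap$start[i] < other_ents$end)
    if (length(hit) > 0) {
      ent <- other_ents[hit[1], , drop = FALSE]
      lem_units <- c(lem_units, toupper(ent$class))
      pos_units <- c(pos_units, toupper(ent$class))
      while (i <= nrow(gap) && ent$start < gap$end[i] &&
               gap$start[i] < ent$end) i <- i + 1L
    } else {
      lem_units <- c(lem_units,
                     if (is_numeric_token(gap$surface[i])) "NUM"
                     else tolower(gap$lemma[i]))
      pos_units <- c(pos_units, gap$pos[i])
      i <- i + 1L
    }
  }
  feats <- c(
    ngram_names("lin", "lem", lem_units, ns = 1),
    ngram_names("lin", "lem", c("SOURCE", lem_units, "TARGET"), ns = 2:3))
  if (!degraded) {
    feats <- c(feats,
               ngram_names("lin", "pos", pos_units, ns = 1),
               ngram_names("lin", "pos", c("SOURCE", pos_units, "TARGET"),
                           ns = 2:3))
  }
  out <- rep(1, length(unique(feats)))
  names(out) <- unique(feats)
  attr(out, "degraded") <- degraded
  out
}

# Head token of a mention: the token (among those overlapping the mention
# span) whose dependency head lies outside the mention — the token highest
# in the tree.
mention_head_token <- function(parse, start, end) {
  in_mention <- which(parse$start < end & start < parse$end)
  if (length(in_mention) == 0) return(NA_integer_)
  for (i in in_mention) {
    h <- parse$head[i]
    if (h == parse$token_idx[i] || !(h %in% parse$token_idx[in_mention])) {
      return(parse$token_idx[i])
    }
  }
  in_mention[1]
}

#' Shortest dependency-parse path between two tokens
#'
#' Breadth-first search over the undirected tree defined by each token's
#' dependency head. The path includes both endpoints; in a tree it is
#' unique.
#'
#' @param parse A one-sentence parse tibble (`token_idx`, `head`, ...).
#' @param from,to Token indices.
#' @return Integer vector of token indices from `from` to `to`.
#' @export
dep_path <- function(parse, from, to) {
  n <- nrow(parse)
  stopifnot(from >= 1, from <= n, to >= 1, to <= n)
  if (from == to) return(from)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- parse$head[i]
    if (h != parse$token_idx[i]) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  prev <- rep(NA_integer_, n)
  seen <- logical(n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[to]) abort("dependency parse is disconnected")
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

#' Dependency-path n-gram features
#'
#' n-grams (n = 1..3) along the shortest dependency path between the
#' pair's mention head tokens, in three streams: masked lemmas, POS tags,
#' and dependency edge labels. Path endpoints are masked `SOURCE`/`TARGET`
#' (per `mask_mode`); the path is canonicalized to run from `SOURCE` to
#' `TARGET`, and edge direction (towards or away from the sentence root) is
#' not encoded, so traversing the pair in either order yields the same
#' features.
#'
#' @inheritParams linear_ngrams
#' @return Named numeric vector of 1s; empty when the covering context has
#'   no parse or spans two sentences (paths are within-sentence only).
#' @export
dep_path_ngrams <- function(instance, corpus, resources) {
  if (instance$prot_sent != instance$loc_sent) return(stats::setNames(numeric(0), character(0)))
  doc <- instance$doc_id
  parse <- get_parse(corpus, doc, instance$prot_sent)
  if (is.null(parse)) return(stats::setNames(numeric(0), character(0)))
  ents <- corpus$entities[corpus$entities$doc_id == doc, , drop = FALSE]
  st <- source_target(instance, ents, resources$mask_mode)
  s_head <- mention_head_token(parse, st$source$start, st$source$end)
  t_head <- mention_head_token(parse, st$target$start, st$target$end)
  if (is.na(s_head) || is.na(t_head)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  path <- dep_path(parse, s_head, t_head)

  other_ents <- ents[!(ents$entity_id %in% c(instance$protein_id,
                                             instance$location_id)), ,
                     drop = FALSE]
  unit_of <- function(idx, stream) {
    row <- parse[parse$token_idx == idx, , drop = FALSE]
    if (idx == s_head) return("SOURCE")
    if (idx == t_head) return("TARGET")
    if (stream == "lem") {
      mask_token(row$surface, row$lemma, row$start, row$end, other_ents)
    } else {
      hit <- other_ents$start < row$end & row$start < other_ents$end
      if (any(hit)) toupper(other_ents$class[which(hit)[1]]) else row$pos
    }
  }
  lem_units <- map_chr(path, unit_of, stream = "lem")
  pos_units <- map_chr(path, unit_of, stream = "pos")
  edge_units <- character()
  if (length(path) > 1) {
    for (k in seq_len(length(path) - 1L)) {
      a <- path[k]; b <- path[k + 1L]
      # the edge label belongs to whichever endpoint is the child
      lab <- if (parse$head[parse$token_idx == a] == b) {
        parse$dep[parse$token_idx == a]
      } else {
        parse$dep[parse$token_idx == b]
      }
      edge_units <- c(edge_units, lab)
    }
  }
  feats <- c(ngram_names("dep", "lem", lem_units),
             ngram_names("dep", "pos", pos_units),
             ngram_names("dep", "edge", edge_units))
  out <- rep(1, length(unique(feats)))
  names(out) <- unique(feats)
  out
}

count_feature_values <- function(instance, corpus, count_mode) {
  doc <- instance$doc_id
  sents <- unique(c(instance$prot_sent, instance$loc_sent))
  span <- corpus$sentences[corpus$sentences$doc_id == doc &
                             corpus$sentences$sent_idx %in% sents, ,
                           drop = FALSE]
  ents <- corpus$entities[corpus$entities$doc_id == doc &
                            corpus$entities$start >= min(span$start) &
                            corpus$entities$end <= max(span$end), ,
                          drop = FALSE]
  n_p <- sum(ents$class == "protein")
  n_l <- sum(ents$class == "location")
  n_o <- sum(ents$class == "organism")
  if (count_mode == "pair") {
    c("cnt|sent|1|protloc" = n_p + n_l, "cnt|sent|1|total" = n_p + n_l + n_o)
  } else {
    c("cnt|sent|1|protein" = n_p, "cnt|sent|1|location" = n_l,
      "cnt|sent|1|organism" = n_o, "cnt|sent|1|total" = n_p + n_l + n_o)
  }
}

#' Fit the count-feature scaler on training instances
#'
#' Records, per count feature, the largest raw count observed over the
#' training instances. At feature time counts are divided by these maxima,
#' mapping training values into \[0, 1\]; a test count larger than any seen
#' in training scales above 1 (a count of 11 against a training maximum of
#' 10 becomes 1.1). Maxima of 0 are replaced by 1.
#'
#' @param candidates Training candidate tibble.
#' @param corpus An `lx_corpus`.
#' @param count_mode See [feature_resources()].
#' @return Named numeric vector of per-feature maxima (class
#'   `lx_count_scaler`).
#' @export
fit_count_scaler <- function(candidates, corpus, count_mode = "pair") {
  raw <- map(seq_len(nrow(candidates)), function(i) {
    count_feature_values(candidates[i, ], corpus, count_mode)
  })
  if (length(raw) == 0) {
    maxima <- count_feature_values(
      tibble(doc_id = corpus$documents$doc_id[1], prot_sent = 1L,
             loc_sent = 1L), corpus, count_mode) * 0
  } else {
    maxima <- do.call(pmax, raw)
  }
  maxima[maxima <= 0] <- 1
  structure(maxima, class = "lx_count_scaler")
}

#' Scaled entity-count features
#'
#' @inheritParams linear_ngrams
#' @return Named numeric vector of counts divided by the training maxima in
#'   the resources' scaler.
#' @export
entity_count_features <- function(instance, corpus, resources) {
  if (is.null(resources$scaler)) abort("count scaler not fitted")
  raw <- count_feature_values(instance, corpus, resources$count_mode)
  vals <- raw / unclass(resources$scaler)[names(raw)]
  vals[vals != 0]
}

#' Protein-marker feature
#'
#' 1 when the protein mention surface, tokenized and lowercased, equals a
#' marker lexicon entry (GFP, red fluorescent protein, ...). Reporter
#' constructs are fused to the protein under study, so their own "mention"
#' rarely names the localized protein.
#'
#' @inheritParams linear_ngrams
#' @return Named numeric vector (empty or the single marker feature).
#' @export
marker_feature <- function(instance, corpus, resources) {
  e <- corpus$entities[corpus$entities$doc_id == instance$doc_id &
                         corpus$entities$entity_id == instance$protein_id, ,
                       drop = FALSE]
  norm <- function(x) {
    paste(tolower(lx_tokenize(x)$token), collapse = " ")
  }
  lex <- vapply(resources$markers, norm, character(1))
  if (norm(e$surface) %in% lex) c("dom|marker|1|is_marker" = 1) else {
    stats::setNames(numeric(0), character(0))
  }
}

#' Known-annotation (Swiss-Prot) feature
#'
#' 1 when some combination of the pair's normalized ids is already an
#' annotation in the protein-to-GO table, or the location term is a
#' descendant of a tabled annotation for that protein.
#'
#' @inheritParams linear_ngrams
#' @return Named numeric vector (empty or the single annotation feature).
#' @export
swissprot_feature <- function(instance, corpus, resources) {
  ents <- corpus$entities[corpus$entities$doc_id == instance$doc_id, ,
                          drop = FALSE]
  acs <- ents$norm_ids[[which(ents$entity_id == instance$protein_id)]]
  gos <- ents$norm_ids[[which(ents$entity_id == instance$location_id)]]
  tab <- resources$swissprot
  hit <- FALSE
  for (ac in acs) {
    known <- tab$go_id[tab$uniprot_ac == ac]
    for (go in gos) {
      if (go %in% known) { hit <- TRUE; break }
      if (!is.null(resources$ontology) &&
            any(map_lgl(known, function(k) {
              go_is_descendant(resources$ontology, go, k)
            }))) { hit <- TRUE; break }
    }
    if (hit) break
  }
  if (hit) c("dom|sp|1|in_swissprot" = 1) else {
    stats::setNames(numeric(0), character(0))
  }
}

#' Full sparse feature vector for one candidate
#'
#' Union of all five feature families. A pure function of the instance and
#' resources: repeated calls give identical vectors. When the covering
#' sentence has no parse, dependency features are absent, the linear
#' family falls back to raw tokenization, and the result carries
#' `attr(, "degraded") = TRUE`.
#'
#' @inheritParams linear_ngrams
#' @return Named numeric vector; no zero entries.
#' @export
featurize <- function(instance, corpus, resources) {
  lin <- linear_ngrams(instance, corpus, resources)
  degraded <- isTRUE(attr(lin, "degraded"))
  attr(lin, "degraded") <- NULL
  out <- c(entity_count_features(instance, corpus, resources),
           marker_feature(instance, corpus, resources),
           swissprot_feature(instance, corpus, resources),
           lin,
           dep_path_ngrams(instance, corpus, resources))
  out <- out[out != 0]
  attr(out, "degraded") <- degraded
  out
}

#' Feature matrix for a set of candidates
#'
#' @param candidates Candidate tibble.
#' @param corpus An `lx_corpus`.
#' @param resources An [feature_resources()] with a fitted scaler.
#' @param feature_names Optional fixed column set (prediction time);
#'   features outside it are dropped, absent ones are zero columns.
#' @return A dense numeric matrix, rows = instances, columns = features
#'   (sorted names when `feature_names` is `NULL`).
#' @export
featurize_matrix <- function(candidates, corpus, resources,
                             feature_names = NULL) {
  vecs <- map(seq_len(nrow(candidates)), function(i) {
    featurize(candidates[i, ], corpus, resources)
  })
  cols <- feature_names %||% sort(unique(unlist(map(vecs, names))))
  X <- matrix(0, nrow = nrow(candidates), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    keep <- names(v) %in% cols
    X[i, names(v)[keep]] <- unname(v[keep])
  }
  X
}
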