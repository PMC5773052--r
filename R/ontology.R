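#' Read a GO ontology subset from an OBO file
#'
#' Parses `[Term]` stanzas for `id`, `name`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are skipped with a warning.
#' The combined `is_a`/`part_of` edge set must be acyclic and may only
#' reference loaded terms. Both edge types are treated identically for
#' ancestry: a term located "part of" a compartment is inside it for the
#' purposes of annotation specificity, which is the reading the Cellular
#' Component hierarchy supports.
#'
#' @param path Path to an OBO file.
#' @return An object of class `lx_ontology`: list with `terms` (tibble
#'   `go_id`, `name`), `edges` (tibble `child`, `parent`, `rel`), and a
#'   precomputed `ancestors` list mapping each id to all its ancestor ids
#'   (excluding itself).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(paste0("no such OBO file: ", path))
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (is.null(cur)) return(terms)
    if (isTRUE(cur$obsolete)) {
      warn(paste0("skipping obsolete term ", cur$id))
      return(terms)
    }
    if (!is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(), rels = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && !is.null(cur)) {
      if (grepl("^id: ", ln)) {
        cur$id <- sub("^id: ", "", ln)
      } else if (grepl("^name: ", ln)) {
        cur$name <- sub("^name: ", "", ln)
      } else if (grepl("^is_a: ", ln)) {
        parent <- sub("^is_a: ([^ !]+).*$", "\\1", ln)
        cur$parents <- c(cur$parents, parent)
        cur$rels <- c(cur$rels, "is_a")
      } else if (grepl("^relationship: part_of ", ln)) {
        parent <- sub("^relationship: part_of ([^ !]+).*$", "\\1", ln)
        cur$parents <- c(cur$parents, parent)
        cur$rels <- c(cur$rels, "part_of")
      } else if (grepl("^is_obsolete: true", ln)) {
        cur$obsolete <- TRUE
      }
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) abort(paste0("no terms parsed from ", path))
  term_tbl <- tibble(
    go_id = map_chr(terms, "id"),
    name = map_chr(terms, function(t) t$name %||% "")
  )
  edge_tbl <- bind_rows(map(terms, function(t) {
    if (length(t$parents) == 0) return(NULL)
    tibble(child = t$id, parent = t$parents, rel = t$rels)
  }))
  if (is.null(edge_tbl) || nrow(edge_tbl) == 0) {
    edge_tbl <- tibble(child = character(), parent = character(),
                       rel = character())
  }
  dangling <- setdiff(edge_tbl$parent, term_tbl$go_id)
  if (length(dangling) > 0) {
    abort(paste0("ontology references unknown parent term(s): ",
                 paste(dangling, collapse = ", ")))
  }
  new_ontology(term_tbl, edge_tbl)
}

#' Build an ontology from term and edge tables
#'
#' Programmatic constructor used by tests and the fixture tooling; performs
#' the same acyclicity validation and ancestor-closure precomputation as
#' [read_obo()].
#'
#' @param terms Tibble with columns `go_id`, `name`.
#' @param edges Tibble with columns `child`, `parent`, `rel`
#'   (`"is_a"` or `"part_of"`).
#' @return An `lx_ontology`.
#' @export
new_ontology <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("child", "parent")], directed = TRUE,
      vertices = terms$go_id)
    if (!igraph::is_dag(g)) {
      abort("ontology edge set (is_a + part_of) contains a cycle")
    }
  }
  parents_of <- split(edges$parent, edges$child)
  anc <- new.env(parent = emptyenv())
  get_anc <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    ps <- parents_of[[id]]
    res <- if (is.null(ps)) character() else {
      unique(c(ps, unlist(lapply(ps, get_anc))))
    }
    anc[[id]] <- res
    res
  }
  closure <- stats::setNames(lapply(terms$go_id, get_anc), terms$go_id)
  structure(list(terms = terms, edges = edges, ancestors = closure),
            class = "lx_ontology")
}

#' @export
print.lx_ontology <- function(x, ...) {
  cat(sprintf("<lx_ontology> %d terms, %d edges (%d is_a, %d part_of)\n",
              nrow(x$terms), nrow(x$edges),
              sum(x$edges$rel == "is_a"), sum(x$edges$rel == "part_of")))
  invisible(x)
}

#' Is one GO term a descendant of another?
#'
#' Descent is reflexive (`candidate == ancestor` is `TRUE`) and transitive
#' over the combined `is_a`/`part_of` edge set. Ids absent from the
#' ontology are never descendants of anything but themselves.
#'
#' @param ontology An `lx_ontology`.
#' @param candidate,ancestor GO id strings (vectorized over `candidate`).
#' @return Logical vector.
#' @export
go_is_descendant <- function(ontology, candidate, ancestor) {
  stopifnot(inherits(ontology, "lx_ontology"), length(ancestor) == 1L)
  map_lgl(candidate, function(id) {
    if (identical(id, ancestor)) return(TRUE)
    ancestor %in% ontology$ancestors[[id]]
  })
}

#' All descendants of a set of root terms
#'
#' @param ontology An `lx_ontology`.
#' @param roots Character vector of GO ids.
#' @return Character vector of GO ids: the roots plus every term reaching a
#'   root over `is_a`/`part_of` edges.
#' @export
go_descendants <- function(ontology, roots) {
  stopifnot(inherits(ontology, "lx_ontology"))
  ids <- ontology$terms$go_id
  keep <- map_lgl(ids, function(id) {
    id %in% roots || any(roots %in% ontology$ancestors[[id]])
  })
  ids[keep]
}

#' The bundled fixture Cellular Component ontology
#'
#' A small synthetic subset of GO Cellular Component (about 25 terms) with
#' realistic `is_a`/`part_of` structure, shipped for tests, examples and the
#' fixture corpus. Not the real ontology: term coverage is limited to the
#' compartments the built-in dictionaries know.
#'
#' @return An `lx_ontology`.
#' @export
fixture_ontology <- function() {
  suppressWarnings(read_obo(extdata_path("cc_fixture.obo")))
}
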