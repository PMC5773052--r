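#' Relation/entity matching policy
#'
#' Governs when a predicted normalized relation (or entity) counts as
#' matching a gold one. Proteins match when their accessions are equal or
#' when a pluggable equivalence predicate accepts the pair — the hook for a
#' sequence-identity criterion (near-identical UniProtKB/TrEMBL entries can
#' carry different accessions); the default provider is exact equality,
#' and a precomputed accession-pair table can stand behind the predicate
#' without any in-package sequence alignment. Locations match when equal
#' or, with `use_go_hierarchy`, when the predicted GO term is a descendant
#' of the gold term (more specific is still correct; the reverse is not).
#'
#' @param protein_identity_threshold Percent sequence identity above which
#'   a provider may treat two accessions as the same protein; recorded in
#'   the policy, interpreted by the provider. In (0, 100].
#' @param protein_equivalence_provider `function(ac1, ac2) -> logical`;
#'   default exact equality.
#' @param use_go_hierarchy Accept GO-descendant predictions (default
#'   `TRUE`).
#' @return A list of class `lx_match_policy`.
#' @export
match_policy <- function(protein_identity_threshold = 90,
                         protein_equivalence_provider = NULL,
                         use_go_hierarchy = TRUE) {
  if (protein_identity_threshold <= 0 || protein_identity_threshold > 100) {
    abort("protein_identity_threshold must be in (0, 100]")
  }
  provider <- protein_equivalence_provider %||%
    function(ac1, ac2) identical(ac1, ac2)
  structure(list(protein_identity_threshold = protein_identity_threshold,
                 protein_equivalence_provider = provider,
                 use_go_hierarchy = isTRUE(use_go_hierarchy)),
            class = "lx_match_policy")
}

proteins_match <- function(ac1, ac2, policy) {
  identical(ac1, ac2) || isTRUE(policy$protein_equivalence_provider(ac1, ac2))
}

locations_match <- function(go_test, go_pred, policy, ontology) {
  if (identical(go_test, go_pred)) return(TRUE)
  if (!policy$use_go_hierarchy || is.null(ontology)) return(FALSE)
  go_is_descendant(ontology, go_pred, go_test)
}

#' Does a predicted relation match a gold relation?
#'
#' Both relations must come from the same document. The proteins must be
#' equal or equivalent under the policy provider; the locations must be
#' equal or the predicted GO id must be a descendant of the gold GO id.
#' The descendant rule is asymmetric: predicting a *less* specific term
#' than annotated is wrong.
#'
#' @param test,pred One-row tibbles (or lists) with `doc_id`, `uniprot_ac`,
#'   `go_id`.
#' @param policy An [match_policy()].
#' @param ontology An `lx_ontology` (needed for the hierarchy rule).
#' @return `TRUE` or `FALSE`.
#' @export
match_relation <- function(test, pred, policy = match_policy(),
                           ontology = NULL) {
  if (!identical(test$doc_id, pred$doc_id)) return(FALSE)
  proteins_match(test$uniprot_ac, pred$uniprot_ac, policy) &&
    locations_match(test$go_id, pred$go_id, policy, ontology)
}

#' Precision, recall and F-measure from counts
#'
#' Percentages: `P = 100 * tp/(tp+fp)`, `R = 100 * tp/(tp+fn)`,
#' `F = 2PR/(P+R)`. A zero denominator yields 0 with the `degenerate` flag
#' set.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_measure`, `degenerate`.
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = p, recall = r, f_measure = f_measure(p, r),
         degenerate = degenerate)
}

#' Harmonic F-measure of a precision/recall pair
#'
#' @param p,r Precision and recall in percent.
#' @return `2pr/(p+r)` in percent; 0 when `p + r == 0`.
#' @export
f_measure <- function(p, r) {
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Score predicted relations against a gold corpus
#'
#' Both sides are first reduced to document-level unique normalized
#' relations ([unique_relations()]). Counting is per gold relation: a gold
#' relation is a true positive when at least one prediction matches it
#' (several matching predictions still count once); a prediction matching
#' no gold relation is a false positive; unmatched gold relations are
#' false negatives. Precision/recall/F come from the pooled counts.
#'
#' @param gold_unique,pred_unique Normalized relation tibbles as from
#'   [unique_relations()].
#' @param policy An [match_policy()].
#' @param ontology An `lx_ontology`.
#' @param docs Documents to score; defaults to those appearing on either
#'   side. Passing the full evaluated document set keeps documents with
#'   neither gold nor predicted relations as (zero-count) evaluation
#'   units, which matters for document-resampling bootstraps.
#' @return A list of class `lx_eval`: `counts` (pooled one-row [prf()]
#'   tibble) and `per_document` (per-doc tp/fp/fn tibble, the bootstrap
#'   sampling unit).
#' @export
evaluate_relations <- function(gold_unique, pred_unique,
                               policy = match_policy(), ontology = NULL,
                               docs = NULL) {
  docs <- docs %||% union(gold_unique$doc_id, pred_unique$doc_id)
  per_doc <- bind_rows(map(docs, function(doc) {
    g <- gold_unique[gold_unique$doc_id == doc, , drop = FALSE]
    p <- pred_unique[pred_unique$doc_id == doc, , drop = FALSE]
    matched_gold <- logical(nrow(g))
    pred_hit <- logical(nrow(p))
    for (j in seq_len(nrow(p))) {
      for (i in seq_len(nrow(g))) {
        if (proteins_match(g$uniprot_ac[i], p$uniprot_ac[j], policy) &&
            locations_match(g$go_id[i], p$go_id[j], policy, ontology)) {
          matched_gold[i] <- TRUE
          pred_hit[j] <- TRUE
        }
      }
    }
    tibble(doc_id = doc,
           tp = sum(matched_gold),
           fp = sum(!pred_hit),
           fn = sum(!matched_gold))
  }))
  if (is.null(per_doc) || nrow(per_doc) == 0) {
    per_doc <- tibble(doc_id = character(), tp = integer(), fp = integer(),
                      fn = integer())
  }
  structure(list(counts = prf(sum(per_doc$tp), sum(per_doc$fp),
                              sum(per_doc$fn)),
                 per_document = per_doc),
            class = "lx_eval")
}

#' @export
print.lx_eval <- function(x, ...) {
  c <- x$counts
  cat(sprintf("<lx_eval> tp=%d fp=%d fn=%d  P=%.1f%% R=%.1f%% F=%.1f%%\n",
              c$tp, c$fp, c$fn, c$precision, c$recall, c$f_measure))
  invisible(x)
}

#' Score predicted entities against gold entities
#'
#' A predicted entity is a true positive when its character span overlaps
#' (shares at least one position with) a gold entity of the same class in
#' the same document and their normalizations match: proteins via the
#' policy provider, locations via equality or the GO-descendant rule,
#' organisms via taxid equality. Each gold entity counts once; unmatched
#' predictions are false positives, unmatched gold entities false
#' negatives. Scores are reported per class and pooled.
#'
#' @param gold,pred Entity tibbles with `doc_id` columns.
#' @param policy An [match_policy()].
#' @param ontology An `lx_ontology`.
#' @return A tibble with one [prf()] row per `class` plus a `"total"` row.
#' @export
evaluate_ner <- function(gold, pred, policy = match_policy(),
                         ontology = NULL) {
  classes <- c("protein", "location", "organism")
  ids_match <- function(cl, gold_ids, pred_ids) {
    if (length(gold_ids) == 0 || length(pred_ids) == 0) return(FALSE)
    for (gi in gold_ids) {
      for (pi in pred_ids) {
        ok <- switch(cl,
                     protein = proteins_match(gi, pi, policy),
                     location = locations_match(gi, pi, policy, ontology),
                     organism = identical(gi, pi))
        if (ok) return(TRUE)
      }
    }
    FALSE
  }
  rows <- map(classes, function(cl) {
    g <- gold[gold$class == cl, , drop = FALSE]
    p <- pred[pred$class == cl, , drop = FALSE]
    matched_gold <- logical(nrow(g))
    pred_hit <- logical(nrow(p))
    for (j in seq_len(nrow(p))) {
      for (i in seq_len(nrow(g))) {
        if (!identical(g$doc_id[i], p$doc_id[j])) next
        overlap <- g$start[i] < p$end[j] && p$start[j] < g$end[i]
        if (overlap && ids_match(cl, g$norm_ids[[i]], p$norm_ids[[j]])) {
          matched_gold[i] <- TRUE
          pred_hit[j] <- TRUE
        }
      }
    }
    mutate(prf(sum(matched_gold), sum(!pred_hit), sum(!matched_gold)),
           class = cl, .before = 1)
  })
  per_class <- bind_rows(rows)
  total <- mutate(prf(sum(per_class$tp), sum(per_class$fp),
                      sum(per_class$fn)),
                  class = "total", .before = 1)
  bind_rows(per_class, total)
}

# The printed spread formula: sigma over bootstrap statistics around the
# whole-test-set value (not the bootstrap mean), with an n-1 denominator.
eq1_sigma <- function(x, overall) {
  n <- length(x)
  stopifnot(n >= 2)
  sqrt(sum((x - overall)^2) / (n - 1))
}

#' Bootstrap standard error of a test-set statistic
#'
#' Draws `n` bootstrap samples, each a without-replacement subset of
#' `ceiling(fraction * length(units))` evaluation units (documents),
#' recomputes the statistic on each, and reports the spread around the
#' whole-test-set value:
#' `sigma = sqrt(sum((x_i - overall)^2) / (n - 1))`,
#' `StdErr = sigma / sqrt(n)`. Note that `overall` is the statistic on the
#' entire test set, not the mean of the bootstrap replicates — a
#' deliberate, slightly unusual convention retained for comparability of
#' the reported error bars.
#'
#' @param units A list (or tibble split into rows) of evaluation units.
#' @param statistic `function(units_subset) -> numeric(1)`.
#' @param n Number of bootstrap samples (default 1000).
#' @param fraction Fraction of units per sample (default 0.15).
#' @param seed Integer seed; equal seeds give identical results.
#' @return A list of class `lx_bootstrap`: `overall`, `sigma`, `stderr`,
#'   `n`, `sample_fraction`, `seed`, `samples` (the replicate statistics).
#' @export
bootstrap_stderr <- function(units, statistic, n = 1000, fraction = 0.15,
                             seed = 1) {
  n_units <- if (is.data.frame(units)) nrow(units) else length(units)
  if (n_units < 1) abort("bootstrap needs a non-empty test set")
  if (n < 2) abort("bootstrap needs at least 2 samples")
  take <- function(idx) {
    if (is.data.frame(units)) units[idx, , drop = FALSE] else units[idx]
  }
  k <- max(1L, as.integer(ceiling(fraction * n_units)))
  overall <- statistic(take(seq_len(n_units)))
  xs <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      statistic(take(sample.int(n_units, k)))
    }, numeric(1))
  })
  sigma <- eq1_sigma(xs, overall)
  structure(list(overall = overall, sigma = sigma,
                 stderr = sigma / sqrt(n), n = n,
                 sample_fraction = fraction, seed = seed, samples = xs),
            class = "lx_bootstrap")
}

#' @export
print.lx_bootstrap <- function(x, ...) {
  cat(sprintf("<lx_bootstrap> overall=%.2f sigma=%.3f StdErr=%.3f (n=%d, %d%% samples)\n",
              x$overall, x$sigma, x$stderr, x$n,
              round(100 * x$sample_fraction)))
  invisible(x)
}
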