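#' 5-fold 60/20/20 document-level split plan
#'
#' Documents are shuffled once by `seed` and cut into five equal blocks.
#' Fold `i` tests on block `i`, cross-trains (validates) on the next block
#' cyclically, and trains on the remaining three — a 60/20/20 split in
#' which every document is tested exactly once across the five folds.
#' Splitting at the document level avoids leakage through repeated
#' mentions of the same relation within an abstract.
#'
#' @param corpus An `lx_corpus` with at least 5 documents.
#' @param seed Integer seed; equal seeds give identical plans.
#' @return An object of class `lx_fold_plan`: list of 5 folds, each with
#'   `train`, `validation`, `test` character vectors of `doc_id`s, plus
#'   `seed`.
#' @export
make_folds <- function(corpus, seed) {
  ids <- corpus$documents$doc_id
  n <- length(ids)
  if (n < 5) abort("cross-validation needs at least 5 documents")
  shuffled <- with_seed(seed, sample(ids))
  block <- sort(rep(1:5, length.out = n))  # sizes differ by at most 1
  folds <- map(1:5, function(i) {
    v <- if (i == 5) 1L else i + 1L
    list(test = shuffled[block == i],
         validation = shuffled[block == v],
         train = shuffled[!(block %in% c(i, v))])
  })
  structure(list(folds = folds, seed = seed), class = "lx_fold_plan")
}

#' @export
print.lx_fold_plan <- function(x, ...) {
  sizes <- map_chr(x$folds, function(f) {
    sprintf("%d/%d/%d", length(f$train), length(f$validation),
            length(f$test))
  })
  cat("<lx_fold_plan> train/validation/test sizes:",
      paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

# Linear SVM fit with weights extracted so that margin = Xw + b is
# positive for the "related" class. Falls back to a majority-sign
# intercept model when no feature columns survive selection.
train_svm <- function(X, y, cost = 1) {
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    abort("training needs both classes present")
  }
  if (ncol(X) == 0) {
    maj <- if (mean(y == "related") > 0.5) 1e-6 else -1e-6
    return(list(w = stats::setNames(numeric(0), character(0)), b = maj))
  }
  yfac <- factor(y, levels = c("related", "unrelated"))
  m <- e1071::svm(X, yfac, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  dv <- attr(stats::predict(m, X, decision.values = TRUE),
             "decision.values")
  ours <- drop(X %*% w) + b
  if (sum(ours * drop(dv)) < 0) {
    w <- -w; b <- -b
  }
  pos_class <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (pos_class != "related") {
    w <- -w; b <- -b
  }
  names(w) <- colnames(X)
  list(w = w, b = b)
}

#' Train a relation-extraction model
#'
#' The full training recipe on one document set: fit the count scaler,
#' extract sparse features, select features with the L1-penalized linear
#' classifier ([select_features_l1()], trade-off `c_select`), then refit a
#' linear-kernel SVM on the kept features (`c_final`). The two stages are
#' deliberately separate: the L1 pass is a selector, the final margin
#' model is an ordinary L2 SVM.
#'
#' @param candidates Labeled candidate tibble (training instances).
#' @param corpus An `lx_corpus`.
#' @param resources An [feature_resources()] (scaler is fitted here).
#' @param c_select L1 selection trade-off (default 2).
#' @param c_final Final SVM cost (default 1).
#' @param threshold Decision threshold on the margin; an instance is
#'   predicted related iff margin is strictly greater (default 0). Raising
#'   it trades recall for precision.
#' @param seed Integer recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return An object of class `lx_model`: kept feature names, weights,
#'   bias, threshold, fitted scaler, masking/count configuration, feature
#'   resources, and training metadata.
#' @export
lx_train <- function(candidates, corpus, resources = NULL,
                     c_select = 2, c_final = 1, threshold = 0, seed = NA) {
  resources <- resources %||% feature_resources()
  resources$scaler <- fit_count_scaler(candidates, corpus,
                                       resources$count_mode)
  X <- featurize_matrix(candidates, corpus, resources)
  sel <- select_features_l1(X, candidates$label, C = c_select)
  Xk <- X[, sel$kept, drop = FALSE]
  fit <- train_svm(Xk, candidates$label, cost = c_final)
  structure(list(kept = sel$kept,
                 w = fit$w, b = fit$b,
                 threshold = threshold,
                 selection = sel,
                 resources = resources,
                 metadata = list(seed = seed, c_select = c_select,
                                 c_final = c_final,
                                 n_train = nrow(candidates),
                                 n_features_full = ncol(X))),
            class = "lx_model")
}

#' @export
print.lx_model <- function(x, ...) {
  cat(sprintf(
    "<lx_model> linear SVM on %d L1-selected feature(s) (of %d), threshold=%g\n",
    length(x$kept), x$metadata$n_features_full %||% NA, x$threshold))
  invisible(x)
}

#' Predict relations for candidate instances
#'
#' Featurizes each candidate with the model's frozen scaler and feature
#' set and applies the linear decision function. An instance is predicted
#' `"related"` iff its margin strictly exceeds the model threshold (a
#' margin exactly at the threshold is unrelated).
#'
#' @param model An `lx_model`.
#' @param candidates Candidate tibble.
#' @param corpus An `lx_corpus`.
#' @return The candidate tibble plus `margin` and `predicted` columns;
#'   empty input gives an empty result.
#' @export
predict_relations <- function(model, candidates, corpus) {
  stopifnot(inherits(model, "lx_model"))
  if (nrow(candidates) == 0) {
    out <- candidates
    out$margin <- numeric(0)
    out$predicted <- character(0)
    return(out)
  }
  X <- featurize_matrix(candidates, corpus, model$resources,
                        feature_names = model$kept)
  margin <- if (length(model$w)) drop(X %*% model$w) + model$b else {
    rep(model$b, nrow(X))
  }
  candidates$margin <- margin
  candidates$predicted <- ifelse(margin > model$threshold,
                                 "related", "unrelated")
  candidates
}

#' Serialize / restore a relation model
#'
#' Models are written as a versioned JSON container carrying the weights,
#' threshold, scaler, configuration and the feature resources (marker
#' lexicon, annotation table, ontology terms and edges), so a reloaded
#' model reproduces the original's predictions exactly.
#'
#' @param model An `lx_model`.
#' @param path Output/input file path.
#' @return `write_model`: `path` invisibly. `read_model`: an `lx_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lx_model"))
  ont <- model$resources$ontology
  out <- list(
    format = "locrex-model", version = 1L,
    kept = as.list(model$kept),
    w = as.list(model$w), b = model$b, threshold = model$threshold,
    scaler = as.list(unclass(model$resources$scaler)),
    count_mode = model$resources$count_mode,
    mask_mode = model$resources$mask_mode,
    markers = as.list(model$resources$markers),
    swissprot = model$resources$swissprot,
    ontology = if (is.null(ont)) NULL else {
      list(terms = ont$terms, edges = ont$edges)
    },
    metadata = model$metadata)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(raw$format, "locrex-model")) {
    abort(paste0(path, " is not a locrex model file"))
  }
  scaler <- structure(unlist(raw$scaler), class = "lx_count_scaler")
  ontology <- if (!is.null(raw$ontology)) {
    new_ontology(as_tibble(raw$ontology$terms),
                 as_tibble(raw$ontology$edges))
  }
  resources <- feature_resources(
    scaler = scaler,
    markers = unlist(raw$markers),
    swissprot = as_tibble(raw$swissprot),
    ontology = ontology,
    count_mode = raw$count_mode,
    mask_mode = raw$mask_mode)
  kept <- as.character(unlist(raw$kept))
  w <- unlist(raw$w)
  if (is.null(w)) w <- stats::setNames(numeric(0), character(0))
  structure(list(kept = kept, w = w[kept], b = raw$b,
                 threshold = raw$threshold,
                 selection = NULL, resources = resources,
                 metadata = raw$metadata),
            class = "lx_model")
}

#' Cross-validated relation extraction
#'
#' Runs the full train/predict/aggregate/score loop under the
#' [make_folds()] plan: per fold, the model (or the co-mention baseline)
#' is fit on the train documents, the validation block is held for
#' optional tuning, and predictions are made on the test block only —
#' every document's prediction comes from a model that never saw it.
#' Predicted mention pairs are collapsed to document-level unique
#' normalized relations and scored against the gold relations of the same
#' documents with [evaluate_relations()].
#'
#' @param corpus An `lx_corpus` with gold entities and relations.
#' @param seed Integer seed driving the fold plan.
#' @param method `"svm"` (the learned extractor) or `"baseline"`
#'   (same-sentence co-mention).
#' @param max_distance Candidate sentence-distance cap (0 or 1).
#' @param resources An [feature_resources()] template.
#' @param ontology An `lx_ontology` for aggregation and matching.
#' @param policy An [match_policy()].
#' @param collapse_hierarchy Collapse GO-ancestor duplicates when
#'   aggregating (default `TRUE`).
#' @param c_select,c_final,threshold Passed to [lx_train()].
#' @return An object of class `lx_cv`: `per_fold` PRF tibble, `pooled`
#'   PRF row over summed counts, `per_document` counts (bootstrap units),
#'   `predictions` (document-level normalized relations), `plan`,
#'   `config`.
#' @export
cross_validate <- function(corpus, seed = 1, method = c("svm", "baseline"),
                           max_distance = 0, resources = NULL,
                           ontology = NULL, policy = match_policy(),
                           collapse_hierarchy = TRUE,
                           c_select = 2, c_final = 1, threshold = 0) {
  method <- match.arg(method)
  if (collapse_hierarchy && is.null(ontology)) {
    abort("collapse_hierarchy = TRUE requires an ontology")
  }
  plan <- make_folds(corpus, seed)
  resources <- resources %||% feature_resources(ontology = ontology)
  fold_rows <- list()
  per_doc <- list()
  preds_all <- list()
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    stopifnot(length(intersect(fold$train, fold$test)) == 0,
              length(intersect(fold$validation, fold$test)) == 0)
    if (method == "svm") {
      train_cand <- generate_candidates(corpus, max_distance,
                                        docs = fold$train)
      model <- lx_train(train_cand, corpus, resources,
                        c_select = c_select, c_final = c_final,
                        threshold = threshold, seed = seed)
      test_cand <- generate_candidates(corpus, max_distance,
                                       docs = fold$test)
      pred <- predict_relations(model, test_cand, corpus)
      pred_rel <- pred[pred$predicted == "related", , drop = FALSE]
    } else {
      pred_rel <- baseline_predict(corpus, docs = fold$test)
    }
    pred_unique <- unique_relations(
      corpus, relations = pred_rel[, c("doc_id", "protein_id",
                                       "location_id")],
      collapse_hierarchy = collapse_hierarchy, ontology = ontology)
    gold_unique <- unique_relations(
      corpus,
      relations = corpus$relations[
        corpus$relations$doc_id %in% fold$test, , drop = FALSE],
      collapse_hierarchy = collapse_hierarchy, ontology = ontology)
    ev <- evaluate_relations(gold_unique, pred_unique, policy, ontology,
                             docs = fold$test)
    fold_rows[[i]] <- mutate(ev$counts, fold = i, .before = 1)
    per_doc[[i]] <- ev$per_document
    preds_all[[i]] <- mutate(pred_unique, fold = i)
  }
  per_fold <- bind_rows(fold_rows)
  per_document <- bind_rows(per_doc)
  pooled <- prf(sum(per_fold$tp), sum(per_fold$fp), sum(per_fold$fn))
  structure(list(per_fold = per_fold, pooled = pooled,
                 per_document = per_document,
                 predictions = bind_rows(preds_all), plan = plan,
                 config = list(seed = seed, method = method,
                               max_distance = max_distance,
                               collapse_hierarchy = collapse_hierarchy,
                               c_select = c_select, c_final = c_final,
                               threshold = threshold)),
            class = "lx_cv")
}

#' @export
print.lx_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<lx_cv> %s, 5 folds: pooled P=%.1f%% R=%.1f%% F=%.1f%% (tp=%d fp=%d fn=%d)\n",
    x$config$method, p$precision, p$recall, p$f_measure, p$tp, p$fp, p$fn))
  invisible(x)
}

#' Bootstrap standard error of a cross-validation statistic
#'
#' Applies [bootstrap_stderr()] to the per-document evaluation counts of a
#' cross-validation run, resampling documents.
#'
#' @param cv An `lx_cv`.
#' @param measure `"precision"`, `"recall"` or `"f_measure"`.
#' @param n,fraction,seed See [bootstrap_stderr()].
#' @return An `lx_bootstrap`.
#' @export
cv_bootstrap <- function(cv, measure = c("f_measure", "precision", "recall"),
                         n = 1000, fraction = 0.15, seed = 1) {
  measure <- match.arg(measure)
  stat <- function(units) {
    prf(sum(units$tp), sum(units$fp), sum(units$fn))[[measure]]
  }
  bootstrap_stderr(cv$per_document, stat, n = n, fraction = fraction,
                   seed = seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a relation model: one row per kept feature
#'
#' @param x An `lx_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (SVM weight), `selector_weight` (L1
#'   stage weight, when available), plus an `(Intercept)` row.
#' @export
tidy.lx_model <- function(x, ...) {
  sel <- if (!is.null(x$selection)) x$selection$weights else NULL
  tb <- tibble(term = c(names(x$w), "(Intercept)"),
               estimate = c(unname(x$w), x$b))
  if (!is.null(sel)) {
    tb$selector_weight <- c(unname(sel[names(x$w)]), NA_real_)
  }
  arrange(tb, desc(abs(.data$estimate)))
}

#' One-row model summary
#'
#' @param x An `lx_model`.
#' @param ... Unused.
#' @return Tibble with feature counts and hyperparameters.
#' @export
glance.lx_model <- function(x, ...) {
  tibble(n_features = length(x$kept),
         n_features_full = x$metadata$n_features_full %||% NA_integer_,
         c_select = x$metadata$c_select %||% NA_real_,
         c_final = x$metadata$c_final %||% NA_real_,
         threshold = x$threshold,
         n_train = x$metadata$n_train %||% NA_integer_)
}

#' Per-fold cross-validation results
#'
#' @param x An `lx_cv`.
#' @param ... Unused.
#' @return The per-fold PRF tibble.
#' @export
tidy.lx_cv <- function(x, ...) as_tibble(x$per_fold)

#' Pooled cross-validation summary
#'
#' @param x An `lx_cv`.
#' @param ... Unused.
#' @return One-row tibble: pooled counts and PRF plus the run
#'   configuration.
#' @export
glance.lx_cv <- function(x, ...) {
  bind_cols(x$pooled,
            tibble(method = x$config$method, seed = x$config$seed,
                   max_distance = x$config$max_distance))
}

#' Plot per-fold precision/recall/F of a cross-validation run
#'
#' @param object An `lx_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lx_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold,
                              c("precision", "recall", "f_measure"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold),
                                     y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = "percent",
                  title = paste0("cross-validation (",
                                 object$config$method, ")")) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
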