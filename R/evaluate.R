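#' Stratified fold assignment
#'
#' Assigns each subject to one of `k` folds, shuffling within each class so
#' class balance is preserved fold-by-fold.
#'
#' @param labels Label factor/vector.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  pos <- as_positive(labels)
  if (min(sum(pos), sum(!pos)) < k) {
    pdb_stop("input_error",
             paste0("each class needs at least k = ", k, " members for stratified folds"))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(pos == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

feature_matrix <- function(table, features) {
  m <- as.matrix(table[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

## Pooled out-of-fold scores for one classifier on fixed folds.
oof_scores <- function(table, spec, features, folds) {
  x <- feature_matrix(table, features)
  y <- table$label
  scores <- numeric(nrow(x))
  for (f in sort(unique(folds))) {
    test <- folds == f
    fold_spec <- classifier_spec(spec$name, spec$hyperparameters,
                                 seed = derive_seed(spec$seed, f))
    model <- fit_classifier(fold_spec, x[!test, , drop = FALSE], y[!test])
    scores[test] <- predict_classifier(model, x[test, , drop = FALSE])
  }
  scores
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection with the given classifier as base model: start
#' from the empty set and at each step add the feature that maximizes the
#' pooled out-of-fold AUROC under stratified k-fold cross-validation; stop
#' when no candidate improves the AUROC by more than `tol`. Ties are broken
#' by canonical column order. Fold assignment is fixed once per call, so the
#' greedy path is deterministic at a fixed seed.
#'
#' @param table Feature table from [build_table()].
#' @param spec A [classifier_spec()] used as the base model.
#' @param k_folds Folds for the selection criterion (default 10).
#' @param seed Seed driving fold assignment and classifier fits.
#' @param tol Minimum AUROC improvement to accept a feature (default 1e-4).
#' @param max_features Optional cap on the number of selected features.
#' @param features Candidate columns (default: all feature columns present).
#' @return Character vector of selected features in selection order, with
#'   attribute `criterion`: the AUROC after each accepted step.
#' @export
sequential_forward_selection <- function(table, spec, k_folds = 10L, seed = 1L,
                                         tol = 1e-4, max_features = Inf,
                                         features = NULL) {
  validate_feature_table(table)
  if (is.null(features)) {
    features <- setdiff(names(table), c("subject_id", "label", "phonetic_score"))
  }
  if (length(features) < 2L) pdb_stop("input_error", "selection needs >= 2 candidate features")
  if (nlevels(droplevels(table$label)) < 2L) {
    pdb_stop("input_error", "selection needs both classes present")
  }
  folds <- stratified_folds(table$label, k_folds, seed = derive_seed(seed, 0L))
  selected <- character(0)
  path <- numeric(0)
  best <- -Inf
  repeat {
    candidates <- setdiff(features, selected)
    if (!length(candidates) || length(selected) >= max_features) break
    scores <- vapply(candidates, function(feat) {
      auroc(oof_scores(table, spec, c(selected, feat), folds), table$label)
    }, numeric(1))
    # ties broken by canonical column order (the order of `features`)
    top <- candidates[which.max(scores)]
    if (length(selected) == 0L || scores[top] > best + tol) {
      selected <- c(selected, top)
      best <- scores[top]
      path <- c(path, best)
    } else break
  }
  attr(selected, "criterion") <- path
  selected
}

#' Feature selection coverage across classifiers
#'
#' For each feature, the percentage of classifiers whose selected set
#' includes it, ranked descending (ties by canonical column order).
#'
#' @param selections Named list of character vectors (one per classifier).
#' @param feature_order Canonical feature ordering used for tie-breaking;
#'   defaults to first appearance across the selections.
#' @return Named numeric vector of coverage percentages, sorted descending.
#' @export
selection_coverage <- function(selections, feature_order = NULL) {
  if (!length(selections)) pdb_stop("input_error", "no selections supplied")
  if (is.null(feature_order)) feature_order <- unique(unlist(selections))
  if (!length(feature_order)) return(stats::setNames(numeric(0), character(0)))
  pct <- vapply(feature_order, function(f) {
    100 * mean(vapply(selections, function(s) f %in% s, logical(1)))
  }, numeric(1))
  pct[order(-pct, seq_along(pct))]
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation with pooled out-of-fold scores: AUROC
#' (rank/trapezoidal) with a stratified-bootstrap 95% CI, plus accuracy,
#' precision, recall and F1 at the 0.5 probability cutoff, and the ROC
#' points of the pooled scores.
#'
#' @inheritParams sequential_forward_selection
#' @param features Feature columns to use (default: all).
#' @param ci_reps Bootstrap replicates for the AUROC CI (default 2000; 0
#'   disables the CI).
#' @return List with elements `classifier`, `features`, `auroc`, `auroc_ci`,
#'   `accuracy`, `precision`, `recall`, `f1`, `roc`, `scores`, `folds`.
#' @export
cross_validated_evaluation <- function(table, spec, k_folds = 10L, seed = 1L,
                                       features = NULL, ci_reps = 2000L) {
  validate_feature_table(table)
  if (is.null(features)) {
    features <- setdiff(names(table), c("subject_id", "label", "phonetic_score"))
  }
  folds <- stratified_folds(table$label, k_folds, seed = derive_seed(seed, 0L))
  scores <- oof_scores(table, spec, features, folds)
  a <- auroc(scores, table$label)
  ci <- if (ci_reps > 0) {
    auroc_ci(scores, table$label, reps = ci_reps, seed = derive_seed(seed, 99L))
  } else c(NA_real_, NA_real_)
  cm <- classification_metrics(scores, table$label)
  c(list(classifier = spec$name, features = features, auroc = a,
         auroc_ci = ci), cm,
    list(roc = roc_points(scores, table$label), scores = scores, folds = folds))
}

#' Run the full selection + evaluation experiment
#'
#' For every classifier: sequential forward selection on the training table,
#' cross-validated training metrics on the selected features, then a refit
#' on the full training table and scoring of the held-out validation table
#' (the train-on-"on"-phase / validate-on-"off"-phase design). Also reports
#' the selection-coverage ranking across classifiers.
#'
#' @param train_table,validation_table Feature tables with identical feature
#'   columns and disjoint subject ids. `validation_table` may be NULL to
#'   skip external validation.
#' @param classifiers Character vector of registry names (default all nine).
#' @param k_folds CV folds (default 10).
#' @param seed Master seed; everything downstream derives from it.
#' @param select Run feature selection (default TRUE); if FALSE all features
#'   are used.
#' @param ci_reps Bootstrap replicates for AUROC CIs.
#' @param tol Selection stopping tolerance.
#' @return Object of class `evaluation_report`: list with `per_classifier`
#'   (one entry per classifier: selection, training CV metrics, validation
#'   metrics) and `coverage`.
#' @export
run_experiment <- function(train_table, validation_table = NULL,
                           classifiers = classifier_names(), k_folds = 10L,
                           seed = 1L, select = TRUE, ci_reps = 2000L,
                           tol = 1e-4) {
  validate_feature_table(train_table)
  feats <- setdiff(names(train_table), c("subject_id", "label", "phonetic_score"))
  if (!is.null(validation_table)) {
    validate_feature_table(validation_table)
    overlap <- intersect(train_table$subject_id, validation_table$subject_id)
    if (length(overlap)) {
      pdb_stop("leakage_error",
               paste0("train and validation share subjects: ",
                      paste(utils::head(overlap, 5L), collapse = ", ")))
    }
    if (!all(feats %in% names(validation_table))) {
      pdb_stop("input_error", "validation table lacks training feature columns")
    }
  }
  per <- list()
  for (i in seq_along(classifiers)) {
    nm <- classifiers[i]
    spec <- classifier_spec(nm, seed = derive_seed(seed, i))
    sel <- if (select) {
      sequential_forward_selection(train_table, spec, k_folds = k_folds,
                                   seed = derive_seed(seed, i, 1L), tol = tol,
                                   features = feats)
    } else feats
    cv <- cross_validated_evaluation(train_table, spec, k_folds = k_folds,
                                     seed = derive_seed(seed, i, 2L),
                                     features = as.character(sel),
                                     ci_reps = ci_reps)
    entry <- list(classifier = nm, selected_features = as.character(sel),
                  train_cv = cv)
    if (!is.null(validation_table)) {
      model <- fit_classifier(
        classifier_spec(nm, seed = derive_seed(seed, i, 3L)),
        feature_matrix(train_table, as.character(sel)), train_table$label)
      vscores <- predict_classifier(
        model, feature_matrix(validation_table, as.character(sel)))
      vcm <- classification_metrics(vscores, validation_table$label)
      entry$validation <- c(
        list(auroc = auroc(vscores, validation_table$label),
             roc = roc_points(vscores, validation_table$label),
             scores = vscores),
        vcm)
    }
    per[[nm]] <- entry
  }
  coverage <- selection_coverage(lapply(per, `[[`, "selected_features"),
                                 feature_order = feats)
  structure(list(per_classifier = per, coverage = coverage,
                 k_folds = k_folds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (e in x$per_classifier) {
    v <- if (!is.null(e$validation)) sprintf("  validation AUROC %.3f", e$validation$auroc) else ""
    cat(sprintf("  %-20s CV AUROC %.3f [%.3f, %.3f]%s  (%d features)\n",
                e$classifier, e$train_cv$auroc, e$train_cv$auroc_ci[1],
                e$train_cv$auroc_ci[2], v, length(e$selected_features)))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report` from [run_experiment()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  slim <- lapply(report$per_classifier, function(e) {
    out <- list(
      classifier = e$classifier,
      selected_features = e$selected_features,
      train_cv = list(auroc = e$train_cv$auroc,
                      auroc_ci = as.numeric(e$train_cv$auroc_ci),
                      accuracy = e$train_cv$accuracy,
                      precision = e$train_cv$precision,
                      recall = e$train_cv$recall,
                      f1 = e$train_cv$f1,
                      roc = e$train_cv$roc))
    if (!is.null(e$validation)) {
      out$validation <- list(auroc = e$validation$auroc,
                             accuracy = e$validation$accuracy,
                             precision = e$validation$precision,
                             recall = e$validation$recall,
                             f1 = e$validation$f1,
                             roc = e$validation$roc)
    }
    out
  })
  jsonlite::write_json(list(per_classifier = slim,
                            coverage = as.list(report$coverage)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
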