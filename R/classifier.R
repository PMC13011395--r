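# Random-forest diagnostics: repeated stratified cross-validation, AUC by
# rank statistic, impurity-based importance ranking, and feature-count
# performance curves with leak-free per-fold feature selection.

#' Cross-validation specification
#'
#' @param seed integer seed controlling fold assignment, bootstrap
#'   samples and feature sub-sampling; reports are bit-reproducible given
#'   (data, seed)
#' @param n_folds folds per repeat (default 5)
#' @param n_repeats repeats (default 5)
#' @param stratified keep class balance per fold (default `TRUE`)
#' @param n_trees trees per forest (default 500)
#' @param mtry features tried per split; default `floor(sqrt(p))`
#' @param min_node minimum node size to attempt a split (default 2)
#' @param pool_repeats if `TRUE`, AUC is computed on out-of-fold
#'   probabilities pooled per repeat instead of per fold
#' @return a `cv_spec` list
#' @export
cv_spec <- function(seed, n_folds = 5L, n_repeats = 5L, stratified = TRUE,
                    n_trees = 500L, mtry = NULL, min_node = 2L,
                    pool_repeats = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  structure(list(seed = as.integer(seed), n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 n_trees = as.integer(n_trees), mtry = mtry,
                 min_node = as.integer(min_node),
                 pool_repeats = isTRUE(pool_repeats)),
            class = "cv_spec")
}

#' Area under the ROC curve by rank statistic
#'
#' Equals the probability that a random positive outranks a random
#' negative; tied scores receive half credit.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (0/1 or logical)
#' @return AUC in `[0, 1]`
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC",
                               call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment using the current RNG stream
.make_folds <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

.rf_fit <- function(X, y, spec) {
  mtry <- spec$mtry %||% max(1L, floor(sqrt(ncol(X))))
  rf_fit_cpp(X, as.integer(y), spec$n_trees, as.integer(mtry),
             spec$min_node)
}

#' Repeated stratified cross-validated random-forest AUC
#'
#' For each repeat, samples are split into stratified folds; a forest is
#' trained on the training folds and out-of-fold probabilities are
#' scored. AUC is computed per fold (default) or on probabilities pooled
#' per repeat, then averaged. Feature importance (mean decrease in Gini
#' impurity) is averaged over all fits.
#'
#' @param X numeric feature matrix (samples x features, named)
#' @param y binary labels (0/1), length `nrow(X)`
#' @param spec a [cv_spec()]
#' @return list of class `classifier_report`: `auc_per_fold` (folds x
#'   repeats, or 1 x repeats when pooling), `mean_auc`,
#'   `importance_ranking` (`data.frame` ordered by decreasing score,
#'   covering all features), `spec`
#' @export
cross_validated_auc <- function(X, y, spec) {
  stopifnot(inherits(spec, "cv_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels contain a single class",
                                  call. = FALSE)
  if (min(table(y)) < 2) stop("need at least 2 samples per class",
                              call. = FALSE)
  with_seed(spec$seed, {
    k <- spec$n_folds
    aucs <- matrix(NA_real_, if (spec$pool_repeats) 1 else k,
                   spec$n_repeats)
    imp <- numeric(ncol(X))
    for (r in seq_len(spec$n_repeats)) {
      fold <- .make_folds(y, k, spec$stratified)
      oof <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- .rf_fit(X[tr, , drop = FALSE], y[tr], spec)
        oof[!tr] <- rf_predict_cpp(fit$forest, X[!tr, , drop = FALSE])
        imp <- imp + fit$importance
        if (!spec$pool_repeats) {
          te <- !tr
          if (length(unique(y[te])) == 2) {
            aucs[f, r] <- auc_rank(oof[te], y[te])
          }
        }
      }
      if (spec$pool_repeats) aucs[1, r] <- auc_rank(oof, y)
    }
    imp <- imp / (spec$n_repeats * k)
    feat <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
    ord <- order(-imp, feat)
    structure(list(
      auc_per_fold = aucs,
      mean_auc = mean(aucs, na.rm = TRUE),
      importance_ranking = data.frame(feature = feat[ord],
                                      importance = imp[ord],
                                      stringsAsFactors = FALSE),
      spec = spec
    ), class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: mean CV AUC = %.3f (%d x %d CV, %d trees)\n",
              x$mean_auc, x$spec$n_folds, x$spec$n_repeats, x$spec$n_trees))
  invisible(x)
}

#' AUC versus number of top-ranked features
#'
#' Leak-free protocol: within each training fold, features are ranked by
#' impurity importance of a forest fit on the training data only; for
#' each `k`, a forest is retrained on the top-k features and scored on
#' the held-out fold. `k` larger than the feature count is clamped with a
#' warning.
#'
#' @param X,y,spec as in [cross_validated_auc()]
#' @param ks integer vector of feature counts
#' @return `data.frame` with columns `k` and `mean_auc`
#' @export
feature_count_curve <- function(X, y, spec, ks) {
  stopifnot(inherits(spec, "cv_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(ks > ncol(X))) {
    warning("k > number of features; clamped")
    ks <- pmin(ks, ncol(X))
  }
  ks <- sort(unique(as.integer(ks)))
  with_seed(spec$seed, {
    k_folds <- spec$n_folds
    aucs <- array(NA_real_, c(length(ks), k_folds, spec$n_repeats))
    for (r in seq_len(spec$n_repeats)) {
      fold <- .make_folds(y, k_folds, spec$stratified)
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        rank_fit <- .rf_fit(X[tr, , drop = FALSE], y[tr], spec)
        ord <- order(-rank_fit$importance,
                     colnames(X) %||% seq_len(ncol(X)))
        for (ki in seq_along(ks)) {
          top <- ord[seq_len(ks[ki])]
          fit <- .rf_fit(X[tr, top, drop = FALSE], y[tr], spec)
          pr <- rf_predict_cpp(fit$forest, X[!tr, top, drop = FALSE])
          if (length(unique(y[!tr])) == 2) {
            aucs[ki, f, r] <- auc_rank(pr, y[!tr])
          }
        }
      }
    }
    data.frame(k = ks,
               mean_auc = apply(aucs, 1, mean, na.rm = TRUE))
  })
}

#' Virus-only, bacteria-only and combined diagnostic models
#'
#' The combined table is the column concatenation of the two feature
#' blocks; importance rankings carry a `class` column (`virus` /
#' `bacterium`) so cross-kingdom dominance among top predictors can be
#' tabulated. An empty bacterial table degrades to the virus-only model.
#'
#' @param X_virus,X_bacteria numeric matrices with identical rownames
#'   (sample ids)
#' @param y binary labels
#' @param spec a [cv_spec()]
#' @return list with `virus`, `bacteria` (`NULL` if the table is empty)
#'   and `combined` classifier reports
#' @export
combined_model <- function(X_virus, X_bacteria, y, spec) {
  X_virus <- as.matrix(X_virus)
  X_bacteria <- as.matrix(X_bacteria)
  if (ncol(X_bacteria) > 0 &&
      !identical(rownames(X_virus), rownames(X_bacteria))) {
    bad <- union(setdiff(rownames(X_virus), rownames(X_bacteria)),
                 setdiff(rownames(X_bacteria), rownames(X_virus)))
    stop("sample mismatch between feature tables: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tag <- function(report, classes) {
    report$importance_ranking$class <-
      classes[report$importance_ranking$feature]
    report
  }
  cls_v <- setNames(rep("virus", ncol(X_virus)), colnames(X_virus))
  virus <- tag(cross_validated_auc(X_virus, y, spec), cls_v)
  if (ncol(X_bacteria) == 0) {
    return(list(virus = virus, bacteria = NULL, combined = virus))
  }
  cls_b <- setNames(rep("bacterium", ncol(X_bacteria)), colnames(X_bacteria))
  bacteria <- tag(cross_validated_auc(X_bacteria, y, spec), cls_b)
  Xc <- cbind(X_virus, X_bacteria)
  combined <- tag(cross_validated_auc(Xc, y, spec), c(cls_v, cls_b))
  list(virus = virus, bacteria = bacteria, combined = combined)
}
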