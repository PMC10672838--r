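#' Evaluate one classifier over the outer cross-validation plan
#'
#' For every outer fold the classifier is fit on the training genomes
#' restricted to `feature_set`, then evaluated on the held-out genomes:
#' train/test precision, recall and F1, test accuracy, AUROC, AUPR and MCC,
#' plus the nested-CV panel -- the mean accuracy of a stratified
#' `plan$inner_folds`-fold cross-validation run entirely inside the training
#' portion (the held-out fold never contributes). A per-classifier mean row
#' (`fold = "mean"`) is appended. A fit failure on degenerate data yields an
#' all-NA metrics row and the run continues.
#'
#' @param pm a [presence_matrix()].
#' @param feature_set character vector of family ids (non-empty subset of
#'   the matrix families).
#' @param plan a [make_outer_folds()] plan on the same genomes.
#' @param clf classifier id (see `CLASSIFIER_IDS`).
#' @param seed integer seed for classifier-internal randomness.
#' @param nested whether to compute the nested inner-CV accuracy panel
#'   (default TRUE).
#' @param feature_set_name label recorded in the output rows.
#' @return data.frame, one row per fold plus the mean row, with columns
#'   classifier, feature_set, fold, train_precision, train_recall, train_f1,
#'   test_precision, test_recall, test_f1, nested_cv_accuracy, auroc, aupr,
#'   mcc.
#' @export
evaluate_classifier <- function(pm, feature_set, plan, clf, seed = 1L,
                                nested = TRUE, feature_set_name = "set") {
  stopifnot(inherits(pm, "presence_matrix"), inherits(plan, "cv_plan"))
  if (!length(feature_set)) stopf("feature_set is empty")
  miss <- setdiff(feature_set, family_ids(pm))
  if (length(miss)) stopf("feature_set contains unknown families: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  x <- pm$bits[, feature_set, drop = FALSE]
  y <- pm$labels
  fold <- plan$fold[genome_ids(pm)]

  one_fold <- function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- tryCatch(
      fit_classifier(clf, x[tr, , drop = FALSE], y[tr],
                     seed = derive_seed(seed, clf, f)),
      error = function(e) {
        warnf("%s failed on fold %d: %s", clf, f, conditionMessage(e))
        NULL
      })
    na_row <- rep(NA_real_, 10)
    names(na_row) <- c("train_precision", "train_recall", "train_f1",
                       "test_precision", "test_recall", "test_f1",
                       "nested_cv_accuracy", "auroc", "aupr", "mcc")
    if (is.null(fit)) return(na_row)
    pr_tr <- predict_classifier(fit, x[tr, , drop = FALSE])
    pr_te <- predict_classifier(fit, x[te, , drop = FALSE])
    m_tr <- compute_metrics(y[tr], pr_tr$label, pr_tr$score)
    m_te <- compute_metrics(y[te], pr_te$label, pr_te$score)
    nest <- if (nested)
      nested_cv_accuracy(x[tr, , drop = FALSE], y[tr], clf,
                         plan$inner_folds, derive_seed(seed, clf, f, "inner"))
    else NA_real_
    c(train_precision = unname(m_tr["precision"]),
      train_recall = unname(m_tr["recall"]),
      train_f1 = unname(m_tr["f1"]),
      test_precision = unname(m_te["precision"]),
      test_recall = unname(m_te["recall"]),
      test_f1 = unname(m_te["f1"]),
      nested_cv_accuracy = nest,
      auroc = unname(m_te["auroc"]),
      aupr = unname(m_te["aupr"]),
      mcc = unname(m_te["mcc"]))
  }

  rows <- t(vapply(seq_len(plan$k), one_fold, numeric(10)))
  means <- colMeans(rows, na.rm = TRUE)
  out <- data.frame(classifier = clf, feature_set = feature_set_name,
                    fold = c(as.character(seq_len(plan$k)), "mean"),
                    rbind(rows, means), row.names = NULL)
  out
}

# Mean accuracy of a stratified k-fold CV run inside one training portion.
nested_cv_accuracy <- function(x, y, clf, k, seed) {
  k <- min(k, min(table(y)))
  if (k < 2) return(NA_real_)
  assign <- inner_fold_assign(y, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- assign != f; te <- assign == f
    fit <- tryCatch(fit_classifier(clf, x[tr, , drop = FALSE], y[tr],
                                   seed = derive_seed(seed, "nested", f)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- predict_classifier(fit, x[te, , drop = FALSE])$label
    mean(pred == y[te])
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Benchmark classifiers over All / Intersection / Random feature sets
#'
#' Runs [evaluate_classifier()] for every requested classifier on the full
#' feature list (`All`), on the consensus `Intersection` set, and on each of
#' the matched-size `Random` sets; Random rows are reported per set
#' (feature_set `Random1`..`RandomN`) and as the across-set average of the
#' per-classifier means (`Random_mean` rows).
#'
#' @param pm a [presence_matrix()].
#' @param sets a `feature_sets` object from [build_feature_sets()], or a
#'   named list with elements `all_set`, `intersection_set`, `random_sets`.
#' @param plan a [make_outer_folds()] plan.
#' @param classifiers character vector of classifier ids (default: all 12).
#' @param seed integer seed.
#' @param nested compute the nested inner-CV accuracy panel (default TRUE).
#' @return object of class `ppa_benchmark`: a data.frame of metric rows
#'   with the attributes `classifiers` and `seed`.
#' @export
benchmark_feature_sets <- function(pm, sets, plan,
                                   classifiers = CLASSIFIER_IDS,
                                   seed = 1L, nested = TRUE) {
  classifiers <- match.arg(classifiers, CLASSIFIER_IDS, several.ok = TRUE)
  jobs <- c(list(All = sets$all_set),
            if (length(sets$intersection_set))
              list(Intersection = sets$intersection_set),
            stats::setNames(sets$random_sets,
                            paste0("Random", seq_along(sets$random_sets))))
  rows <- list()
  for (clf in classifiers) {
    for (nm in names(jobs)) {
      rows[[paste(clf, nm)]] <- evaluate_classifier(
        pm, jobs[[nm]], plan, clf, seed = seed, nested = nested,
        feature_set_name = nm)
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # average the per-classifier mean rows over the random sets
  rnd <- res[grepl("^Random", res$feature_set) & res$fold == "mean", ]
  if (nrow(rnd)) {
    metric_cols <- setdiff(names(res), c("classifier", "feature_set", "fold"))
    agg <- stats::aggregate(rnd[metric_cols], by = list(classifier = rnd$classifier),
                            FUN = mean, na.rm = TRUE)
    agg <- data.frame(classifier = agg$classifier, feature_set = "Random_mean",
                      fold = "mean", agg[metric_cols])
    res <- rbind(res, agg)
  }
  structure(res, class = c("ppa_benchmark", "data.frame"),
            classifiers = classifiers, seed = seed)
}

#' @export
print.ppa_benchmark <- function(x, ...) {
  cat(sprintf("ppa_benchmark: %d classifiers x %s feature sets\n",
              length(attr(x, "classifiers")),
              length(unique(x$feature_set))))
  print(summary(x))
  invisible(x)
}

#' Summarize a benchmark as the per-classifier mean metric grid
#' @param object a `ppa_benchmark`.
#' @param feature_set which feature-set rows to tabulate (default all).
#' @param ... unused.
#' @export
summary.ppa_benchmark <- function(object, feature_set = NULL, ...) {
  m <- object[object$fold == "mean", ]
  m <- m[!grepl("^Random[0-9]", m$feature_set), ]
  if (!is.null(feature_set)) m <- m[m$feature_set %in% feature_set, ]
  cols <- c("classifier", "feature_set", "test_precision", "test_recall",
            "test_f1", "nested_cv_accuracy", "auroc", "aupr", "mcc")
  out <- m[order(m$feature_set, m$classifier), cols]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Write benchmark results as long- and wide-format TSV
#' @param bench a `ppa_benchmark`.
#' @param long_path long format (classifier, feature_set, fold, metric, value).
#' @param wide_path wide per-fold grid (optional).
#' @export
write_benchmark_tsv <- function(bench, long_path, wide_path = NULL) {
  metric_cols <- setdiff(names(bench), c("classifier", "feature_set", "fold"))
  long <- do.call(rbind, lapply(metric_cols, function(mc)
    data.frame(classifier = bench$classifier, feature_set = bench$feature_set,
               fold = bench$fold, metric = mc, value = bench[[mc]])))
  write_tsv(long[order(long$classifier, long$feature_set, long$fold,
                       long$metric), ], long_path)
  if (!is.null(wide_path)) write_tsv(as.data.frame(bench), wide_path)
  invisible(long_path)
}
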