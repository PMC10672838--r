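#' Rank feature importances per outer fold
#'
#' For each outer fold, the classifier is fit on the training genomes only
#' and every feature receives an importance score: either the classifier's
#' native importance (coefficient magnitude or impurity gain; see
#' [native_importance()]) or model-agnostic permutation importance -- the
#' mean drop in training F1 over `n_repeats` random shuffles of the feature
#' column. Requesting `method = "native"` for a classifier without native
#' importances (gNB, SVM, KNN) falls back to permutation with a message.
#' The held-out fold of each round never contributes to its ranking.
#'
#' @param pm a [presence_matrix()].
#' @param plan a [make_outer_folds()] plan.
#' @param clf classifier id.
#' @param method "native" or "permutation".
#' @param seed integer seed.
#' @param n_repeats shuffles per feature for permutation importance.
#' @return list of `plan$k` data.frames (class `importance_ranking`), each
#'   with columns fold, classifier, rank, family_id, score, sorted by
#'   score descending with ties broken by family id.
#' @export
rank_importances <- function(pm, plan, clf, method = c("native", "permutation"),
                             seed = 1L, n_repeats = 10) {
  method <- match.arg(method)
  stopifnot(inherits(pm, "presence_matrix"), inherits(plan, "cv_plan"))
  clf <- match.arg(clf, CLASSIFIER_IDS)
  x <- pm$bits
  y <- pm$labels
  fold <- plan$fold[genome_ids(pm)]

  lapply(seq_len(plan$k), function(f) {
    tr <- which(fold != f)
    fit <- fit_classifier(clf, x[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, "rank", clf, f))
    scores <- NULL
    if (method == "native") {
      scores <- native_importance(fit)
      if (is.null(scores)) {
        message(sprintf(
          "%s has no native importances; falling back to permutation", clf))
      }
    }
    if (is.null(scores))
      scores <- permutation_importance(fit, x[tr, , drop = FALSE], y[tr],
                                       n_repeats,
                                       derive_seed(seed, "perm", clf, f))
    ord <- order(-scores, names(scores))   # stable: score desc, id asc
    structure(data.frame(fold = f, classifier = clf,
                         rank = seq_along(scores),
                         family_id = names(scores)[ord],
                         score = unname(scores[ord]),
                         stringsAsFactors = FALSE),
              class = c("importance_ranking", "data.frame"))
  })
}

#' Permutation importance: mean F1 drop under column shuffles
#'
#' @param fit a fitted `panphen_fit`.
#' @param x,y the (training) data the fit saw.
#' @param n_repeats shuffles per feature.
#' @param seed integer seed.
#' @return named numeric vector of importances (floored at 0 internally
#'   by rank ordering; raw mean drops are returned, may be negative).
#' @export
permutation_importance <- function(fit, x, y, n_repeats = 10, seed = 1L) {
  base <- compute_metrics(y, predict_classifier(fit, x)$label)["f1"]
  set.seed(seed)
  drops <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- x[sample(nrow(x)), j]
      base - compute_metrics(y, predict_classifier(fit, xp)$label)["f1"]
    }, 0))
  }, 0)
  stats::setNames(drops, colnames(x))
}

#' Consensus Intersection Set across the outer folds
#'
#' The features appearing in the top `top_k` of every fold's ranking,
#' ordered by ascending mean rank. An empty intersection is returned empty
#' with a warning; downstream evaluation refuses empty sets.
#'
#' @param rankings list of per-fold rankings from [rank_importances()]
#'   (one per outer fold).
#' @param top_k per-fold cutoff defining "important" (default 50).
#' @return character vector of family ids.
#' @export
intersection_set <- function(rankings, top_k = 50) {
  stopifnot(length(rankings) >= 2)
  tops <- lapply(rankings, function(r) r$family_id[seq_len(min(top_k, nrow(r)))])
  inter <- Reduce(intersect, tops)
  if (!length(inter)) {
    warnf("empty intersection at top_k = %d", top_k)
    return(character())
  }
  mean_rank <- sapply(inter, function(f)
    mean(vapply(rankings, function(r) r$rank[match(f, r$family_id)], 0)))
  inter[order(mean_rank, inter)]
}

#' Matched-size Random Sets
#'
#' Draws `n_sets` feature sets of the given size uniformly without
#' replacement from the full feature list, independently per set. Matched
#' random sets are the null reference for the Intersection Set: equal size,
#' no selection.
#'
#' @param all_features character vector (the All Set).
#' @param size features per set (= Intersection Set size).
#' @param n_sets number of sets (default 10).
#' @param seed integer seed.
#' @return list of `n_sets` character vectors.
#' @export
random_sets <- function(all_features, size, n_sets = 10, seed = 1L) {
  if (size > length(all_features))
    stopf("requested set size %d exceeds feature count %d",
          size, length(all_features))
  if (size < 1) stopf("set size must be >= 1")
  set.seed(derive_seed(seed, "random-sets"))
  lapply(seq_len(n_sets), function(i) sample(all_features, size))
}

#' Build the All / Intersection / Random feature-set bundle
#'
#' Convenience wrapper: ranks importances per fold, intersects the top
#' `top_k`, and draws the matched-size random sets.
#'
#' @param pm a [presence_matrix()].
#' @param plan a [make_outer_folds()] plan.
#' @param clf classifier whose importances define the ranking (default RF).
#' @param method importance method, "native" or "permutation".
#' @param top_k per-fold cutoff (default 50).
#' @param n_random number of random sets (default 10).
#' @param seed integer seed.
#' @return object of class `feature_sets`: list with `all_set`,
#'   `intersection_set`, `random_sets`, `top_k`, `rankings`.
#' @export
build_feature_sets <- function(pm, plan, clf = "RF",
                               method = c("native", "permutation"),
                               top_k = 50, n_random = 10, seed = 1L) {
  method <- match.arg(method)
  rankings <- rank_importances(pm, plan, clf, method, seed = seed)
  inter <- intersection_set(rankings, top_k)
  rnd <- if (length(inter))
    random_sets(family_ids(pm), length(inter), n_random, seed)
  else list()
  structure(list(all_set = family_ids(pm), intersection_set = inter,
                 random_sets = rnd, top_k = top_k, rankings = rankings,
                 rank_classifier = clf, method = method, seed = seed),
            class = "feature_sets")
}

#' @export
print.feature_sets <- function(x, ...) {
  cat(sprintf("feature_sets: All = %d, Intersection = %d (top_k = %d, %s/%s), %d random sets\n",
              length(x$all_set), length(x$intersection_set), x$top_k,
              x$rank_classifier, x$method, length(x$random_sets)))
  invisible(x)
}

#' Write rankings and feature sets to disk
#' @param sets a `feature_sets` object.
#' @param rankings_path TSV of per-fold rankings.
#' @param sets_path JSON of the three set kinds plus top_k/seed.
#' @export
write_feature_sets <- function(sets, rankings_path, sets_path) {
  write_tsv(do.call(rbind, sets$rankings), rankings_path)
  jsonlite::write_json(
    list(all_set = sets$all_set, intersection_set = sets$intersection_set,
         random_sets = sets$random_sets, top_k = sets$top_k,
         rank_classifier = sets$rank_classifier, method = sets$method,
         seed = sets$seed),
    sets_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(sets_path)
}
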