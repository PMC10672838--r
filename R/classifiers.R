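# Uniform wrappers around the twelve benchmarked classifiers.
#
# Each wrapper takes a numeric feature matrix x (genomes x families, binary
# in this package) and an integer 0/1 label vector y, and returns an object
# carrying everything predict_classifier() needs. Scores are oriented so
# larger means more confident in class 1 (the positive class): class-1
# probability where the model has one, a decision value for SVM/LDA, and the
# weighted margin for AdaBoost. Hyperparameters follow the wrapped
# libraries' own defaults (500 trees for randomForest and ranger, cost 1 for
# e1071's SVM, 100 rounds of depth-3 boosting, k = 5 neighbours, 50 AdaBoost
# stumps, 10 bagging replicates); they are recorded in the run manifest.
# Gini importance rankings in particular need the full-size forest to
# stabilise over many near-equivalent binary features.
#
# Feature columns are renamed f1..fp internally so formula interfaces never
# choke on family ids; importances are mapped back to family ids.

#' The twelve benchmark classifier identifiers
#' @export
CLASSIFIER_IDS <- c("logR", "gNB", "SVM", "DT", "RF", "KNN",
                    "LDA", "mNB", "ABC", "GBC", "ETC", "BC")

safe_x <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  list(x = `colnames<-`(x, paste0("f", seq_len(ncol(x)))),
       features = colnames(x))
}

#' Fit one of the twelve benchmark classifiers
#'
#' @param clf classifier id, one of `CLASSIFIER_IDS`.
#' @param x numeric feature matrix (samples x features).
#' @param y integer 0/1 labels (1 = positive class).
#' @param seed integer seed controlling all classifier-internal randomness.
#' @return object of class `panphen_fit`.
#' @export
fit_classifier <- function(clf, x, y, seed = 1L) {
  clf <- match.arg(clf, CLASSIFIER_IDS)
  s <- safe_x(x); x <- s$x
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% 0:1))
  set.seed(derive_seed(seed, "fit", clf))
  if (length(unique(y)) < 2) {
    fit <- list(kind = "constant", level = unique(y))
  } else {
    fit <- switch(clf,
      logR = fit_logR(x, y), gNB = fit_gnb(x, y), SVM = fit_svm(x, y),
      DT = fit_dt(x, y), RF = fit_rf(x, y), KNN = fit_knn(x, y),
      LDA = fit_lda2(x, y), mNB = fit_mnb(x, y), ABC = fit_adaboost(x, y),
      GBC = fit_gbc(x, y), ETC = fit_etc(x, y), BC = fit_bagging(x, y))
  }
  structure(c(fit, list(clf = clf, features = s$features, seed = seed)),
            class = "panphen_fit")
}

#' Predict labels and positive-class scores
#' @param fit a `panphen_fit` from [fit_classifier()].
#' @param x feature matrix with the same columns as at fit time.
#' @return data.frame with columns `label` (0/1) and `score`.
#' @export
predict_classifier <- function(fit, x) {
  stopifnot(inherits(fit, "panphen_fit"))
  s <- safe_x(x); x <- s$x
  if (identical(fit$kind, "constant"))
    return(data.frame(label = rep(fit$level, nrow(x)),
                      score = rep(as.numeric(fit$level), nrow(x))))
  set.seed(derive_seed(fit$seed, "predict", fit$clf, nrow(x)))
  out <- fit$predict(fit, x)
  data.frame(label = as.integer(out$label), score = as.numeric(out$score))
}

#' Native feature importances, if the classifier has them
#'
#' Coefficient magnitudes for the linear models (logR, LDA, mNB log-odds),
#' impurity importances for the tree ensembles (DT, RF, ETC, GBC, ABC, BC).
#'
#' @param fit a `panphen_fit`.
#' @return named numeric vector over the original feature ids, or NULL when
#'   the classifier exposes no native importance (gNB, SVM, KNN).
#' @export
native_importance <- function(fit) {
  stopifnot(inherits(fit, "panphen_fit"))
  if (identical(fit$kind, "constant") || is.null(fit$importance)) return(NULL)
  imp <- fit$importance(fit)
  full <- stats::setNames(numeric(length(fit$features)),
                          paste0("f", seq_along(fit$features)))
  imp <- imp[names(imp) %in% names(full)]
  full[names(imp)] <- imp
  stats::setNames(pmax(full, 0), fit$features)
}

# ---- individual classifiers -------------------------------------------

# Logistic regression with L2 ridge penalty (lambda = 1/n, the C = 1
# convention); glmnet needs >= 2 columns, so a constant dummy is appended
# for single-feature sets.
fit_logR <- function(x, y) {
  xx <- if (ncol(x) == 1) cbind(x, .dummy = 0) else x
  # small CV folds trip glmnet's class-size advisory on every fit
  model <- suppressWarnings(
    glmnet::glmnet(xx, factor(y, levels = 0:1), family = "binomial",
                   alpha = 0, lambda = 1 / nrow(xx), standardize = FALSE))
  list(kind = "logR", model = model, pad = ncol(x) == 1,
    predict = function(fit, x) {
      if (fit$pad) x <- cbind(x, .dummy = 0)
      p <- as.numeric(stats::predict(fit$model, x, type = "response"))
      list(label = as.integer(p > 0.5), score = p)
    },
    importance = function(fit) {
      co <- abs(as.matrix(stats::coef(fit$model))[-1, 1])
      co[names(co) != ".dummy"]
    })
}

# Gaussian naive Bayes with additive variance smoothing, so that
# zero-variance (within-class constant) binary features stay usable.
fit_gnb <- function(x, y) {
  eps <- 1e-9 * max(apply(x, 2, stats::var), 1e-12)
  stats_by <- lapply(0:1, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mu = colMeans(xc),
         var = apply(xc, 2, function(v) mean((v - mean(v))^2)) + eps,
         logprior = log(nrow(xc) / nrow(x)))
  })
  list(kind = "gNB", stats = stats_by,
    predict = function(fit, x) {
      ll <- vapply(fit$stats, function(s) {
        rowSums(sweep(-(sweep(x, 2, s$mu)^2), 2, 2 * s$var, "/") -
                  matrix(0.5 * log(2 * pi * s$var), nrow(x), ncol(x),
                         byrow = TRUE)) + s$logprior
      }, numeric(nrow(x)))
      ll <- matrix(ll, ncol = 2)
      p1 <- 1 / (1 + exp(ll[, 1] - ll[, 2]))
      list(label = as.integer(p1 > 0.5), score = p1)
    },
    importance = NULL)
}

fit_svm <- function(x, y) {
  model <- e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                      cost = 1, scale = FALSE)
  list(kind = "SVM", model = model,
    predict = function(fit, x) {
      pr <- stats::predict(fit$model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients decision values towards the first level named in the
      # column label; flip so larger always means class 1
      score <- if (grepl("^1", colnames(dv)[1])) dv[, 1] else -dv[, 1]
      list(label = as.integer(as.character(pr)), score = score)
    },
    importance = NULL)
}

rpart_full <- function(df, weights = NULL, maxdepth = 30) {
  # no surrogates/competes: binary complete data, and they dominate runtime
  rpart::rpart(y ~ ., df, weights = weights, method = "class",
               control = rpart::rpart.control(minsplit = 2, cp = 0,
                                              maxdepth = maxdepth,
                                              xval = 0, maxcompete = 0,
                                              maxsurrogate = 0,
                                              usesurrogate = 0))
}

rpart_importance <- function(model) {
  vi <- model$variable.importance
  if (is.null(vi)) stats::setNames(numeric(0), character(0)) else vi
}

fit_dt <- function(x, y) {
  df <- data.frame(x, y = factor(y, levels = 0:1))
  model <- rpart_full(df)
  list(kind = "DT", model = model,
    predict = function(fit, x) {
      p <- stats::predict(fit$model, data.frame(x), type = "prob")[, "1"]
      list(label = as.integer(p > 0.5), score = p)
    },
    importance = function(fit) rpart_importance(fit$model))
}

fit_rf <- function(x, y) {
  model <- randomForest::randomForest(x, factor(y, levels = 0:1),
                                      ntree = 500, importance = FALSE)
  list(kind = "RF", model = model,
    predict = function(fit, x) {
      p <- stats::predict(fit$model, x, type = "prob")[, "1"]
      list(label = as.integer(p > 0.5), score = p)
    },
    importance = function(fit)
      randomForest::importance(fit$model)[, "MeanDecreaseGini"])
}

fit_knn <- function(x, y, k = 5) {
  k <- min(k, nrow(x))
  list(kind = "KNN", train = x, y = y, k = k,
    predict = function(fit, x) {
      pr <- class::knn(fit$train, x, factor(fit$y, levels = 0:1),
                       k = fit$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      lab <- as.integer(as.character(pr))
      p1 <- ifelse(lab == 1, p_win, 1 - p_win)
      list(label = lab, score = p1)
    },
    importance = NULL)
}

# Two-class Fisher linear discriminant on a ridge-regularized pooled
# covariance: behaves like classical LDA on well-conditioned data and stays
# defined (and discriminative) when features are constant within classes or
# p > n -- binary pan-genome matrices are routinely both, and a plain
# pseudoinverse would project the discriminative direction away whenever it
# lies in the null space of the within-class scatter.
fit_lda2 <- function(x, y) {
  mu0 <- colMeans(x[y == 0, , drop = FALSE])
  mu1 <- colMeans(x[y == 1, , drop = FALSE])
  centered <- x - rbind(mu0, mu1)[y + 1, , drop = FALSE]
  sigma <- crossprod(centered) / max(nrow(x) - 2, 1)
  lambda <- 1e-6 * mean(diag(sigma)) + 1e-10
  w <- solve(sigma + diag(lambda, ncol(x)), mu1 - mu0)
  thr <- 0.5 * sum(w * (mu1 + mu0)) - log(sum(y == 1) / sum(y == 0))
  list(kind = "LDA", w = as.numeric(w), thr = thr,
    predict = function(fit, x) {
      s <- as.numeric(x %*% fit$w) - fit$thr
      list(label = as.integer(s > 0), score = s)
    },
    importance = function(fit)
      stats::setNames(abs(fit$w), paste0("f", seq_along(fit$w))))
}

# Multinomial naive Bayes with Laplace (add-one) smoothing on feature counts.
fit_mnb <- function(x, y) {
  logtheta <- vapply(0:1, function(cl) {
    cnt <- colSums(x[y == cl, , drop = FALSE]) + 1
    log(cnt / sum(cnt))
  }, numeric(ncol(x)))
  logprior <- log(c(sum(y == 0), sum(y == 1)) / length(y))
  list(kind = "mNB", logtheta = logtheta, logprior = logprior,
    predict = function(fit, x) {
      ll <- x %*% fit$logtheta +
        matrix(fit$logprior, nrow(x), 2, byrow = TRUE)
      p1 <- 1 / (1 + exp(ll[, 1] - ll[, 2]))
      list(label = as.integer(p1 > 0.5), score = as.numeric(p1))
    },
    importance = function(fit)
      stats::setNames(abs(fit$logtheta[, 2] - fit$logtheta[, 1]),
                      rownames(fit$logtheta)))
}

# Exact weighted CART stump over 0/1 features: the split minimising the
# weight-summed Gini impurity of the two children (the classification-tree
# convention), with weighted-majority leaf predictions -- computable for all
# features at once from four weighted column sums. Falls back to an rpart
# stump for non-binary input.
best_binary_stump <- function(x, y, w) {
  w1 <- as.numeric(crossprod(w, x))            # weight with bit 1
  w1p <- as.numeric(crossprod(w * y, x))       # ... and label 1
  w0 <- sum(w) - w1
  w0p <- sum(w * y) - w1p
  gini_side <- function(wt, wp) ifelse(wt > 0, 2 * wp * (wt - wp) / wt, 0)
  score <- gini_side(w0, w0p) + gini_side(w1, w1p)
  j <- which.min(score)
  maj <- as.integer(sum(w * y) > 0.5 * sum(w))  # for empty children
  list(feature = j,
       pred0 = if (w0[j] > 0) as.integer(w0p[j] > 0.5 * w0[j]) else maj,
       pred1 = if (w1[j] > 0) as.integer(w1p[j] > 0.5 * w1[j]) else maj)
}

stump_predict <- function(stump, x) {
  b <- x[, stump$feature]
  stump$pred1 * b + stump$pred0 * (1 - b)
}

# AdaBoost (discrete, two-class) over depth-1 stumps, 50 rounds.
fit_adaboost <- function(x, y, n_rounds = 50) {
  if (!all(x %in% c(0, 1)))
    return(fit_adaboost_rpart(x, y, n_rounds))
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    stump <- best_binary_stump(x, y, w)
    pred <- stump_predict(stump, x)
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) {  # no stump beat chance; fall back to majority vote
    maj <- as.integer(mean(y) >= 0.5)
    return(list(kind = "constant", level = maj))
  }
  list(kind = "ABC", stumps = stumps, alphas = alphas,
    predict = function(fit, x) {
      margin <- rowSums(vapply(seq_along(fit$stumps), function(m)
        fit$alphas[m] * (2 * stump_predict(fit$stumps[[m]], x) - 1),
        numeric(nrow(x))))
      list(label = as.integer(margin > 0), score = margin)
    },
    importance = function(fit) {
      imp <- stats::setNames(numeric(0), character(0))
      for (m in seq_along(fit$stumps)) {
        nm <- paste0("f", fit$stumps[[m]]$feature)
        imp[nm] <- (imp[nm] %0% 0) + fit$alphas[m]
      }
      imp
    })
}

fit_adaboost_rpart <- function(x, y, n_rounds = 50) {
  df <- data.frame(x, y = factor(y, levels = 0:1))
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    stump <- rpart_full(df, weights = w, maxdepth = 1)
    pred <- as.integer(as.character(stats::predict(stump, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) {
    maj <- as.integer(mean(y) >= 0.5)
    return(list(kind = "constant", level = maj))
  }
  list(kind = "ABC", stumps = stumps, alphas = alphas,
    predict = function(fit, x) {
      df <- data.frame(x)
      margin <- rowSums(vapply(seq_along(fit$stumps), function(m) {
        p <- as.integer(as.character(
          stats::predict(fit$stumps[[m]], df, type = "class")))
        fit$alphas[m] * (2 * p - 1)
      }, numeric(nrow(df))))
      list(label = as.integer(margin > 0), score = margin)
    },
    importance = function(fit) {
      imp <- stats::setNames(numeric(0), character(0))
      for (m in seq_along(fit$stumps)) {
        vi <- rpart_importance(fit$stumps[[m]]) * fit$alphas[m]
        for (nm in names(vi)) imp[nm] <- (imp[nm] %0% 0) + vi[nm]
      }
      imp
    })
}

`%0%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Gradient boosting via xgboost configured as classic (Friedman) gradient
# tree boosting: 100 rounds, depth 3, learning rate 0.1, and no L2 leaf
# penalty or hessian-based child-weight pruning -- the regularised xgboost
# defaults otherwise stop adapting on nearly separable data well before the
# 100 rounds the classic algorithm would use.
fit_gbc <- function(x, y) {
  model <- xgboost::xgboost(x, factor(y, levels = 0:1), nrounds = 100,
                            max_depth = 3, learning_rate = 0.1,
                            objective = "binary:logistic",
                            reg_lambda = 0, min_child_weight = 0,
                            nthreads = 1, verbosity = 0,
                            seed = sample.int(.Machine$integer.max, 1))
  list(kind = "GBC", model = model,
    predict = function(fit, x) {
      # probability of the second factor level, i.e. class 1
      p <- stats::predict(fit$model, x, type = "response")
      list(label = as.integer(p > 0.5), score = p)
    },
    importance = function(fit) {
      im <- xgboost::xgb.importance(model = fit$model)
      stats::setNames(im$Gain, im$Feature)
    })
}

# Extremely randomized trees via ranger (no bootstrap, random split points).
fit_etc <- function(x, y) {
  model <- ranger::ranger(x = x, y = factor(y, levels = 0:1),
                          num.trees = 500, splitrule = "extratrees",
                          num.random.splits = 1, replace = FALSE,
                          sample.fraction = 1, min.node.size = 1,
                          mtry = max(1, floor(sqrt(ncol(x)))),
                          probability = TRUE, importance = "impurity",
                          num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1))
  list(kind = "ETC", model = model,
    predict = function(fit, x) {
      p <- stats::predict(fit$model, data.frame(x),
                          num.threads = 1)$predictions[, "1"]
      list(label = as.integer(p > 0.5), score = p)
    },
    importance = function(fit) ranger::importance(fit$model))
}

# Bagging: 10 bootstrap replicates of an unpruned decision tree.
fit_bagging <- function(x, y, n_bags = 10) {
  df <- data.frame(x, y = factor(y, levels = 0:1))
  trees <- lapply(seq_len(n_bags), function(b) {
    repeat {  # redraw degenerate single-class bootstrap samples
      idx <- sample(nrow(df), replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    rpart_full(df[idx, , drop = FALSE])
  })
  list(kind = "BC", trees = trees,
    predict = function(fit, x) {
      df <- data.frame(x)
      p <- rowMeans(vapply(fit$trees, function(tr)
        stats::predict(tr, df, type = "prob")[, "1"], numeric(nrow(df))))
      list(label = as.integer(p > 0.5), score = p)
    },
    importance = function(fit) {
      imp <- stats::setNames(numeric(0), character(0))
      for (tr in fit$trees) {
        vi <- rpart_importance(tr)
        for (nm in names(vi)) imp[nm] <- (imp[nm] %0% 0) + vi[nm]
      }
      imp / length(fit$trees)
    })
}
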