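test_that("a decision tree scores perfectly when a planted column splits the classes", {
  gen <- generate_matrix(tiny_spec(q_high = 1, q_low = 0, epsilon = 0))
  plan <- make_outer_folds(gen$matrix, 6, 1)
  res <- evaluate_classifier(gen$matrix, gen$truth$set1_gene_ids, plan, "DT",
                             seed = 1, nested = FALSE)
  folds <- res[res$fold != "mean", ]
  expect_equal(folds$test_f1, rep(1, 6))
  expect_equal(folds$mcc, rep(1, 6))
})

test_that("the metrics report carries all nine panel metrics plus MCC", {
  gen <- generate_matrix(tiny_spec())
  plan <- make_outer_folds(gen$matrix, 6, 1)
  res <- evaluate_classifier(gen$matrix, family_ids(gen$matrix), plan,
                             "gNB", seed = 1, nested = TRUE)
  expect_named(res, c("classifier", "feature_set", "fold",
                      "train_precision", "train_recall", "train_f1",
                      "test_precision", "test_recall", "test_f1",
                      "nested_cv_accuracy", "auroc", "aupr", "mcc"))
  expect_identical(nrow(res), 7L)              # 6 folds + mean
  expect_true(all(res$nested_cv_accuracy >= 0 & res$nested_cv_accuracy <= 1))
  expect_true(all(res$mcc >= -1 & res$mcc <= 1))
})

test_that("every classifier can be fit, predicted and scored", {
  gen <- generate_matrix(tiny_spec(n_background = 20))
  x <- gen$matrix$bits; y <- gen$matrix$labels
  for (clf in CLASSIFIER_IDS) {
    fit <- fit_classifier(clf, x, y, seed = 1)
    pr <- predict_classifier(fit, x)
    expect_identical(nrow(pr), nrow(x))
    expect_true(all(pr$label %in% 0:1))
    expect_true(all(is.finite(pr$score)))
    # resubstitution on strong planted signal beats chance comfortably
    expect_gt(mean(pr$label == y), 0.7)
  }
})

test_that("classifier fits are deterministic under a fixed seed", {
  gen <- generate_matrix(tiny_spec(n_background = 30))
  x <- gen$matrix$bits; y <- gen$matrix$labels
  for (clf in c("RF", "ETC", "GBC", "BC", "ABC", "logR")) {
    p1 <- predict_classifier(fit_classifier(clf, x, y, seed = 5), x)
    p2 <- predict_classifier(fit_classifier(clf, x, y, seed = 5), x)
    expect_identical(p1, p2)
  }
})

test_that("our regularized LDA matches classical LDA on well-conditioned data", {
  set.seed(99)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 4, 0), ncol = 4),
             matrix(rnorm(n / 2 * 4, 1.5), ncol = 4))
  y <- rep(0:1, each = n / 2)
  ours <- predict_classifier(fit_classifier("LDA", x, y, 1), x)$label
  ref <- MASS::lda(x, grouping = factor(y))
  ref_lab <- as.integer(as.character(stats::predict(ref, x)$class))
  expect_identical(ours, ref_lab)
})

test_that("single-class training data yields a constant classifier, not an error", {
  x <- matrix(rbinom(40, 1, 0.5), 10)
  fit <- fit_classifier("RF", x, rep(1L, 10), seed = 1)
  pr <- predict_classifier(fit, x)
  expect_true(all(pr$label == 1L))
})

test_that("duplicating minority-class rows never decreases its resubstitution recall", {
  gen <- generate_matrix(tiny_spec(n_background = 20, seed = 3))
  x <- gen$matrix$bits; y <- gen$matrix$labels
  minority <- which(y == 1)[1:4]
  for (clf in c("mNB", "gNB", "DT")) {
    r0 <- {
      pr <- predict_classifier(fit_classifier(clf, x, y, 1), x)
      compute_metrics(y, pr$label)["recall"]
    }
    x2 <- rbind(x, x[minority, ]); y2 <- c(y, y[minority])
    r1 <- {
      pr <- predict_classifier(fit_classifier(clf, x2, y2, 1), x2)
      m <- compute_metrics(y2, pr$label)
      m["recall"]
    }
    expect_gte(unname(r1), unname(r0) - 1e-12)
  }
})

test_that("empty or unknown feature sets are refused", {
  gen <- generate_matrix(tiny_spec())
  plan <- make_outer_folds(gen$matrix, 6, 1)
  expect_error(evaluate_classifier(gen$matrix, character(), plan, "DT"),
               "empty")
  expect_error(evaluate_classifier(gen$matrix, "nope", plan, "DT"),
               "unknown")
})

test_that("train and test rows are disjoint in every fold", {
  gen <- generate_matrix(tiny_spec())
  plan <- make_outer_folds(gen$matrix, 6, 2)
  for (f in 1:6) {
    te <- names(plan$fold)[plan$fold == f]
    tr <- names(plan$fold)[plan$fold != f]
    expect_length(intersect(te, tr), 0)
    expect_setequal(c(te, tr), genome_ids(gen$matrix))
  }
})

test_that("benchmark output averages random sets and summarizes cleanly", {
  gen <- generate_matrix(tiny_spec(n_background = 40))
  plan <- make_outer_folds(gen$matrix, 6, 1)
  sets <- build_feature_sets(gen$matrix, plan, top_k = 15, n_random = 3,
                             seed = 1)
  bench <- benchmark_feature_sets(gen$matrix, sets, plan,
                                  classifiers = c("gNB", "DT"),
                                  seed = 1, nested = FALSE)
  expect_s3_class(bench, "ppa_benchmark")
  expect_setequal(unique(bench$feature_set),
                  c("All", "Intersection", paste0("Random", 1:3),
                    "Random_mean"))
  sm <- summary(bench)
  expect_true(all(c("classifier", "feature_set", "test_f1", "mcc")
                  %in% names(sm)))
  d <- withr::local_tempdir()
  write_benchmark_tsv(bench, file.path(d, "long.tsv"),
                      file.path(d, "wide.tsv"))
  long <- read.table(file.path(d, "long.tsv"), sep = "\t", header = TRUE)
  expect_setequal(unique(long$metric),
                  setdiff(names(bench), c("classifier", "feature_set", "fold")))
})
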