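test_that("stratified folds are disjoint, exhaustive and balanced", {
  labels <- rep(c(1, 0), each = 50)
  folds <- kfold_split(labels, 5L, seed = 2L)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:100)
  expect_equal(vapply(test_sets, length, integer(1)), rep(20L, 5))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    frac <- mean(labels[f$test])
    expect_lt(abs(frac - 0.5), 1 / length(f$test) + 1e-12)
  }
  expect_identical(kfold_split(labels, 5L, seed = 2L), folds)
  expect_error(kfold_split(labels, 101L), "exceeds")
  expect_error(kfold_split(labels, 1L), ">= 2")
})

test_that("confusion metrics reproduce hand arithmetic and flag 0/0", {
  y <- c(rep(1, 50), rep(0, 50))
  p <- c(rep(1, 50), rep(1, 10), rep(0, 40))  # TP=50 TN=40 FP=10 FN=0
  m <- confusion_metrics(y, p)
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 0.8333, tolerance = 1e-4)
  expect_equal(m$recall, 1.0)
  expect_equal(m$f1, 0.9091, tolerance = 1e-4)
  perfect <- confusion_metrics(y, y)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  allneg <- confusion_metrics(y, rep(0, 100))
  expect_equal(allneg$precision, 0)
  expect_equal(allneg$recall, 0)
  expect_true(all(c("precision", "f1") %in% attr(allneg, "undefined")))
  expect_error(confusion_metrics(y, p[1:10]), "length")
})

test_that("f1 equals 2PR/(P+R) whenever defined", {
  set.seed(3)
  for (i in 1:20) {
    y <- stats::rbinom(40, 1, 0.5)
    p <- stats::rbinom(40, 1, 0.5)
    m <- confusion_metrics(y, p)
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("AUC agrees with the O(n^2) pair-counting oracle", {
  expect_equal(threshold_free_metrics(c(1, 0, 1, 0),
                                      c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  # perfectly separated
  expect_equal(threshold_free_metrics(c(1, 1, 0, 0),
                                      c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  # constant scores -> midrank ties -> 0.5
  expect_equal(threshold_free_metrics(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    y <- c(1, 0, stats::rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(threshold_free_metrics(y, s)$auc, auc_paircount(y, s))
  }
  expect_error(threshold_free_metrics(rep(1, 5), stats::runif(5)),
               "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    y <- c(0, 1, stats::rbinom(30, 1, 0.4))
    s <- stats::rnorm(32)
    expect_equal(threshold_free_metrics(y, s)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))))
  }
})

test_that("AUPR behaves at the extremes and improves with separation", {
  perfect <- threshold_free_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$aupr, 1)
  good <- threshold_free_metrics(c(1, 1, 0, 0), c(0.9, 0.3, 0.5, 0.1))$aupr
  bad <- threshold_free_metrics(c(1, 1, 0, 0), c(0.2, 0.3, 0.9, 0.8))$aupr
  expect_gt(good, bad)
  expect_true(good <= 1 && bad >= 0)
})

test_that("cross-validation runs per-fold retraining and summarises", {
  data <- tiny_data()
  cfg <- tiny_config(); cfg$train$epochs <- 25L
  res <- suppressWarnings(run_cv(data, k = 2L, cfg, seed = 1L))
  expect_length(res$folds, 2L)
  expect_equal(sort(res$summary$metric),
               sort(c("auc", "aupr", "accuracy", "precision", "recall", "f1")))
  expect_true(all(res$summary$mean >= 0 & res$summary$mean <= 1))
  # binarisation at 0.5 is what feeds the confusion metrics
  f1 <- res$folds[[1]]
  expect_equal(f1$metrics$accuracy,
               confusion_metrics(f1$y_true,
                                 as.integer(f1$y_score >= 0.5))$accuracy)
  # reproducible under the same master seed
  res2 <- suppressWarnings(run_cv(data, k = 2L, cfg, seed = 1L))
  expect_equal(res2$summary, res$summary)
})

test_that("held-out features never leak into training-fold matrices", {
  data <- tiny_data()
  cfg <- tiny_config()
  ds <- build_pair_dataset(data$assoc, data$mirna_ids, data$disease_ids,
                           seed = 3L)
  folds <- kfold_split(ds$label, 2L, seed = 9L)
  tr <- ds[folds[[1]]$train, ]
  te <- ds[folds[[1]]$test, ]
  pos <- tr[tr$label == 1L, ]
  key <- paste(data$assoc$mirna, data$assoc$disease)
  train_assoc <- data$assoc[key %in% paste(pos$mirna, pos$disease), ]
  # variant of the full data in which one held-out positive disappears
  drop_pair <- te[te$label == 1L, ][1, ]
  data2 <- data
  data2$assoc <- data$assoc[!(data$assoc$mirna == drop_pair$mirna &
                                data$assoc$disease == drop_pair$disease), ]
  f1 <- suppressWarnings(build_fold_features(data, train_assoc, cfg))
  f2 <- suppressWarnings(build_fold_features(data2, train_assoc, cfg))
  expect_identical(f1$sims, f2$sims)
  expect_identical(f1$F_m, f2$F_m)
  expect_identical(f1$F_d, f2$F_d)
  # and the fitted model's message-passing graph excludes test edges
  m <- suppressWarnings(fit_gonnmda(data, tr, cfg, seed = 5L))
  e <- m$graph$edges$`miRNA-disease`
  te_pos <- te[te$label == 1L, ]
  te_idx <- cbind(node_index(m$graph, "miRNA", te_pos$mirna),
                  node_index(m$graph, "disease", te_pos$disease))
  expect_false(any(paste(te_idx[, 1], te_idx[, 2]) %in%
                     paste(e[, "src"], e[, "dst"])))
})
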