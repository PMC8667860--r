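# a small linearly separable two-feature table
separable_table <- function(seed = 0, n = 40) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  X <- cbind(f1 = as.numeric(y) * 3 + rnorm(n, sd = 0.2),
             f2 = rnorm(n))
  feature_table(X, paste0("s", seq_len(n)), c("f1", "f2"), y)
}

test_that("forest configuration validates its fields", {
  cfg <- forest_config()
  expect_equal(cfg$n_trees, 800L)
  expect_equal(cfg$max_depth, 50L)
  expect_equal(cfg$features_per_split, "all")
  expect_null(forest_config(max_depth = NULL)$max_depth)
  expect_error(forest_config(n_trees = 0), class = "pssmDBP_validation_error")
  expect_error(forest_config(max_depth = 0), class = "pssmDBP_validation_error")
  expect_error(forest_config(features_per_split = 2),
               class = "pssmDBP_validation_error")
})

test_that("training a separable table reaches perfect training accuracy", {
  t <- separable_table(0)
  model <- train_forest(t, forest_config(n_trees = 100, seed = 1))
  pred <- predict_forest(model, t)
  expect_equal(pred$labels, t$labels)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
})

test_that("training is deterministic given the seed", {
  t <- separable_table(1)
  cfg <- forest_config(n_trees = 60, seed = 42)
  m1 <- train_forest(t, cfg)
  m2 <- train_forest(t, cfg)
  expect_equal(predict_forest(m1, t)$scores, predict_forest(m2, t)$scores)
  expect_equal(model_hash(m1), model_hash(m2))
  m3 <- train_forest(t, forest_config(n_trees = 60, seed = 43))
  expect_false(model_hash(m1) == model_hash(m3))
})

test_that("degenerate configurations still train", {
  t <- separable_table(2)
  m <- train_forest(t, forest_config(n_trees = 1, max_depth = 1, seed = 1))
  p <- predict_forest(m, t)
  expect_true(all(p$scores %in% c(0, 1)))   # one tree votes 0 or 1
})

test_that("single-class training input is rejected", {
  t <- separable_table(3)
  t$labels <- rep(1L, length(t$labels))
  expect_error(train_forest(t), class = "pssmDBP_validation_error")
})

test_that("prediction enforces the training feature schema", {
  t <- separable_table(4)
  model <- train_forest(t, forest_config(n_trees = 30, seed = 1))
  other <- feature_table(t$values, t$sample_ids, c("f1", "other"), t$labels)
  err <- expect_error(predict_forest(model, other),
                      class = "pssmDBP_schema_error")
  expect_match(conditionMessage(err), "f2")
  expect_match(conditionMessage(err), "other")
  # reordering rows permutes outputs identically
  perm <- c(5:1, 6:nrow(t$values))
  tp <- feature_table(t$values[perm, ], t$sample_ids[perm],
                      t$feature_names, t$labels[perm])
  expect_equal(predict_forest(model, tp)$scores,
               predict_forest(model, t)$scores[perm])
})

test_that("models survive a save/load round trip with sidecar", {
  t <- separable_table(5)
  model <- train_forest(t, forest_config(n_trees = 30, seed = 7))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(predict_forest(back, t)$scores, predict_forest(model, t)$scores)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$hash, model_hash(model))
  expect_equal(side$n_features, 2L)
  expect_error(load_model(withr::local_tempfile()),
               class = "pssmDBP_io_error")
})

test_that("metrics match hand calculations and the brute-force oracle", {
  m <- classification_metrics(confusion_matrix(50, 0, 50, 0))
  expect_equal(c(m$acc, m$sn, m$sp, m$mcc), c(100, 100, 100, 1))

  m0 <- classification_metrics(confusion_matrix(0, 0, 10, 10))
  expect_equal(m0$sn, 0)
  expect_equal(m0$sp, 100)
  expect_equal(m0$mcc, 0)
  expect_true(m0$mcc_degenerate)

  set.seed(12)
  for (i in 1:500) {
    cnt <- sample(0:40, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    got <- classification_metrics(confusion_matrix(cnt[1], cnt[2],
                                                   cnt[3], cnt[4]))
    want <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got$acc, want$acc, tolerance = 1e-12)
    expect_equal(got$sn, want$sn, tolerance = 1e-12)
    expect_equal(got$sp, want$sp, tolerance = 1e-12)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
  }
  expect_error(classification_metrics(confusion_matrix(0, 0, 0, 0)),
               class = "pssmDBP_degenerate_error")
  expect_error(confusion_matrix(-1, 0, 0, 2),
               class = "pssmDBP_validation_error")
})

test_that("MCC is symmetric under the TP/TN, FP/FN swap", {
  set.seed(13)
  for (i in 1:50) {
    cnt <- sample(1:30, 4, replace = TRUE)
    a <- classification_metrics(confusion_matrix(cnt[1], cnt[2],
                                                 cnt[3], cnt[4]))
    b <- classification_metrics(confusion_matrix(cnt[3], cnt[4],
                                                 cnt[1], cnt[2]))
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  }
})

test_that("ROC/AUC agree with pairwise concordance, with tie handling", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)

  lab <- c(1, 1, 1, 0, 0, 0)
  sc <- c(0.9, 0.7, 0.4, 0.7, 0.3, 0.1)   # one cross-class tie
  got <- roc_auc(lab, sc)
  expect_equal(got$auc, oracle_auc(lab, sc))
  expect_equal(got$roc$fpr[1], 0)
  expect_equal(got$roc$tpr[1], 0)
  expect_equal(got$roc$fpr[nrow(got$roc)], 1)
  expect_equal(got$roc$tpr[nrow(got$roc)], 1)

  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- round(runif(n), 1)    # coarse scores force ties
    expect_equal(roc_auc(lab, sc)$auc, oracle_auc(lab, sc),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 4), runif(4)),
               class = "pssmDBP_validation_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(lab, sc, direction = "<", quiet = TRUE))
    expect_equal(roc_auc(lab, sc)$auc, ref, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  lab <- sample(0:1, 30, replace = TRUE, prob = c(0.5, 0.5))
  lab[1:2] <- c(0, 1)
  sc <- rnorm(30)
  a <- roc_auc(lab, sc)$auc
  expect_equal(roc_auc(lab, exp(sc))$auc, a)
  expect_equal(roc_auc(lab, 2 * sc - 7)$auc, a)
})

test_that("cross-validation pools folds deterministically", {
  t <- separable_table(6, n = 50)
  cfg <- forest_config(n_trees = 80, seed = 3)
  r1 <- cross_validate(t, cfg, folds = 5, seed = 11)
  r2 <- cross_validate(t, cfg, folds = 5, seed = 11)
  expect_equal(r1$scores, r2$scores)
  expect_equal(r1$acc, r2$acc)
  expect_gte(r1$acc, 95)
  expect_equal(sum(r1$cm$tp, r1$cm$fp, r1$cm$tn, r1$cm$fn), 50)
  expect_length(r1$fold_acc, 5L)
  expect_true(all(r1$fold_acc >= 0 & r1$fold_acc <= 1))
  expect_error(cross_validate(t, cfg, folds = 60, seed = 1),
               class = "pssmDBP_validation_error")
})

test_that("label-permuted data shows no signal", {
  t <- separable_table(7, n = 60)
  set.seed(21)
  t$labels <- t$labels[sample.int(60)]
  # break the feature-label link entirely
  set.seed(22)
  t$values[, 1] <- rnorm(60)
  r <- cross_validate(t, forest_config(n_trees = 100, seed = 1),
                      folds = 5, seed = 2)
  expect_gte(r$auc, 0.25)
  expect_lte(r$auc, 0.75)
})
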