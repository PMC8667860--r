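#' Random-forest configuration
#'
#' The final-model defaults are 800 trees with a maximum depth of 50 and
#' all features available at every split; selected as strong settings
#' for very wide PSSM feature tables. Unlimited depth is available with
#' `max_depth = NULL`.
#'
#' @param n_trees Number of trees (>= 1).
#' @param max_depth Maximum tree depth (>= 1), or `NULL` for unlimited.
#' @param features_per_split `"all"`, `"sqrt"`, or a fraction in (0, 1]
#'   of the feature count tried at each split.
#' @param seed Integer seed making training deterministic.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 800L, max_depth = 50L,
                          features_per_split = "all", seed = 1L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop_validation("n_trees must be >= 1")
  if (!is.null(max_depth)) {
    max_depth <- as.integer(max_depth)
    if (is.na(max_depth) || max_depth < 1L) {
      stop_validation("max_depth must be >= 1 or NULL")
    }
  }
  if (is.character(features_per_split)) {
    features_per_split <- match.arg(features_per_split, c("all", "sqrt"))
  } else {
    features_per_split <- as.numeric(features_per_split)
    if (is.na(features_per_split) || features_per_split <= 0 ||
        features_per_split > 1) {
      stop_validation("features_per_split must be 'all', 'sqrt' or in (0, 1]")
    }
  }
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 features_per_split = features_per_split,
                 seed = as.integer(seed)),
            class = "forest_config")
}

mtry_of <- function(cfg, m) {
  if (identical(cfg$features_per_split, "all")) return(m)
  if (identical(cfg$features_per_split, "sqrt")) return(max(1L, floor(sqrt(m))))
  max(1L, floor(cfg$features_per_split * m))
}

#' Train the random-forest DBP classifier
#'
#' Fits a classification forest (via ranger) on a labelled feature
#' table. Training is deterministic for a given `cfg$seed` and runs on
#' one thread so results do not depend on scheduling.
#'
#' @param t A labelled [feature_table()] with both classes present.
#' @param cfg A [forest_config()].
#' @return Object of class `dbp_model` wrapping the fitted forest, the
#'   training feature names (order matters for prediction) and the
#'   configuration.
#' @importFrom ranger ranger
#' @export
train_forest <- function(t, cfg = forest_config()) {
  stopifnot(inherits(t, "feature_table"), inherits(cfg, "forest_config"))
  if (is.null(t$labels) || length(unique(t$labels)) < 2L) {
    stop_validation("training requires both classes")
  }
  df <- as.data.frame(t$values)
  names(df) <- make.names(t$feature_names)
  df$.label <- factor(t$labels, levels = c(0L, 1L))
  rf <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = cfg$n_trees,
    mtry = mtry_of(cfg, ncol(t$values)),
    max.depth = if (is.null(cfg$max_depth)) 0L else cfg$max_depth,
    seed = cfg$seed, num.threads = 1L)
  structure(list(forest = rf, feature_names = t$feature_names, cfg = cfg),
            class = "dbp_model")
}

#' @export
print.dbp_model <- function(x, ...) {
  cat("<dbp_model>", x$cfg$n_trees, "trees,",
      length(x$feature_names), "features\n")
  invisible(x)
}

#' Predict DBP labels and scores
#'
#' The score of a sample is the fraction of trees voting for the
#' positive (DNA-binding) class; the label is positive when the score
#' is at least 0.5. The table's feature names must match training
#' exactly, in the same order.
#'
#' @param model A `dbp_model` from [train_forest()].
#' @param t A [feature_table()] (labels, if present, are ignored).
#' @return List with integer `labels` in \{0, 1\} and numeric `scores`
#'   in `[0, 1]`.
#' @export
predict_forest <- function(model, t) {
  stopifnot(inherits(model, "dbp_model"), inherits(t, "feature_table"))
  if (!identical(t$feature_names, model$feature_names)) {
    miss <- setdiff(model$feature_names, t$feature_names)
    extra <- setdiff(t$feature_names, model$feature_names)
    stop_schema("feature mismatch with training",
                if (length(miss)) paste0("; missing: ",
                                         paste(utils::head(miss, 5), collapse = ", ")),
                if (length(extra)) paste0("; extra: ",
                                          paste(utils::head(extra, 5), collapse = ", ")),
                if (!length(miss) && !length(extra)) "; same names, different order")
  }
  df <- as.data.frame(t$values)
  names(df) <- make.names(t$feature_names)
  votes <- stats::predict(model$forest, data = df, predict.all = TRUE,
                          num.threads = 1L)$predictions
  pos_idx <- which(model$forest$forest$levels == "1")
  scores <- rowMeans(votes == pos_idx)
  list(labels = as.integer(scores >= 0.5), scores = scores)
}

#' Stable content hash of a trained model
#'
#' MD5 over the fitted forest structure, feature names and
#' configuration; identical data + seed give identical hashes.
#'
#' @param model A `dbp_model`.
#' @return Character MD5 digest.
#' @export
model_hash <- function(model) {
  stopifnot(inherits(model, "dbp_model"))
  object_hash(list(model$forest$forest, model$feature_names,
                   unclass(model$cfg)))
}

#' Save / load a model with a JSON sidecar
#'
#' The model is serialized with `saveRDS`; `<path>.json` records the
#' configuration, feature names and content hash for provenance.
#'
#' @param model A `dbp_model`.
#' @param path Output `.rds` path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dbp_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(config = unclass(model$cfg),
         n_features = length(model$feature_names),
         feature_names = model$feature_names,
         hash = model_hash(model)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io("no such model file: ", path)
  m <- readRDS(path)
  if (!inherits(m, "dbp_model")) stop_validation("not a dbp_model file")
  m
}

# Stratified fold assignment: within each class, samples are shuffled by
# the seed and dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

# Out-of-fold predictions for a fixed fold assignment; returns pooled
# scores in the original sample order.
cv_scores <- function(t, cfg, fold_id) {
  scores <- numeric(nrow(t$values))
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    train_t <- feature_table(t$values[!test, , drop = FALSE],
                             t$sample_ids[!test], t$feature_names,
                             t$labels[!test])
    test_t <- feature_table(t$values[test, , drop = FALSE],
                            t$sample_ids[test], t$feature_names,
                            t$labels[test])
    scores[test] <- predict_forest(train_forest(train_t, cfg), test_t)$scores
  }
  scores
}

# Per-fold accuracies (fraction in [0, 1]) at the 0.5 threshold.
cv_fold_accuracies <- function(t, cfg, fold_id) {
  scores <- cv_scores(t, cfg, fold_id)
  pred <- as.integer(scores >= 0.5)
  vapply(sort(unique(fold_id)), function(f) {
    mean(pred[fold_id == f] == t$labels[fold_id == f])
  }, 0)
}

#' Stratified k-fold cross-validation of the forest
#'
#' Splits the samples into stratified folds (shuffled by `seed`), trains
#' on each training fold and predicts the held-out fold, then pools all
#' out-of-fold predictions into a single [eval_report()]. Per-fold
#' accuracies (mean and sd) are attached for reference. Deterministic
#' given the seed.
#'
#' @param t A labelled [feature_table()].
#' @param cfg A [forest_config()].
#' @param folds Number of folds (default 10); requires `N >= folds` and
#'   both classes in every training fold.
#' @param seed Integer seed for fold assignment.
#' @return An [eval_report()] with extra elements `fold_acc`, `scores`
#'   and `fold_id`.
#' @export
cross_validate <- function(t, cfg = forest_config(), folds = 10L, seed = 1L) {
  stopifnot(inherits(t, "feature_table"))
  n <- nrow(t$values)
  if (is.null(t$labels)) stop_validation("cross-validation requires labels")
  if (n < folds) {
    stop_validation("N = ", n, " < folds = ", folds,
                    "; use a smaller fold count")
  }
  if (length(unique(t$labels)) < 2L) {
    stop_validation("both classes must be present")
  }
  fold_id <- stratified_folds(t$labels, folds, seed)
  scores <- cv_scores(t, cfg, fold_id)
  rep <- eval_report(t$labels, scores)
  pred <- as.integer(scores >= 0.5)
  rep$fold_acc <- vapply(sort(unique(fold_id)), function(f) {
    mean(pred[fold_id == f] == t$labels[fold_id == f])
  }, 0)
  rep$scores <- scores
  rep$fold_id <- fold_id
  rep
}
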