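# High-level commands wiring the pipeline stages (simulate profiles ->
# extract descriptors -> MRMD rank/select -> train -> evaluate/predict)
# into file-in/file-out steps. Each command records a provenance JSON
# next to its outputs so any artifact can be traced to a seed, a
# configuration and input hashes.

write_provenance <- function(path, command, seed, config, inputs) {
  jsonlite::write_json(
    list(command = command, seed = seed, config = config,
         inputs = lapply(inputs, function(f)
           if (file.exists(f)) unname(tools::md5sum(f)) else NA),
         package = "pssmDBP",
         version = as.character(utils::packageVersion("pssmDBP")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate a PSSM dataset to disk
#'
#' Writes a directory of ASCII PSSM files plus `labels.tsv` — the
#' pipeline's external input format — from a [sim_spec()].
#'
#' @param out_dir Output directory.
#' @param n_pos,n_neg,length_range,score_band,effect,seed Passed to
#'   [sim_spec()].
#' @return Invisibly, `out_dir`.
#' @export
run_simulate <- function(out_dir, n_pos = 100L, n_neg = 100L,
                         length_range = c(50L, 200L),
                         score_band = c(-8L, 12L), effect = 4, seed = 1L) {
  spec <- sim_spec(n_pos, n_neg, length_range, score_band, effect, seed)
  ds <- simulate_dataset(spec)
  write_dataset(ds, out_dir)
  write_provenance(file.path(out_dir, "provenance.json"), "simulate",
                   seed, unclass(spec), character())
  invisible(out_dir)
}

#' Extract a feature table from a directory of PSSM files
#'
#' @param pssm_dir Directory of `*.pssm` files.
#' @param out Output TSV path for the feature table.
#' @param labels_file Optional label TSV (`id`, `label`); defaults to
#'   `labels.tsv` inside `pssm_dir` when present.
#' @param blocks Descriptor blocks to extract (all three by default,
#'   giving the fused 930-d row).
#' @param sigmoid Logistic-transform scores first.
#' @param skip_bad Skip unparseable files instead of aborting.
#' @param seed Recorded in provenance (extraction itself is
#'   deterministic).
#' @return Invisibly, `out`.
#' @export
run_extract <- function(pssm_dir, out, labels_file = NULL,
                        blocks = c("aadp", "composition", "rpssm"),
                        sigmoid = FALSE, skip_bad = FALSE, seed = 1L) {
  if (is.null(labels_file)) {
    cand <- file.path(pssm_dir, "labels.tsv")
    if (file.exists(cand)) labels_file <- cand
  }
  labels <- if (!is.null(labels_file)) read_labels(labels_file)
  ds <- read_pssm_dir(pssm_dir, labels = labels, skip_bad = skip_bad)
  t <- extract_features(ds, blocks = blocks, sigmoid = sigmoid)
  write_feature_table(t, out)
  write_provenance(paste0(out, ".provenance.json"), "extract", seed,
                   list(blocks = blocks, sigmoid = sigmoid),
                   c(labels_file %||% character()))
  invisible(out)
}

#' Rank features and select the optimal prefix subset
#'
#' Runs [rank_features()] and [select_subset()] on a feature table file;
#' writes the ranking as TSV and the selection result as JSON.
#'
#' @param table_file Feature table TSV (with labels).
#' @param out_prefix Output prefix: writes `<prefix>.ranking.tsv` and
#'   `<prefix>.selection.json`.
#' @param folds CV folds for the incremental search.
#' @param seed Integer seed.
#' @param k_grid Optional prefix sizes to evaluate.
#' @param weight,method Passed to [rank_features()].
#' @return Invisibly, the selection result.
#' @export
run_select <- function(table_file, out_prefix, folds = 10L, seed = 1L,
                       k_grid = NULL, weight = 0.5, method = "score") {
  t <- read_feature_table(table_file)
  ranking <- rank_features(t, weight = weight, method = method)
  sel <- select_subset(t, ranking, folds = folds, seed = seed, k_grid = k_grid)
  write_ranking(ranking, paste0(out_prefix, ".ranking.tsv"))
  write_selection(sel, paste0(out_prefix, ".selection.json"))
  write_provenance(paste0(out_prefix, ".provenance.json"), "select", seed,
                   list(folds = folds, weight = weight, method = method,
                        k_grid = k_grid),
                   table_file)
  invisible(sel)
}

#' Train the forest on a feature table file
#'
#' @param table_file Feature table TSV (with labels).
#' @param model_file Output `.rds` path (a JSON sidecar is added).
#' @param features Optional feature-name subset (e.g. a selection's
#'   `selected_names`) to train on.
#' @param n_trees,max_depth,features_per_split,seed [forest_config()]
#'   fields.
#' @return Invisibly, the trained model.
#' @export
run_train <- function(table_file, model_file, features = NULL,
                      n_trees = 800L, max_depth = 50L,
                      features_per_split = "all", seed = 1L) {
  t <- read_feature_table(table_file)
  if (!is.null(features)) t <- subset_features(t, features)
  cfg <- forest_config(n_trees, max_depth, features_per_split, seed)
  model <- train_forest(t, cfg)
  save_model(model, model_file)
  write_provenance(paste0(model_file, ".provenance.json"), "train", seed,
                   unclass(cfg), table_file)
  invisible(model)
}

#' Cross-validated evaluation of a feature table
#'
#' @param table_file Feature table TSV (with labels).
#' @param out_prefix Writes `<prefix>.report.json` and `<prefix>.roc.tsv`.
#' @param folds CV folds.
#' @param n_trees,max_depth,features_per_split,seed [forest_config()]
#'   fields.
#' @param features Optional feature-name subset.
#' @return Invisibly, the [eval_report()].
#' @export
run_eval <- function(table_file, out_prefix, folds = 10L, n_trees = 800L,
                     max_depth = 50L, features_per_split = "all",
                     seed = 1L, features = NULL) {
  t <- read_feature_table(table_file)
  if (!is.null(features)) t <- subset_features(t, features)
  cfg <- forest_config(n_trees, max_depth, features_per_split, seed)
  report <- cross_validate(t, cfg, folds = folds, seed = seed)
  write_report(report, paste0(out_prefix, ".report.json"),
               paste0(out_prefix, ".roc.tsv"))
  write_provenance(paste0(out_prefix, ".provenance.json"), "eval", seed,
                   c(unclass(cfg), folds = folds), table_file)
  invisible(report)
}

#' Predict labels for a feature table with a saved model
#'
#' @param model_file Path of a model saved by [run_train()].
#' @param table_file Feature table TSV (labels optional, ignored).
#' @param out Output TSV (`sample_id`, `score`, `label`).
#' @param seed Recorded in provenance (prediction is deterministic).
#' @return Invisibly, the prediction list.
#' @export
run_predict <- function(model_file, table_file, out, seed = 1L) {
  model <- load_model(model_file)
  t <- read_feature_table(table_file)
  if (!identical(t$feature_names, model$feature_names) &&
      all(model$feature_names %in% t$feature_names)) {
    t <- subset_features(t, model$feature_names)
  }
  pred <- predict_forest(model, t)
  utils::write.table(
    data.frame(sample_id = t$sample_ids,
               score = sprintf("%.12g", pred$scores), label = pred$labels),
    out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(paste0(out, ".provenance.json"), "predict", seed,
                   list(model_hash = model_hash(model)),
                   c(model_file, table_file))
  invisible(pred)
}
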