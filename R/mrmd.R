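#' Pearson correlation with a zero-variance convention
#'
#' Sample Pearson correlation of two equal-length vectors. A constant
#' vector has no linear relevance, so the correlation is defined as 0
#' there instead of NaN.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_validation("length mismatch")
  if (length(x) < 2L) stop_validation("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Euclidean, cosine and Tanimoto measures between two vectors
#'
#' The three pairwise measures used by MRMD redundancy scoring:
#' Euclidean distance `sqrt(sum((x-y)^2))`, cosine similarity
#' `<x,y>/(|x||y|)` and the Tanimoto coefficient
#' `<x,y>/(|x|^2+|y|^2-<x,y>)`. When either vector is all-zero the two
#' similarity measures are defined as 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Named list with elements `ed`, `cos`, `tc`.
#' @export
vector_distances <- function(x, y) {
  if (length(x) != length(y)) stop_validation("length mismatch")
  ed <- sqrt(sum((x - y)^2))
  xx <- sum(x^2); yy <- sum(y^2); xy <- sum(x * y)
  if (xx == 0 || yy == 0) {
    cosv <- 0
    tc <- 0
  } else {
    cosv <- xy / sqrt(xx * yy)
    tc <- xy / (xx + yy - xy)
  }
  list(ed = ed, cos = cosv, tc = tc)
}

#' Rank features by max-relevance / max-distance (MRMD)
#'
#' Relevance of feature i is `maxMR_i = |pearson(f_i, labels)|`.
#' Redundancy is summarised by the mean of each of the three pairwise
#' measures of [vector_distances()] against all other features
#' (`ED_i`, `COS_i`, `TC_i`), combined as
#' `maxMD_i = (ED_i + COS_i + TC_i)/3`. Because Euclidean distance is
#' unbounded while the other two lie in `[-1, 1]`, `ED_i` is min-max
#' normalised to `[0, 1]` across features before averaging (disable
#' with `normalize_ed = FALSE`). The default combined score is
#' `weight * maxMR + (1 - weight) * maxMD`, ranked descending, ties
#' broken by original feature index.
#'
#' Note the combination mixes one distance with two similarities, as the
#' method defines it; `similarity = "complement"` replaces `COS_i` and
#' `TC_i` by `1 - COS_i` and `1 - TC_i` so that all three components
#' reward features far from the rest.
#'
#' An alternative aggregation builds a feature graph with an edge
#' j -> i whenever i outranks j in any one of the four constituent
#' orderings (by maxMR, ED, COS, TC) and ranks features by PageRank
#' (damping 0.85); select with `method = "pagerank"`. Both modes are
#' deterministic.
#'
#' @param t A labelled [feature_table()] with both classes present.
#' @param weight Relevance weight in `[0, 1]` for the combined score.
#' @param normalize_ed Min-max normalise the mean Euclidean component.
#' @param similarity `"raw"` (as defined) or `"complement"`.
#' @param method `"score"` (default) or `"pagerank"`.
#' @return Object of class `feature_ranking`: a data frame with columns
#'   `feature`, `maxMR`, `ED`, `COS`, `TC`, `maxMD`, `score`, `rank`
#'   (ranks are a permutation of 1..M).
#' @export
rank_features <- function(t, weight = 0.5, normalize_ed = TRUE,
                          similarity = c("raw", "complement"),
                          method = c("score", "pagerank")) {
  stopifnot(inherits(t, "feature_table"))
  similarity <- match.arg(similarity)
  method <- match.arg(method)
  if (is.null(t$labels)) stop_validation("ranking requires labels")
  if (length(unique(t$labels)) < 2L) {
    stop_validation("both classes must be present")
  }
  if (weight < 0 || weight > 1) stop_validation("weight must be in [0, 1]")
  X <- t$values
  M <- ncol(X)
  y <- as.numeric(t$labels)

  maxMR <- vapply(seq_len(M), function(i) abs(pearson_cor(X[, i], y)), 0)

  g <- crossprod(X)                       # M x M Gram matrix
  sq <- diag(g)
  d2 <- outer(sq, rep(1, M)) + outer(rep(1, M), sq) - 2 * g
  d2[d2 < 0] <- 0                         # numerical guard
  edm <- sqrt(d2)
  nrm <- sqrt(sq)
  cosm <- g / outer(nrm, nrm)
  tcm <- g / (outer(sq, rep(1, M)) + outer(rep(1, M), sq) - g)
  cosm[!is.finite(cosm)] <- 0             # all-zero features: similarities 0
  tcm[!is.finite(tcm)] <- 0
  zero <- nrm == 0
  cosm[zero, ] <- 0; cosm[, zero] <- 0
  tcm[zero, ] <- 0; tcm[, zero] <- 0

  mean_off <- function(mat) {
    if (M == 1L) return(rep(0, 1L))
    (rowSums(mat) - diag(mat)) / (M - 1)
  }
  ED <- mean_off(edm)
  COS <- mean_off(cosm)
  TC <- mean_off(tcm)

  ED_comb <- ED
  if (normalize_ed && M > 1L) {
    rng <- range(ED)
    ED_comb <- if (diff(rng) == 0) rep(0, M) else (ED - rng[1]) / diff(rng)
  }
  COS_comb <- if (similarity == "complement") 1 - COS else COS
  TC_comb <- if (similarity == "complement") 1 - TC else TC
  maxMD <- (ED_comb + COS_comb + TC_comb) / 3
  score <- weight * maxMR + (1 - weight) * maxMD

  if (method == "pagerank") {
    pr_score <- pagerank_scores(cbind(maxMR, ED_comb, COS_comb, TC_comb))
    ord <- order(-pr_score, seq_len(M))
  } else {
    ord <- order(-score, seq_len(M))
  }
  rank <- integer(M)
  rank[ord] <- seq_len(M)

  structure(data.frame(feature = t$feature_names, maxMR = maxMR,
                       ED = ED, COS = COS, TC = TC,
                       maxMD = maxMD, score = score, rank = rank,
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

# PageRank aggregation of several per-feature criteria: edge j -> i
# whenever feature i strictly outranks feature j in any criterion
# column; uniform edge weights, damping 0.85.
pagerank_scores <- function(crit) {
  M <- nrow(crit)
  adj <- matrix(FALSE, M, M)
  for (k in seq_len(ncol(crit))) {
    adj <- adj | outer(crit[, k], crit[, k], `<`)   # [j, i]: i beats j
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::page_rank(g, damping = 0.85)$vector
}

#' Features in ranked order
#'
#' @param ranking A `feature_ranking` from [rank_features()].
#' @return Character vector of feature names, best first.
#' @export
ranked_names <- function(ranking) {
  stopifnot(inherits(ranking, "feature_ranking"))
  ranking$feature[order(ranking$rank)]
}

#' Write a feature ranking as tab-separated text
#'
#' @param ranking A `feature_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "rank"
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the optimal ranked-prefix feature subset
#'
#' Walks the MRMD ranking, adding one feature at a time, and evaluates
#' each prefix by stratified k-fold cross-validated accuracy with a
#' random forest; the selected subset is the prefix with the highest
#' mean fold accuracy (smallest size on ties). The selection-stage
#' forest uses modest defaults ([forest_config()] with 500 trees,
#' unlimited depth, sqrt mtry); the heavier final-model configuration
#' belongs to [train_forest()].
#'
#' @param t A labelled [feature_table()].
#' @param ranking A `feature_ranking` for the same features.
#' @param folds Number of CV folds (>= 2, and N >= folds).
#' @param seed Integer seed controlling fold assignment and the forests.
#' @param k_grid Prefix sizes to evaluate; default all of `1..M`. A
#'   coarser grid trades resolution of the accuracy curve for speed on
#'   wide tables.
#' @param cfg Optional [forest_config()] override for the CV forests.
#' @return Object of class `selection_result`: list with the `ranking`,
#'   the evaluated `k_grid`, the `cv_accuracy_curve` (mean fold accuracy
#'   in `[0, 1]` per evaluated prefix), `best_k`, and `selected_names`.
#' @export
select_subset <- function(t, ranking, folds = 10L, seed = 1L, k_grid = NULL,
                          cfg = NULL) {
  stopifnot(inherits(t, "feature_table"), inherits(ranking, "feature_ranking"))
  n <- nrow(t$values)
  if (folds < 2L) stop_validation("folds must be >= 2")
  if (n < folds) {
    stop_validation("N = ", n, " < folds = ", folds,
                    "; use a smaller fold count")
  }
  ordered <- ranked_names(ranking)
  M <- length(ordered)
  if (!setequal(ordered, t$feature_names)) {
    stop_schema("ranking and table features differ")
  }
  k_grid <- if (is.null(k_grid)) seq_len(M) else sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L | k_grid > M)) stop_validation("k_grid out of range")
  if (is.null(cfg)) {
    cfg <- forest_config(n_trees = 500L, max_depth = NULL,
                         features_per_split = "sqrt", seed = seed)
  }
  fold_id <- stratified_folds(t$labels, folds, seed)
  curve <- vapply(k_grid, function(k) {
    sub <- subset_features(t, ordered[seq_len(k)])
    mean(cv_fold_accuracies(sub, cfg, fold_id))
  }, 0)
  best <- k_grid[which.max(curve)]   # which.max takes the smallest on ties
  structure(list(ranking = ranking, k_grid = k_grid,
                 cv_accuracy_curve = curve, best_k = best,
                 selected_names = ordered[seq_len(best)],
                 folds = folds, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> best_k =", x$best_k, "of", length(x$k_grid),
      "evaluated prefixes; best mean CV accuracy =",
      sprintf("%.3f", max(x$cv_accuracy_curve)), "\n")
  invisible(x)
}

#' Write a selection result as JSON
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(k_grid = sel$k_grid, cv_accuracy_curve = sel$cv_accuracy_curve,
         best_k = sel$best_k, selected_names = sel$selected_names,
         folds = sel$folds, seed = sel$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
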