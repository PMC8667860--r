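#' @rdname feature_vector
#' @export
feature_vector <- function(values, names, block, sample_id = "") {
  values <- as.numeric(values)
  if (length(values) != length(names)) {
    stop_validation("feature values and names differ in length")
  }
  expected <- c(aac = 20L, dpc = 400L, aadp = 420L, composition = 400L,
                rpssm = 110L, fused = 930L)
  if (block %in% names(expected) && length(values) != expected[[block]]) {
    stop_validation("block '", block, "' must have ", expected[[block]],
                    " entries, got ", length(values))
  }
  structure(list(sample_id = sample_id, block = block,
                 names = names, values = stats::setNames(values, names)),
            class = "feature_vector")
}

#' Feature vector container
#'
#' A named, ordered block of real-valued descriptors for one protein.
#' Block dimensions are enforced: `aac` 20, `dpc` 400, `aadp` 420,
#' `composition` 400, `rpssm` 110, `fused` 930.
#'
#' @param values Numeric vector.
#' @param names Character vector of feature names, same length.
#' @param block Block tag.
#' @param sample_id Sample identifier.
#' @name feature_vector
#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> ", x$block, " (", length(x$values), "-d), sample '",
      x$sample_id, "'\n", sep = "")
  invisible(x)
}

scores_of <- function(m, sigmoid) {
  s <- m$scores
  storage.mode(s) <- "double"
  if (sigmoid) s <- 1 / (1 + exp(-s))
  s
}

#' Evolutionary amino-acid composition (AAC-PSSM, 20-d)
#'
#' The per-column mean of the PSSM: `x_j = (1/L) * sum_i p_ij`. Each of
#' the 20 values summarises how strongly the profile favours amino acid
#' j averaged over the whole sequence.
#'
#' @param m A [pssm_matrix()].
#' @param sigmoid Apply the logistic map `1/(1+exp(-p))` to every score
#'   first. Off by default: the descriptor definitions operate on the raw
#'   integer log-odds.
#' @return 20-d [feature_vector()], block `aac`.
#' @export
aac_pssm <- function(m, sigmoid = FALSE) {
  stopifnot(inherits(m, "pssm_matrix"))
  s <- scores_of(m, sigmoid)
  if (nrow(s) == 0L) stop_degenerate("empty PSSM")
  feature_vector(colMeans(s), paste0("AAC.", AA_ORDER), "aac", m$id)
}

#' Dipeptide cross-product descriptor (DPC-PSSM, 400-d)
#'
#' Products of consecutive profile rows:
#' `y_ij = (1/(L-1)) * sum_k p[k,i] * p[k+1,j]`, capturing local order
#' information that the column means discard. Because it reads scores,
#' not letters, positions occupied by `X` still contribute.
#'
#' @inheritParams aac_pssm
#' @return 400-d [feature_vector()], block `dpc`, flattened row-major
#'   over (i, j).
#' @export
dpc_pssm <- function(m, sigmoid = FALSE) {
  stopifnot(inherits(m, "pssm_matrix"))
  s <- scores_of(m, sigmoid)
  L <- nrow(s)
  if (L < 2L) stop_degenerate("DPC-PSSM requires sequence length >= 2")
  y <- crossprod(s[-L, , drop = FALSE], s[-1, , drop = FALSE]) / (L - 1)
  nms <- as.vector(t(outer(AA_ORDER, AA_ORDER,
                           function(a, b) paste0("DPC.", a, ".", b))))
  feature_vector(as.vector(t(y)), nms, "dpc", m$id)
}

#' Combined composition + dipeptide descriptor (AADP-PSSM, 420-d)
#'
#' Concatenation of [aac_pssm()] (20-d) and [dpc_pssm()] (400-d):
#' 20 + 400 = 420 dimensions.
#'
#' @inheritParams aac_pssm
#' @return 420-d [feature_vector()], block `aadp`.
#' @export
aadp_pssm <- function(m, sigmoid = FALSE) {
  a <- aac_pssm(m, sigmoid)
  d <- dpc_pssm(m, sigmoid)
  feature_vector(c(a$values, d$values), c(a$names, d$names), "aadp", m$id)
}

#' Residue-grouped profile composition (PSSM-COMPOSITION, 400-d)
#'
#' Rows of the PSSM are grouped by the residue letter occupying each
#' position: for residue type a and column j,
#' `c_aj = (1/L) * sum_{i: residue_i == a} p_ij`. The resulting 20 x 20
#' matrix (rows = residue type, columns = profile column) is flattened
#' row-major and min-max scaled to `[-1, 1]` over its 400 entries;
#' an all-constant vector maps to 0. Positions holding `X` contribute to
#' the length divisor L but to no residue group.
#'
#' @inheritParams aac_pssm
#' @param scale Apply the `[-1, 1]` min-max rescaling (the descriptor's
#'   definition); `FALSE` returns the raw length-normalised sums.
#' @return 400-d [feature_vector()], block `composition`.
#' @export
pssm_composition <- function(m, sigmoid = FALSE, scale = TRUE) {
  stopifnot(inherits(m, "pssm_matrix"))
  s <- scores_of(m, sigmoid)
  L <- nrow(s)
  if (L == 0L) stop_degenerate("empty PSSM")
  res <- strsplit(m$residues, "")[[1]]
  comp <- matrix(0, 20L, 20L, dimnames = list(AA_ORDER, AA_ORDER))
  for (a in AA_ORDER) {
    rows <- which(res == a)
    if (length(rows)) comp[a, ] <- colSums(s[rows, , drop = FALSE]) / L
  }
  v <- as.vector(t(comp))
  if (scale) {
    rng <- range(v)
    v <- if (diff(rng) == 0) rep(0, length(v)) else
      2 * (v - rng[1]) / diff(rng) - 1
  }
  nms <- as.vector(t(outer(AA_ORDER, AA_ORDER,
                           function(a, b) paste0("COMP.", a, ".", b))))
  feature_vector(v, nms, "composition", m$id)
}

#' Collapse a PSSM to a 10-column reduced-alphabet profile
#'
#' Each reduced column is the per-row mean of the original columns in
#' one group of the scheme (the mean, not the sum, so multi-member
#' groups are not inflated).
#'
#' @inheritParams aac_pssm
#' @param scheme A [reduction_scheme()].
#' @param agg Aggregation over grouped columns, `"mean"` (default) or
#'   `"sum"`.
#' @return Numeric L x 10 matrix with group-named columns.
#' @export
reduce_pssm <- function(m, scheme = reduction_scheme(), agg = c("mean", "sum"),
                        sigmoid = FALSE) {
  stopifnot(inherits(m, "pssm_matrix"))
  if (!inherits(scheme, "reduction_scheme")) {
    stop_validation("scheme must be a reduction_scheme object")
  }
  agg <- match.arg(agg)
  s <- scores_of(m, sigmoid)
  out <- vapply(scheme$groups, function(g) {
    block <- s[, g, drop = FALSE]
    if (agg == "mean") rowMeans(block) else rowSums(block)
  }, numeric(nrow(s)))
  out <- matrix(out, nrow = nrow(s), ncol = 10L,
                dimnames = list(NULL, scheme$group_names))
  out
}

#' Reduced-profile descriptor (RPSSM, 110-d)
#'
#' Over the L x 10 reduced profile from [reduce_pssm()]: first the 10
#' per-column pseudo-compositions, the population variance of each
#' reduced column, `D_s = (1/L) * sum_i (p[i,s] - mean(p[,s]))^2`; then
#' the 100 dipeptide terms over consecutive positions,
#' `D_st = (1/(L-1)) * sum_i (p[i,s] - p[i+1,t])^2 / 2`,
#' flattened row-major over (s, t). The dipeptide term uses the squared
#' DIFFERENCE of consecutive reduced scores, the form that measures
#' local profile change; a squared-sum variant is available for
#' comparison via `form = "sum"`.
#'
#' @inheritParams reduce_pssm
#' @param form `"difference"` (default) or `"sum"` for the dipeptide
#'   term.
#' @return 110-d [feature_vector()], block `rpssm`. All entries are
#'   non-negative under the default form.
#' @export
rpssm <- function(m, scheme = reduction_scheme(),
                  form = c("difference", "sum"), sigmoid = FALSE) {
  form <- match.arg(form)
  r <- reduce_pssm(m, scheme, sigmoid = sigmoid)
  L <- nrow(r)
  if (L < 2L) stop_degenerate("RPSSM requires sequence length >= 2")
  d_s <- colMeans(sweep(r, 2, colMeans(r))^2)
  a <- r[-L, , drop = FALSE]
  b <- r[-1, , drop = FALSE]
  pair <- matrix(0, 10L, 10L)
  for (s in 1:10) for (t in 1:10) {
    z <- if (form == "difference") a[, s] - b[, t] else a[, s] + b[, t]
    pair[s, t] <- sum(z^2 / 2) / (L - 1)
  }
  gn <- scheme$group_names
  nms <- c(paste0("RPSSM.D.", gn),
           as.vector(t(outer(gn, gn, function(x, y) paste0("RPSSM.DD.", x, ".", y)))))
  feature_vector(c(d_s, as.vector(t(pair))), nms, "rpssm", m$id)
}

#' Fuse the three descriptor blocks into one 930-d vector
#'
#' Concatenates, in fixed order, AADP-PSSM (420) | PSSM-COMPOSITION
#' (400) | RPSSM (110) = 930 dimensions. The order is fixed by block
#' tag, not by argument order, and all parts must describe the same
#' sample.
#'
#' @param parts List of exactly three [feature_vector()]s with blocks
#'   `aadp`, `composition` and `rpssm` (any order).
#' @return 930-d [feature_vector()], block `fused`.
#' @export
fuse_features <- function(parts) {
  blocks <- vapply(parts, function(p) p$block, "")
  need <- c("aadp", "composition", "rpssm")
  if (!setequal(blocks, need) || length(parts) != 3L) {
    stop_validation("fusion needs exactly the blocks aadp, composition, ",
                    "rpssm; got: ", paste(blocks, collapse = ", "))
  }
  ids <- unique(vapply(parts, function(p) p$sample_id, ""))
  if (length(ids) != 1L) {
    stop_validation("mismatched sample ids: ", paste(ids, collapse = ", "))
  }
  ord <- parts[match(need, blocks)]
  feature_vector(unlist(lapply(ord, function(p) unname(p$values))),
                 unlist(lapply(ord, function(p) p$names)),
                 "fused", ids)
}

#' Extract a feature table from a PSSM dataset
#'
#' Runs the selected descriptor blocks on every sample and stacks the
#' results into a samples x features table with 0/1 labels (1 =
#' DNA-binding). With all three blocks (the default) each row is the
#' fused 930-d vector.
#'
#' @param ds A [pssm_dataset()].
#' @param blocks Character subset of `c("aadp", "composition", "rpssm")`.
#' @param sigmoid Passed to the extractors.
#' @param scheme [reduction_scheme()] for the RPSSM block.
#' @param rpssm_form Dipeptide form for [rpssm()].
#' @return A [feature_table()].
#' @export
extract_features <- function(ds, blocks = c("aadp", "composition", "rpssm"),
                             sigmoid = FALSE, scheme = reduction_scheme(),
                             rpssm_form = "difference") {
  stopifnot(inherits(ds, "pssm_dataset"))
  blocks <- match.arg(blocks, several.ok = TRUE)
  ids <- c(ds$positives, ds$negatives)
  labels <- c(rep(1L, length(ds$positives)), rep(0L, length(ds$negatives)))
  one <- function(id) {
    m <- ds$pssms[[id]]
    parts <- list()
    if ("aadp" %in% blocks) parts <- c(parts, list(aadp_pssm(m, sigmoid)))
    if ("composition" %in% blocks)
      parts <- c(parts, list(pssm_composition(m, sigmoid)))
    if ("rpssm" %in% blocks)
      parts <- c(parts, list(rpssm(m, scheme, rpssm_form, sigmoid)))
    if (length(parts) == 3L) fuse_features(parts)
    else feature_vector(unlist(lapply(parts, function(p) unname(p$values))),
                        unlist(lapply(parts, function(p) p$names)),
                        paste(vapply(parts, function(p) p$block, ""),
                              collapse = "+"),
                        id)
  }
  fvs <- lapply(ids, one)
  vals <- do.call(rbind, lapply(fvs, function(f) unname(f$values)))
  feature_table(vals, sample_ids = ids, feature_names = fvs[[1]]$names,
                labels = labels)
}
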