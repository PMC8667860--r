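# Independent brute-force oracles: every formula coded as plain loops,
# deliberately sharing no code with the package implementations.

random_pssm <- function(seed, L = 20L, id = paste0("s", seed)) {
  set.seed(seed)
  sc <- matrix(sample(-8:12, L * 20L, replace = TRUE), L, 20L)
  res <- paste(sample(c(AA_ORDER, "X"), L, replace = TRUE,
                      prob = c(rep(1, 20), 0.5)), collapse = "")
  pssm_matrix(sc, res, id = id)
}

oracle_aac <- function(m) {
  s <- m$scores
  out <- numeric(20)
  for (j in 1:20) {
    acc <- 0
    for (i in seq_len(nrow(s))) acc <- acc + s[i, j]
    out[j] <- acc / nrow(s)
  }
  out
}

oracle_dpc <- function(m) {
  s <- m$scores
  L <- nrow(s)
  out <- numeric(400)
  pos <- 0
  for (i in 1:20) for (j in 1:20) {
    acc <- 0
    for (k in 1:(L - 1)) acc <- acc + s[k, i] * s[k + 1, j]
    pos <- pos + 1
    out[pos] <- acc / (L - 1)
  }
  out
}

# raw (unscaled) residue-grouped composition
oracle_comp_raw <- function(m) {
  s <- m$scores
  res <- strsplit(m$residues, "")[[1]]
  out <- numeric(400)
  pos <- 0
  for (a in AA_ORDER) for (j in 1:20) {
    acc <- 0
    for (i in seq_len(nrow(s))) if (res[i] == a) acc <- acc + s[i, j]
    pos <- pos + 1
    out[pos] <- acc / nrow(s)
  }
  out
}

oracle_minmax_scale <- function(v) {
  if (max(v) == min(v)) return(rep(0, length(v)))
  2 * (v - min(v)) / (max(v) - min(v)) - 1
}

oracle_reduce <- function(m, scheme) {
  s <- m$scores
  out <- matrix(0, nrow(s), 10)
  for (g in seq_along(scheme$groups)) {
    cols <- match(scheme$groups[[g]], AA_ORDER)
    for (i in seq_len(nrow(s))) out[i, g] <- mean(s[i, cols])
  }
  out
}

oracle_rpssm <- function(m, scheme) {
  r <- oracle_reduce(m, scheme)
  L <- nrow(r)
  d <- numeric(10)
  for (s in 1:10) {
    mu <- mean(r[, s])
    acc <- 0
    for (i in 1:L) acc <- acc + (r[i, s] - mu)^2
    d[s] <- acc / L
  }
  dd <- numeric(100)
  pos <- 0
  for (s in 1:10) for (t in 1:10) {
    acc <- 0
    for (i in 1:(L - 1)) acc <- acc + (r[i, s] - r[i + 1, t])^2 / 2
    pos <- pos + 1
    dd[pos] <- acc / (L - 1)
  }
  c(d, dd)
}

# textbook Pearson formula, written out
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my)) / (n - 1)
  den <- sqrt(sum((x - mx)^2) / (n - 1)) * sqrt(sum((y - my)^2) / (n - 1))
  if (den == 0) 0 else num / den
}

oracle_distances <- function(x, y) {
  ed <- sqrt(sum((x - y)^2))
  xy <- sum(x * y); xx <- sum(x * x); yy <- sum(y * y)
  list(ed = ed,
       cos = if (xx == 0 || yy == 0) 0 else xy / (sqrt(xx) * sqrt(yy)),
       tc = if (xx == 0 && yy == 0) 0 else xy / (xx + yy - xy))
}

# full O(M^2 N) MRMD ranking oracle mirroring the default configuration
oracle_rank <- function(X, y, weight = 0.5) {
  M <- ncol(X)
  maxMR <- ED <- COS <- TC <- numeric(M)
  for (i in 1:M) {
    maxMR[i] <- abs(oracle_pearson(X[, i], y))
    for (k in 1:M) {
      if (k == i) next
      d <- oracle_distances(X[, i], X[, k])
      ED[i] <- ED[i] + d$ed
      COS[i] <- COS[i] + d$cos
      TC[i] <- TC[i] + d$tc
    }
    ED[i] <- ED[i] / (M - 1)
    COS[i] <- COS[i] / (M - 1)
    TC[i] <- TC[i] / (M - 1)
  }
  edn <- if (max(ED) == min(ED)) rep(0, M) else
    (ED - min(ED)) / (max(ED) - min(ED))
  maxMD <- (edn + COS + TC) / 3
  score <- weight * maxMR + (1 - weight) * maxMD
  ord <- order(-score, seq_len(M))
  rank <- integer(M); rank[ord] <- seq_len(M)
  list(maxMR = maxMR, ED = ED, COS = COS, TC = TC,
       maxMD = maxMD, score = score, rank = rank)
}

oracle_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  den <- (tp + fn) * (tn + fn) * (tp + fp) * (tn + fp)
  list(acc = 100 * (tp + tn) / total,
       sn = if (tp + fn == 0) 0 else 100 * tp / (tp + fn),
       sp = if (tn + fp == 0) 0 else 100 * tn / (tn + fp),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

# pairwise Mann-Whitney concordance, ties counted one half
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (n in neg) {
    acc <- acc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

random_labelled_table <- function(seed, n = 20L, m = 5L) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  y <- rep_len(c(0L, 1L), n)[sample.int(n)]
  feature_table(X, paste0("s", seq_len(n)), paste0("f", seq_len(m)), y)
}
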