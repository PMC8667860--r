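test_that("AAC-PSSM is the per-column mean", {
  v <- sample(-8:12, 20, replace = TRUE)
  m <- pssm_matrix(matrix(rep(v, each = 4), 4, 20), "ACDE")
  expect_equal(unname(aac_pssm(m)$values), as.numeric(v))

  z <- pssm_matrix(matrix(0L, 3, 20), "ACD")
  expect_equal(unname(aac_pssm(z)$values), rep(0, 20))

  sc <- matrix(0L, 2, 20); sc[, 1] <- c(2L, 4L)
  m2 <- pssm_matrix(sc, "AC")
  expect_equal(unname(aac_pssm(m2)$values), c(3, rep(0, 19)))

  # mean invariance under row duplication
  m3 <- random_pssm(11, L = 15)
  doubled <- pssm_matrix(rbind(m3$scores, m3$scores),
                         paste0(m3$residues, m3$residues))
  expect_equal(aac_pssm(doubled)$values, aac_pssm(m3)$values,
               ignore_attr = TRUE)
})

test_that("DPC-PSSM equals the consecutive-row cross product", {
  sc <- rbind(rep(1L, 20), rep(2L, 20))
  m <- pssm_matrix(sc, "AC")
  expect_equal(unname(dpc_pssm(m)$values), rep(2, 400))

  z <- pssm_matrix(matrix(0L, 2, 20), "AC")
  expect_equal(unname(dpc_pssm(z)$values), rep(0, 400))

  m30 <- random_pssm(3, L = 30)
  expect_equal(unname(dpc_pssm(m30)$values), oracle_dpc(m30))

  one <- pssm_matrix(matrix(0L, 1, 20), "A")
  expect_error(dpc_pssm(one), class = "pssmDBP_degenerate_error")
})

test_that("AADP-PSSM concatenates AAC and DPC in order", {
  m <- random_pssm(3, L = 12)
  a <- aadp_pssm(m)
  expect_length(a$values, 420L)
  expect_equal(unname(a$values[1:20]), unname(aac_pssm(m)$values))
  expect_equal(unname(a$values[21:420]), unname(dpc_pssm(m)$values))
  expect_equal(unname(aadp_pssm(pssm_matrix(matrix(0L, 2, 20), "AC"))$values),
               rep(0, 420))
})

test_that("PSSM-COMPOSITION groups rows by residue and scales to [-1, 1]", {
  z <- pssm_matrix(matrix(0L, 3, 20), "ACD")
  expect_equal(unname(pssm_composition(z)$values), rep(0, 400))

  set.seed(9)
  sc <- matrix(sample(-8:12, 60, replace = TRUE), 3, 20)
  m <- pssm_matrix(sc, "AAC")
  raw <- unname(pssm_composition(m, scale = FALSE)$values)
  expect_equal(raw[1:20], (sc[1, ] + sc[2, ]) / 3)       # residue A row
  expect_equal(raw[81:100], sc[3, ] / 3)                 # residue C row
  expect_equal(raw[21:80], rep(0, 60))                   # R, N rows empty
  expect_equal(raw, oracle_comp_raw(m))

  scaled <- unname(pssm_composition(m)$values)
  expect_true(all(scaled >= -1 & scaled <= 1))
  expect_equal(max(scaled), 1)
  expect_equal(min(scaled), -1)
  expect_equal(scaled, oracle_minmax_scale(raw))

  # X rows count toward L but join no group
  mx <- pssm_matrix(sc, "AXC")
  rawx <- unname(pssm_composition(mx, scale = FALSE)$values)
  expect_equal(rawx[1:20], sc[1, ] / 3)
})

test_that("profile reduction averages grouped columns", {
  m <- random_pssm(5, L = 8)
  r <- reduce_pssm(m)
  expect_equal(ncol(r), 10L)
  expect_equal(nrow(r), 8L)
  expect_equal(r, oracle_reduce(m, reduction_scheme()), ignore_attr = TRUE)
  # singleton group reproduces the original column
  expect_equal(r[, "G"], as.numeric(m$scores[, "G"]))
  # two-member group is the mean
  sc <- matrix(0L, 3, 20)
  sc[, match("M", AA_ORDER)] <- 2L
  sc[, match("L", AA_ORDER)] <- 4L
  m2 <- pssm_matrix(sc, "ACD")
  expect_equal(unname(reduce_pssm(m2)[, "ML"]), rep(3, 3))

  expect_error(reduce_pssm(m, scheme = list(1, 2)),
               class = "pssmDBP_validation_error")
  expect_error(reduction_scheme(list(a = AA_ORDER)),
               class = "pssmDBP_validation_error")
  expect_error(reduction_scheme(c(DEFAULT_REDUCTION[-1],
                                  list(bad = c("F", "Y"), W = "W"))),
               class = "pssmDBP_validation_error")
})

test_that("RPSSM yields 10 column variances plus 100 dipeptide terms", {
  # constant reduced profile: everything vanishes
  m <- pssm_matrix(matrix(3L, 4, 20), "ACDE")
  expect_equal(unname(rpssm(m)$values), rep(0, 110))

  m2 <- random_pssm(6, L = 9)
  v <- rpssm(m2)
  expect_length(v$values, 110L)
  expect_true(all(v$values >= 0))
  expect_equal(unname(v$values), oracle_rpssm(m2, reduction_scheme()))

  # hand-checked variance: reduced column (1, 2, 3) has D_s = 2/3
  sc <- matrix(0L, 3, 20)
  sc[, match("G", AA_ORDER)] <- 1:3
  m3 <- pssm_matrix(sc, "ACD")
  expect_equal(unname(rpssm(m3)$values[["RPSSM.D.G"]]), 2 / 3)

  one <- pssm_matrix(matrix(0L, 1, 20), "A")
  expect_error(rpssm(one), class = "pssmDBP_degenerate_error")
})

test_that("the squared-sum dipeptide variant differs and stays available", {
  m <- random_pssm(8, L = 10)
  d <- unname(rpssm(m, form = "difference")$values)
  s <- unname(rpssm(m, form = "sum")$values)
  expect_equal(d[1:10], s[1:10])      # the variance part is shared
  expect_false(isTRUE(all.equal(d[11:110], s[11:110])))
})

test_that("fusion is 930-d, order-fixed, and checks sample identity", {
  m <- random_pssm(4, L = 14)
  parts <- list(aadp_pssm(m), pssm_composition(m), rpssm(m))
  fused <- fuse_features(parts)
  expect_length(fused$values, 930L)
  expect_equal(unname(fused$values[1:420]), unname(parts[[1]]$values))
  expect_equal(unname(fused$values[421:820]), unname(parts[[2]]$values))
  expect_equal(unname(fused$values[821:930]), unname(parts[[3]]$values))
  # argument order does not matter
  expect_equal(fuse_features(parts[c(3, 1, 2)]), fused)

  other <- aadp_pssm(random_pssm(5, L = 14, id = "other"))
  expect_error(fuse_features(list(other, parts[[2]], parts[[3]])),
               class = "pssmDBP_validation_error")
  expect_error(fuse_features(parts[1:2]), class = "pssmDBP_validation_error")
})

test_that("extractors match brute-force oracles on random profiles", {
  scheme <- reduction_scheme()
  for (seed in 0:49) {
    m <- random_pssm(seed, L = sample(2:25, 1))
    expect_equal(unname(aac_pssm(m)$values), oracle_aac(m), tolerance = 1e-10)
    expect_equal(unname(dpc_pssm(m)$values), oracle_dpc(m), tolerance = 1e-10)
    expect_equal(unname(pssm_composition(m, scale = FALSE)$values),
                 oracle_comp_raw(m), tolerance = 1e-10)
    expect_equal(unname(rpssm(m)$values), oracle_rpssm(m, scheme),
                 tolerance = 1e-10)
  }
})

test_that("the sigmoid option transforms scores before extraction", {
  m <- random_pssm(10, L = 8)
  sig <- 1 / (1 + exp(-m$scores))
  expect_equal(unname(aac_pssm(m, sigmoid = TRUE)$values),
               unname(colMeans(sig)))
  expect_false(isTRUE(all.equal(aac_pssm(m, sigmoid = TRUE)$values,
                                aac_pssm(m)$values)))
})

test_that("extract_features builds fused and per-block tables", {
  ds <- simulate_dataset(sim_spec(n_pos = 3, n_neg = 2,
                                  length_range = c(10, 15), seed = 7))
  t <- extract_features(ds)
  expect_equal(dim(t), c(5L, 930L))
  expect_equal(t$labels, c(1L, 1L, 1L, 0L, 0L))
  tr <- extract_features(ds, blocks = "rpssm")
  expect_equal(dim(tr), c(5L, 110L))
  # pure function of matrix + residues: matches per-sample fusion
  id <- ds$positives[1]
  fused <- fuse_features(list(aadp_pssm(ds$pssms[[id]]),
                              pssm_composition(ds$pssms[[id]]),
                              rpssm(ds$pssms[[id]])))
  expect_equal(unname(t$values[1, ]), unname(fused$values))
})
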