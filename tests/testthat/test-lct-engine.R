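test_that("shrinkage intensity matches its defining formula", {
  # nothing to shrink in one dimension
  expect_equal(estimate_shrinkage_intensity(matrix(rnorm(10))), 0)
  expect_error(estimate_shrinkage_intensity(matrix(1, 1, 2)),
               class = "llct_parameter_error")

  # exactly uncorrelated columns: 0/0 guarded to 0
  X0 <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(estimate_shrinkage_intensity(X0), 0)

  # 10x3 fixed random matrix: step-by-step formula oracle
  X <- with_test_seed(21, matrix(rnorm(30), 10, 3))
  expect_equal(estimate_shrinkage_intensity(X),
               shrinkage_intensity_oracle(X), tolerance = 1e-10)
  lam <- estimate_shrinkage_intensity(X)
  expect_true(lam >= 0 && lam <= 1)
})

test_that("covariance shrinkage preserves the diagonal", {
  X <- with_test_seed(22, matrix(rnorm(40), 10, 4))
  S <- cov(X)
  expect_equal(shrink_covariance(X, 1)$matrix, diag(diag(S)),
               ignore_attr = TRUE)
  expect_equal(shrink_covariance(X, 0)$matrix, S)
  for (lam in c(0.25, 0.8)) {
    Sl <- shrink_covariance(X, lam)$matrix
    expect_equal(diag(Sl), diag(S))
    off <- !diag(4)
    expect_equal(Sl[off], (1 - lam) * S[off])
  }
  # a diagonal covariance is a fixed point
  Xd <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(shrink_covariance(Xd, 0.6)$matrix, cov(Xd))
  expect_error(shrink_covariance(X, 1.5), class = "llct_parameter_error")
})

test_that("whitening reconstructs the covariance and drops null space", {
  wb <- whiten(diag(3))
  expect_equal(wb$values, rep(1, 3))
  expect_equal(wb$vectors %*% diag(wb$values) %*% t(wb$vectors), diag(3))

  v <- c(1, 2, -2)
  wb1 <- whiten(v %*% t(v))
  expect_equal(length(wb1$values), 1L)
  expect_equal(wb1$values, sum(v^2))

  S <- with_test_seed(23, crossprod(matrix(rnorm(60), 10, 6)))
  wbS <- whiten(S)
  expect_lt(max(abs(wbS$vectors %*% diag(wbS$values) %*% t(wbS$vectors) - S)),
            1e-8)
  expect_lt(max(abs(crossprod(wbS$vectors) - diag(ncol(S)))), 1e-8)
  expect_true(all(diff(wbS$values) <= 0))

  expect_error(whiten(matrix(0, 2, 2)), class = "llct_degenerate_error")
})

test_that("T2* agrees with direct correlation and the brute-force oracle", {
  # orthogonal blocks give a zero statistic
  G <- matrix(c(1, -1, 1, -1), 4)
  B <- matrix(c(1, 1, -1, -1), 4)
  expect_equal(lct_statistic(G, B, shrinkage = 0)$statistic, 0)

  # one column each: squared Pearson correlation
  with_test_seed(24, { g <- rnorm(15); b <- 0.5 * g + rnorm(15) })
  expect_equal(lct_statistic(matrix(g), matrix(b), shrinkage = 0)$statistic,
               cor(g, b)^2, tolerance = 1e-10)

  # 12 rows, 3 vs 2 columns: dense grid + refinement oracle
  with_test_seed(25, { G3 <- matrix(rnorm(36), 12); B2 <- matrix(rnorm(24), 12) })
  t2 <- lct_statistic(G3, B2, shrinkage = 0)$statistic
  expect_equal(t2, grid_max_sqcorr(G3, B2), tolerance = 1e-4)
  expect_true(t2 >= 0 && t2 <= 1)

  expect_error(lct_statistic(matrix(1, 5, 2), matrix(rnorm(5)),
                             shrinkage = 0),
               class = "llct_degenerate_error")
})

test_that("T2* is symmetric in its blocks and permutation-equivariant", {
  with_test_seed(26, {
    for (rep in 1:5) {
      G <- matrix(rnorm(48), 12)
      B <- matrix(rnorm(24), 12)
      s1 <- lct_statistic(G, B)$statistic
      s2 <- lct_statistic(B, G)$statistic
      expect_equal(s1, s2, tolerance = 1e-10)
      # permuting BOTH blocks by the same subject order changes nothing
      perm <- sample(12)
      s3 <- lct_statistic(G[perm, ], B[perm, ])$statistic
      expect_equal(s1, s3, tolerance = 1e-10)
    }
  })
})

test_that("loadings reproduce the statistic and have canonical sign", {
  with_test_seed(27, { G <- matrix(rnorm(60), 20); B <- matrix(rnorm(40), 20) })
  st <- lct_statistic(G, B, shrinkage = 0)
  expect_gt(st$eta[which(abs(st$eta) > 0)[1]], 0)
  # the recovered loadings achieve the statistic as a squared correlation
  zg <- as.vector(G %*% st$loadings_genes)
  zb <- as.vector(B %*% st$loadings_trends)
  expect_equal(cor(zg, zb)^2, st$statistic, tolerance = 1e-8)
})

test_that("permutation p-values follow the add-one rule", {
  # perfect association: observed beats every permutation
  with_test_seed(28, g <- rnorm(12))
  strong <- permutation_pvalue(matrix(g), matrix(2 * g), n_perm = 99,
                               seed = 31)
  expect_equal(strong$p_value, 1 / 100)

  # a gene block with all columns constant is degenerate, not p = 1
  G2 <- matrix(1, 12, 1)
  expect_error(permutation_pvalue(G2, matrix(rnorm(12)), n_perm = 19,
                                  seed = 1),
               class = "llct_degenerate_error")

  # p never leaves [1/(n_perm+1), 1] and is seed-reproducible
  with_test_seed(29, { G <- matrix(rnorm(30), 10); B <- matrix(rnorm(10)) })
  for (np in c(19, 99, 499)) {
    p <- permutation_pvalue(G, B, n_perm = np, seed = 5)$p_value
    expect_gte(p, 1 / (np + 1))
    expect_lte(p, 1)
  }
  expect_identical(permutation_pvalue(G, B, n_perm = 99, seed = 5)$p_value,
                   permutation_pvalue(G, B, n_perm = 99, seed = 5)$p_value)

  expect_error(permutation_pvalue(matrix(rnorm(2)), matrix(rnorm(2)),
                                  n_perm = 19, seed = 1),
               class = "llct_insufficient_error")
})

test_that("permutation ties give p = 1 when subject blocks are identical", {
  # two genes whose values repeat identically for every subject (Q = 2
  # rows per subject, varying within the block but identical across
  # subjects): any subject permutation reproduces the observed matrix
  I <- 6; Q <- 2
  block <- rbind(c(1, 3), c(2, 5))
  G <- block[rep(1:2, I), ]        # each subject's 2 rows are (1,3),(2,5)
  B <- with_test_seed(30, matrix(rnorm(I * Q), I * Q, 1))
  res <- permutation_pvalue(G, B, n_perm = 49, seed = 2, Q = Q)
  expect_equal(res$p_value, 1)
})

test_that("null permutation p-values are uniform", {
  ps <- with_test_seed(31, vapply(1:150, function(r) {
    G <- matrix(rnorm(36), 12)
    B <- matrix(rnorm(12))
    permutation_pvalue(G, B, n_perm = 99, seed = 1000 + r)$p_value
  }, numeric(1)))
  # permutation p-values live on a lattice; the tie warning is expected
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("BH adjustment and prioritization scores are exact", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  # hand BH on an uneven vector: q_i = min_{j>=i} p_(j) * n / j
  p <- c(0.005, 0.011, 0.02, 0.8)
  expect_equal(bh_fdr(p), c(0.02, 0.022, 0.8 / 30, 0.8))
  expect_error(bh_fdr(c(0.1, 0)), class = "llct_parameter_error")

  expect_equal(prioritization_scores(0.5), 1)
  expect_equal(prioritization_scores(c(0.1, 0.1, 0.5)), c(1, 1, 3) / 3)
  ps <- prioritization_scores(c(0.4, 0.01, 0.2))
  expect_equal(ps, c(3, 1, 2) / 3)
})

test_that("gene set analysis is deterministic and order-independent", {
  sim <- simulate_dataset(simulation_config(I = 12, P = 8), seed = 77)
  sets <- lapply(1:5, function(k)
    list(name = paste0("S", k), description = "d",
         genes = sample(sim$expression$gene_ids, 4)))
  coll <- gene_set_collection(sets)
  r1 <- suppressMessages(
    analyze_gene_sets(sim$dataset, sim$expression, coll, n_perm = 49,
                      seed = 9))
  r2 <- suppressMessages(
    analyze_gene_sets(sim$dataset, sim$expression, coll, n_perm = 49,
                      seed = 9))
  expect_identical(r1, r2)

  rev_coll <- gene_set_collection(rev(sets))
  r3 <- suppressMessages(
    analyze_gene_sets(sim$dataset, sim$expression, rev_coll, n_perm = 49,
                      seed = 9))
  expect_equal(r3$p_value[match(r1$set, r3$set)], r1$p_value)

  # q-values and prioritization scores are filled; failures recorded
  expect_true(all(!is.na(r1$q_value)))
  expect_true(all(r1$prioritization_score > 0 &
                  r1$prioritization_score <= 1))
  bad <- gene_set_collection(c(sets[1],
                               list(list(name = "none", description = "d",
                                         genes = "absent_gene"))))
  rb <- suppressMessages(
    analyze_gene_sets(sim$dataset, sim$expression, bad, n_perm = 49,
                      seed = 9))
  expect_true(is.na(rb$p_value[rb$set == "none"]))
  expect_match(rb$status[rb$set == "none"], "no usable genes")
})
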