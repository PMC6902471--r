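test_that("time design columns are fixed-order polynomial powers", {
  expect_equal(build_time_design(c(1, 2, 3), time_design_spec()),
               cbind(`(Intercept)` = c(1, 1, 1), `t^1` = c(1, 2, 3)))
  expect_equal(unname(build_time_design(2, time_design_spec(degree = 2))),
               matrix(c(1, 2, 4), 1))
  # degree 3 on 5 times: elementwise power oracle
  tms <- c(0.5, 1, 2.5, 4, 9)
  Z <- build_time_design(tms, time_design_spec(degree = 3))
  for (d in 1:3) expect_equal(unname(Z[, d + 1]), vapply(tms, `^`, 1, d))
})

test_that("per-subject OLS is exact and matches the normal equations", {
  Z <- build_time_design(c(1, 2, 3), time_design_spec())
  # constant outcome: intercept 5, slope 0
  f1 <- fit_subject_trends(matrix(c(5, 5, 5)), Z)
  expect_equal(unname(f1$beta[, 1]), c(5, 0))
  # exact linear: intercept 0, slope 2
  f2 <- fit_subject_trends(matrix(c(2, 4, 6)), Z)
  expect_equal(unname(f2$beta[, 1]), c(0, 2))

  # random 6x2 response with one covariate: normal-equations oracle
  with_test_seed(5, {
    t6 <- sort(runif(6, 0, 10))
    Y <- matrix(rnorm(12), 6, 2)
    W <- matrix(rnorm(6), 6, 1)
  })
  Z6 <- build_time_design(t6, time_design_spec())
  fit <- fit_subject_trends(Y, Z6, W)
  coef <- ols_oracle(cbind(Z6, W), Y)
  expect_equal(unname(fit$beta), unname(coef[1:2, , drop = FALSE]),
               tolerance = 1e-10)
  expect_equal(unname(fit$gamma), unname(coef[3, , drop = FALSE]),
               tolerance = 1e-10)
  # residuals orthogonal to design columns
  resid <- Y - cbind(Z6, W) %*% coef
  expect_lt(max(abs(t(cbind(Z6, W)) %*% resid)), 1e-8)

  # rank-deficient design names the subject
  Zdup <- build_time_design(c(2, 2), time_design_spec())
  expect_error(fit_subject_trends(matrix(c(1, 2)), Zdup, subject = "s9"),
               "s9", class = "llct_identifiability_error")
})

test_that("trend blocks stack per-subject coefficients with exclusions", {
  ds <- make_dataset(I = 3, n_i = 4, M = 2, seed = 3)
  tb <- assemble_trend_block(ds, time_design_spec())
  expect_equal(dim(tb$values), c(3L, 2L))  # slopes only, Q = 1
  expect_equal(tb$Q, 1L)

  # subject with 2 visits cannot support 3 parameters and is excluded
  ds2 <- make_dataset(I = 3, n_i = 4, M = 1, seed = 4, Qprime = 1)
  ds2$visits[[2]]$times <- ds2$visits[[2]]$times[1:2]
  ds2$visits[[2]]$Y <- ds2$visits[[2]]$Y[1:2, , drop = FALSE]
  ds2$visits[[2]]$W <- ds2$visits[[2]]$W[1:2, , drop = FALSE]
  tb2 <- assemble_trend_block(ds2, time_design_spec())
  expect_equal(length(tb2$subject_ids), 2L)
  expect_equal(tb2$excluded_subjects$subject, "s2")
  expect_match(tb2$excluded_subjects$reason, "visits")

  # Q = 2 (intercept + slope passed): rows 3-4 belong to subject 2,
  # matching an independent per-subject refit
  spec2 <- time_design_spec(pass_intercept = TRUE)
  tb3 <- assemble_trend_block(ds, spec2)
  expect_equal(dim(tb3$values), c(6L, 2L))
  v <- ds$visits[[2]]
  refit <- ols_oracle(build_time_design(v$times, spec2), v$Y)
  expect_equal(unname(tb3$values[3:4, ]), unname(refit), tolerance = 1e-10)

  # all subjects excluded is a hard error
  ds3 <- make_dataset(I = 2, n_i = 1, seed = 6)
  expect_error(assemble_trend_block(ds3, time_design_spec()),
               class = "llct_empty_analysis_error")
})

test_that("fitting is invariant to visit order and matches the slope formula", {
  ds <- make_dataset(I = 4, n_i = 5, M = 1, seed = 8)
  tb <- assemble_trend_block(ds, time_design_spec())
  ds_shuf <- ds
  for (s in ds$subject_ids) {
    perm <- with_test_seed(match(s, ds$subject_ids), sample(5))
    ds_shuf$visits[[s]]$times <- ds$visits[[s]]$times[perm]
    ds_shuf$visits[[s]]$Y <- ds$visits[[s]]$Y[perm, , drop = FALSE]
  }
  tb_shuf <- assemble_trend_block(ds_shuf, time_design_spec())
  expect_equal(tb$values, tb_shuf$values, tolerance = 1e-10)

  # classical least-squares slope formula
  for (s in ds$subject_ids) {
    v <- ds$visits[[s]]
    slope <- sum((v$times - mean(v$times)) * (v$Y - mean(v$Y))) /
      sum((v$times - mean(v$times))^2)
    expect_equal(unname(tb$values[match(s, tb$subject_ids), 1]), slope,
                 tolerance = 1e-10)
  }
})

test_that("gene blocks duplicate rows Q times and drop unusable genes", {
  em <- make_expression(I = 2, P = 1, seed = 11, subjects = c("a", "b"))
  gb <- expand_gene_block(em, "g1", Q = 2, subject_ids = c("a", "b"))
  expect_equal(unname(gb$values[, 1]),
               em$values[c(1, 1, 2, 2), 1], ignore_attr = TRUE)

  # Q = 1 is the identity case
  gb1 <- expand_gene_block(em, "g1", Q = 1, subject_ids = c("a", "b"))
  expect_equal(unname(gb1$values), unname(em$values))

  # 5 requested, 2 absent, 1 constant -> P = 2 with logged counts
  vals <- cbind(g1 = c(1, 2, 3), g2 = c(7, 7, 7), g3 = c(4, 1, 2))
  em2 <- expression_matrix(c("a", "b", "c"), colnames(vals), vals)
  msgs <- capture_messages(
    gb2 <- expand_gene_block(em2, c("g1", "g2", "g3", "gX", "gY"),
                             Q = 1, subject_ids = c("a", "b", "c")))
  expect_match(msgs, "2 absent, 1 constant", all = FALSE)
  expect_equal(gb2$gene_ids, c("g1", "g3"))
  expect_equal(gb2$n_absent, 2L)
  expect_equal(gb2$n_constant, 1L)

  expect_error(suppressMessages(
    expand_gene_block(em2, c("gX", "gY"), 1, c("a", "b", "c"))),
    class = "llct_empty_set_error")

  # trend and gene block row counts always agree
  ds <- make_dataset(I = 4, n_i = 5, seed = 12)
  em4 <- make_expression(I = 4, P = 3, seed = 13)
  for (spec in list(time_design_spec(),
                    time_design_spec(pass_intercept = TRUE),
                    time_design_spec(degree = 2))) {
    tb <- assemble_trend_block(ds, spec)
    gb <- expand_gene_block(em4, em4$gene_ids, tb$Q, tb$subject_ids)
    expect_equal(nrow(gb$values), nrow(tb$values))
  }
})
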