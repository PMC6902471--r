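# In-code fixtures and independent oracles shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small long-format phenotype CSV
fixture_phenotype_csv <- function() {
  write_lines_tmp(c(
    "subject,time,bp,hr",
    "s1,1,120,60",
    "s1,2,125,62",
    "s1,3,130,64",
    "s2,1,110,70",
    "s2,4,115,72",
    "s3,2,100,80",
    "s3,3,105,82",
    "s3,5,110,84",
    "s3,6,115,86"), ".csv")
}

fixture_expression_tsv <- function(subjects = c("s1", "s2", "s3"),
                                   genes = c("g1", "g2", "g3"),
                                   seed = 99) {
  vals <- with_test_seed(seed,
    matrix(round(rnorm(length(subjects) * length(genes)), 4),
           length(subjects)))
  lines <- c(paste(c("subject", genes), collapse = "\t"),
             vapply(seq_along(subjects), function(i)
               paste(c(subjects[i], format(vals[i, ], trim = TRUE)),
                     collapse = "\t"), character(1)))
  write_lines_tmp(lines, ".tsv")
}

fixture_gmt <- function(sets = list(S1 = c("g1", "g2"),
                                    S2 = c("g2", "g3"))) {
  write_lines_tmp(vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1)),
    ".gmt")
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# build a small longitudinal_dataset directly in code
make_dataset <- function(I = 5, n_i = 4, M = 1, seed = 1, Qprime = 0,
                         family_labels = NULL) {
  with_test_seed(seed, {
    visits <- lapply(seq_len(I), function(i) {
      times <- sort(runif(n_i, 1, 10))
      list(times = times,
           Y = matrix(rnorm(n_i * M), n_i, M),
           W = matrix(rnorm(n_i * Qprime), n_i, Qprime))
    })
    longitudinal_dataset(paste0("s", seq_len(I)), visits,
                         phenotype_names = paste0("y", seq_len(M)),
                         covariate_names = if (Qprime)
                           paste0("w", seq_len(Qprime)) else character(0),
                         family_labels = family_labels)
  })
}

make_expression <- function(I = 5, P = 4, seed = 2,
                            subjects = paste0("s", seq_len(I))) {
  with_test_seed(seed,
    expression_matrix(subjects, paste0("g", seq_len(P)),
                      matrix(rnorm(I * P), I)))
}

# two-group time-course generator: `slope_genes` of the genes change
# slope with the (binary) group covariate
tc_sim <- function(I = 20, genes = paste0("g", 1:10), slope_genes = 3,
                   effect = 1.5, noise = 0.3, seed = 1) {
  with_test_seed(seed, {
    grp <- rep(c(0, 1), length.out = I)
    d <- expand.grid(subject = seq_len(I), time = 0:3,
                     gene = seq_along(genes))
    slope <- 0.2 + effect * grp[d$subject] * (d$gene <= slope_genes)
    list(expr = data.frame(subject = paste0("s", d$subject),
                           time = d$time, gene = genes[d$gene],
                           value = slope * d$time +
                             rnorm(nrow(d), 0, noise),
                           stringsAsFactors = FALSE),
         cov = data.frame(subject = paste0("s", seq_len(I)), group = grp))
  })
}

# ---- independent oracles ----

# normal-equations OLS: solve(X'X) X'Y, no qr
ols_oracle <- function(X, Y) solve(t(X) %*% X) %*% t(X) %*% Y

# brute-force maximization of squared correlation between linear
# combinations of the two blocks: dense grid over unit vectors
# followed by Nelder-Mead refinement (the objective is scale-invariant,
# so refinement runs on raw coordinates)
unit_grid <- function(d, n = 24) {
  if (d == 1) return(matrix(1, 1, 1))
  if (d == 2) {
    th <- seq(0, pi, length.out = n + 1)[-(n + 1)]
    return(rbind(cos(th), sin(th)))
  }
  stopifnot(d == 3)
  g <- expand.grid(th = seq(0, pi, length.out = n),
                   ph = seq(0, pi, length.out = n + 1)[-(n + 1)])
  rbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
}

grid_max_sqcorr <- function(G, B, n = 24) {
  sq <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)^2
  }
  VA <- unit_grid(ncol(G), n); VB <- unit_grid(ncol(B), n)
  GX <- G %*% VA; BX <- B %*% VB
  cc <- suppressWarnings(cor(GX, BX))
  cc[!is.finite(cc)] <- 0
  best <- which(cc^2 == max(cc^2), arr.ind = TRUE)[1, ]
  par0 <- c(VA[, best[1]], VB[, best[2]])
  fn <- function(par) {
    a <- par[seq_len(ncol(G))]; b <- par[-seq_len(ncol(G))]
    -sq(as.vector(G %*% a), as.vector(B %*% b))
  }
  o <- optim(par0, fn, control = list(maxit = 5000, reltol = 1e-14))
  max(max(cc^2), -o$value)
}

# step-by-step recomputation of the shrinkage intensity formula with
# explicit loops (independent of the vectorized implementation)
shrinkage_intensity_oracle <- function(X) {
  n <- nrow(X); d <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  num <- 0; den <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i == j) next
    w <- Xc[, i] * Xc[, j]
    s_ij <- n / (n - 1) * mean(w)
    var_s <- n / (n - 1)^3 * sum((w - mean(w))^2)
    num <- num + var_s
    den <- den + s_ij^2
  }
  if (den == 0) return(0)
  min(1, max(0, num / den))
}
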