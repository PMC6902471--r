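# Step 2: shrinkage covariance, whitening, the largest-eigenvalue linear
# combination statistic, subject-permutation p-values, FDR and
# prioritization scores.

block_values <- function(x) {
  if (is.matrix(x)) x
  else if (inherits(x, c("expanded_gene_block", "trend_block"))) x$values
  else as.matrix(x)
}

# evaluate expr with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Analytic shrinkage intensity for a covariance matrix
#'
#' Estimates the optimal weight for pulling the unbiased sample
#' covariance toward its own diagonal:
#' `lambda* = clip( sum_{i!=j} Var_hat(s_ij) / sum_{i!=j} s_ij^2, 0, 1 )`,
#' where `Var_hat(s_ij)` is the usual estimate of the sampling variance
#' of the covariance `s_ij`. This is the standard analytic
#' (Ledoit-Wolf-style) intensity for the diagonal target; a 0/0
#' numerator and denominator (exactly uncorrelated columns) is guarded
#' to 0, as is the `d = 1` case where there is nothing to shrink.
#'
#' @param X `n x d` data matrix (centered internally).
#' @return intensity in `[0, 1]`.
#' @export
estimate_shrinkage_intensity <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) llct_error("need at least 2 rows", "llct_parameter_error")
  if (d == 1L) return(0)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  wbar <- crossprod(Xc) / n                    # mean of w_kij over k
  S <- wbar * n / (n - 1)                      # unbiased covariances
  sumw2 <- crossprod(Xc^2)                     # sum_k w_kij^2
  var_s <- n / (n - 1)^3 * (sumw2 - n * wbar^2)
  off <- upper.tri(S) | lower.tri(S)
  num <- sum(var_s[off]); den <- sum(S[off]^2)
  if (den == 0) return(0)
  min(1, max(0, num / den))
}

#' Shrink a sample covariance toward its diagonal
#'
#' `Sigma* = (1 - lambda) S + lambda diag(S)`: variances are preserved
#' exactly and off-diagonals are scaled by `1 - lambda`, which keeps the
#' estimate positive definite whenever any column varies.
#'
#' @param X `n x d` data matrix.
#' @param intensity `"auto"` (analytic, see
#'   [estimate_shrinkage_intensity]) or a fixed value in `[0, 1]`.
#' @return an object of class `shrunk_covariance`: list with `matrix`,
#'   `intensity` and `target`.
#' @export
shrink_covariance <- function(X, intensity = "auto") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) llct_error("need at least 2 rows", "llct_parameter_error")
  lam <- if (identical(intensity, "auto")) estimate_shrinkage_intensity(X)
         else as.numeric(intensity)
  if (!is.finite(lam) || lam < 0 || lam > 1)
    llct_error("shrinkage intensity must lie in [0, 1]",
               "llct_parameter_error")
  S <- stats::cov(X)
  Sstar <- (1 - lam) * S
  diag(Sstar) <- diag(S)
  structure(list(matrix = Sstar, intensity = lam,
                 target = "diagonal-of-sample-covariance"),
            class = "shrunk_covariance")
}

#' Eigendecompose a (shrunk) covariance for whitening
#'
#' Returns the orthonormal eigenvectors and descending eigenvalues of
#' the covariance; components with eigenvalue `<= rank_tolerance *
#' max(eigenvalue)` are excluded from the whitening transform.
#'
#' @param cov a `shrunk_covariance` or a symmetric PSD matrix.
#' @param rank_tolerance relative eigenvalue cutoff.
#' @return an object of class `whitened_basis`: list with `vectors`
#'   (`d x k`), `values` (length `k`, descending) and `rank_tolerance`.
#' @export
whiten <- function(cov, rank_tolerance = 1e-10) {
  S <- if (inherits(cov, "shrunk_covariance")) cov$matrix else as.matrix(cov)
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > rank_tolerance * max(e$values)
  if (!any(keep))
    llct_error("degenerate block: all eigenvalues below tolerance",
               "llct_degenerate_error")
  structure(list(vectors = e$vectors[, keep, drop = FALSE],
                 values = e$values[keep], rank_tolerance = rank_tolerance),
            class = "whitened_basis")
}

# center (optionally standardize) columns and return the whitened
# coordinates X_tilde = Xc Psi D^{-1/2} together with the basis
whiten_block <- function(X, shrinkage = "auto", rank_tolerance = 1e-10,
                         standardize = FALSE) {
  X <- block_values(X)
  Xc <- scale(X, center = TRUE, scale = standardize)
  if (all(apply(X, 2L, stats::var) == 0))
    llct_error("degenerate block: all columns constant",
               "llct_degenerate_error")
  sc <- shrink_covariance(Xc, shrinkage)
  wb <- whiten(sc, rank_tolerance)
  list(coords = Xc %*% sweep(wb$vectors, 2L, sqrt(wb$values), `/`),
       basis = wb, intensity = sc$intensity)
}

# largest singular value (squared) of the whitened cross-covariance;
# min(dim) is usually 1 in practice, where svd reduces to a norm
largest_sv2 <- function(C) {
  if (ncol(C) == 1L || nrow(C) == 1L) sum(C^2) else svd(C, nu = 0, nv = 0)$d[1]^2
}

#' The linear combination test statistic T2*
#'
#' Computes the largest squared singular value of the whitened
#' cross-covariance between the gene block and the trend block:
#' the maximum over loading pairs of the squared correlation between a
#' linear combination of gene expressions and a linear combination of
#' trend coefficients, with the two within-block covariances replaced
#' by their shrinkage versions. With shrinkage forced to 0 and full
#' rank this is exactly the squared first canonical correlation and
#' lies in `[0, 1]`.
#'
#' @param G_block `expanded_gene_block` or plain matrix (rows =
#'   subject-by-Q, columns = genes).
#' @param B_block `trend_block` or plain matrix (same row count,
#'   columns = trend coefficients).
#' @param shrinkage `"auto"` or a fixed intensity in `[0, 1]` applied to
#'   both within-block covariances (the cross-covariance is never
#'   shrunk).
#' @param rank_tolerance relative eigenvalue cutoff for whitening.
#' @param standardize scale block columns to unit variance before the
#'   covariance computation (off by default; the statistic is defined on
#'   covariances).
#' @return list with `statistic` (T2*), `eta`/`theta` (singular vectors
#'   in the whitened bases, sign fixed so the first nonzero entry of
#'   `eta` is positive), `loadings_genes` (`A`), `loadings_trends`
#'   (`Gamma`), and the shrinkage intensities used.
#' @export
lct_statistic <- function(G_block, B_block, shrinkage = "auto",
                          rank_tolerance = 1e-10, standardize = FALSE) {
  G <- block_values(G_block); B <- block_values(B_block)
  if (nrow(G) != nrow(B))
    llct_error("gene and trend blocks must have equal row counts",
               "llct_parameter_error")
  n <- nrow(G)
  wg <- whiten_block(G, shrinkage, rank_tolerance, standardize)
  wb <- whiten_block(B, shrinkage, rank_tolerance, standardize)
  C <- crossprod(wg$coords, wb$coords) / (n - 1)
  sv <- svd(C)
  T2 <- sv$d[1]^2
  eta <- sv$u[, 1]; theta <- sv$v[, 1]
  nz <- which(abs(eta) > 0)[1]
  if (!is.na(nz) && eta[nz] < 0) { eta <- -eta; theta <- -theta }
  A <- sweep(wg$basis$vectors, 2L, sqrt(wg$basis$values), `/`) %*% eta
  Gamma <- sweep(wb$basis$vectors, 2L, sqrt(wb$basis$values), `/`) %*% theta
  list(statistic = T2, eta = eta, theta = theta,
       loadings_genes = drop(A), loadings_trends = drop(Gamma),
       intensity_G = wg$intensity, intensity_B = wb$intensity)
}

# Shared permutation engine. `draw_perm` is called once per replicate
# and must return a subject-level source index vector of length I
# (subject slot j receives the gene rows of subject draw[j]). The
# whitening bases are computed once: permuting whole subjects leaves
# both within-block covariances unchanged, so only the cross-covariance
# and its largest singular value are recomputed per replicate.
perm_engine <- function(G_block, B_block, Q, n_perm, seed, draw_perm,
                        shrinkage = "auto", rank_tolerance = 1e-10,
                        standardize = FALSE) {
  G <- block_values(G_block); B <- block_values(B_block)
  if (nrow(G) != nrow(B))
    llct_error("gene and trend blocks must have equal row counts",
               "llct_parameter_error")
  n <- nrow(G)
  if (n %% Q != 0L)
    llct_error("row count is not a multiple of Q", "llct_parameter_error")
  I <- n %/% Q
  if (I < 3L)
    llct_error("need at least 3 subjects for permutation inference",
               "llct_insufficient_error")
  if (n_perm < 1L) llct_error("n_perm must be >= 1", "llct_parameter_error")
  wg <- whiten_block(G, shrinkage, rank_tolerance, standardize)
  wbk <- whiten_block(B, shrinkage, rank_tolerance, standardize)
  Gt <- wg$coords; Bt <- wbk$coords
  obs <- largest_sv2(crossprod(Gt, Bt) / (n - 1))
  base <- (seq_len(I) - 1L) * Q
  stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      perm <- draw_perm(I)
      rows <- rep(base[perm], each = Q) + seq_len(Q)
      largest_sv2(crossprod(Gt[rows, , drop = FALSE], Bt) / (n - 1))
    }, numeric(1))
  })
  p <- (1 + sum(stats >= obs)) / (1 + n_perm)
  list(p_value = p, statistic = obs, perm_statistics = stats,
       intensity_G = wg$intensity, intensity_B = wbk$intensity)
}

#' Subject-permutation p-value for the linear combination test
#'
#' Permutes whole subjects (entire `Q`-row blocks of the gene block move
#' together) relative to the trend block, recomputing only the whitened
#' cross-covariance per replicate; the eigendecompositions are computed
#' once because a subject permutation changes neither within-block
#' covariance. The p-value uses the add-one Monte-Carlo estimator
#' `p = (1 + #{T2*_perm >= T2*_obs}) / (1 + n_perm)`, so it is never 0
#' and never below `1/(n_perm + 1)`.
#'
#' @inheritParams lct_statistic
#' @param n_perm number of permutation replicates (default 1000).
#' @param seed integer seed for the permutation stream; the caller's RNG
#'   state is left untouched.
#' @param Q rows per subject; taken from the blocks when they carry it.
#' @return list with `p_value`, `statistic` (observed T2*),
#'   `perm_statistics` and the shrinkage intensities.
#' @export
permutation_pvalue <- function(G_block, B_block, n_perm = 1000L, seed = 1L,
                               Q = NULL, shrinkage = "auto",
                               rank_tolerance = 1e-10, standardize = FALSE) {
  if (is.null(Q))
    Q <- if (inherits(G_block, "expanded_gene_block")) G_block$Q
         else if (inherits(B_block, "trend_block")) B_block$Q else 1L
  perm_engine(G_block, B_block, Q, n_perm, seed,
              draw_perm = function(I) sample.int(I),
              shrinkage = shrinkage, rank_tolerance = rank_tolerance,
              standardize = standardize)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return step-up adjusted q-values, each `<= 1`.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    llct_error("p-values must lie in (0, 1]", "llct_parameter_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Prioritization scores
#'
#' For each tested set, the proportion of all sets with smaller
#' p-values, counted one-based: `PS_i = (#{j: p_j < p_i} + 1) / N`.
#' The unique smallest p-value gets `1/N`; ties share a score.
#'
#' @param p_values numeric vector (length `N >= 1`).
#' @return scores in `(0, 1]`.
#' @export
prioritization_scores <- function(p_values) {
  if (length(p_values) < 1L)
    llct_error("need at least one p-value", "llct_parameter_error")
  rank(p_values, ties.method = "min") / length(p_values)
}

#' Run the full two-step test over a gene-set collection
#'
#' Assembles the trend block once, then tests every gene set:
#' expression rows are subset and duplicated per set, the linear
#' combination statistic is computed, and a subject-permutation p-value
#' is attached. Each set gets its own deterministic seed derived from
#' the master seed and a stable hash of the set's name, so results do
#' not depend on the order in which sets are analyzed. q-values (Benjamini-Hochberg) and
#' prioritization scores are filled across the collection. Per-set
#' failures (e.g. no usable genes) are recorded in `status`, not fatal.
#'
#' @param dataset a [longitudinal_dataset].
#' @param expression an [expression_matrix] paired with `dataset`.
#' @param collection a [gene_set_collection].
#' @param spec a [time_design_spec].
#' @param n_perm,seed,shrinkage,rank_tolerance,standardize passed to the
#'   engine; `seed` is the master seed.
#' @return data frame with one row per set: `set`, `genes_used`,
#'   `statistic`, `p_value`, `q_value`, `prioritization_score`,
#'   `status`; per-set loadings are in `attr(, "details")`.
#' @export
analyze_gene_sets <- function(dataset, expression, collection,
                              spec = time_design_spec(), n_perm = 1000L,
                              seed = 1L, shrinkage = "auto",
                              rank_tolerance = 1e-10, standardize = FALSE) {
  check_paired(dataset, expression)
  tb <- assemble_trend_block(dataset, spec)
  analyze_sets_with_blocks(tb, expression, collection, n_perm, seed,
                           shrinkage, rank_tolerance, standardize)
}

# core shared by analyze_gene_sets and the time-course mode: one trend
# block, many gene sets
analyze_sets_with_blocks <- function(tb, expression, collection, n_perm,
                                     seed, shrinkage, rank_tolerance,
                                     standardize,
                                     perm_fun = permutation_pvalue, ...) {
  nsets <- length(collection$sets)
  out <- data.frame(set = vapply(collection$sets, `[[`, character(1), "name"),
                    genes_used = NA_integer_, statistic = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    prioritization_score = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  details <- vector("list", nsets)
  for (j in seq_len(nsets)) {
    set_seed_j <- derive_seed(seed, hash_string(collection$sets[[j]]$name))
    res <- tryCatch({
      gb <- expand_gene_block(expression, collection$sets[[j]]$genes,
                              tb$Q, tb$subject_ids)
      pv <- perm_fun(gb, tb, n_perm = n_perm, seed = set_seed_j,
                     shrinkage = shrinkage,
                     rank_tolerance = rank_tolerance,
                     standardize = standardize, ...)
      st <- lct_statistic(gb, tb, shrinkage, rank_tolerance, standardize)
      list(gb = gb, pv = pv, st = st)
    }, llct_error = function(e) e)
    if (inherits(res, "llct_error")) {
      out$status[j] <- conditionMessage(res)
      next
    }
    out$genes_used[j] <- length(res$gb$gene_ids)
    out$statistic[j] <- res$pv$statistic
    out$p_value[j] <- res$pv$p_value
    details[[j]] <- list(loadings_genes = res$st$loadings_genes,
                         loadings_trends = res$st$loadings_trends,
                         gene_ids = res$gb$gene_ids,
                         intensity_G = res$pv$intensity_G,
                         intensity_B = res$pv$intensity_B)
  }
  ok <- !is.na(out$p_value)
  if (any(ok)) {
    out$q_value[ok] <- bh_fdr(out$p_value[ok])
    out$prioritization_score[ok] <- prioritization_scores(out$p_value[ok])
  }
  attr(out, "details") <- details
  out
}

# deterministic per-set seed below 2^31, independent of execution order
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483629)
}

# stable non-cryptographic string hash so a set's permutation stream
# depends on its name, not its position in the collection
hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483629
  h
}
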