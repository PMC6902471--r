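# Generative model for evaluation: compound-symmetric gene sets, a
# random-intercept / random-slope phenotype trajectory with a gene-set
# main effect and gene-set-by-time interaction, AR(1) within-subject
# errors, and a rejection-rate harness.

#' Simulation configuration
#'
#' Parameters of the generative model used for type-I error and power
#' studies. Gene expressions for each subject are drawn from a
#' multivariate normal with mean vector sampled from a truncated
#' exponential (rate `lambda_exp`, truncated to `[0, exp_trunc]`) and a
#' compound-symmetric covariance (variance `sigma2_G`, common
#' correlation `rho_G`; set `gene_cor_structure = "ar1"` for a
#' geometric alternative). The single phenotype follows
#' `y_ij = B1*GS_i + B2*t_ij + B3*GS_i*t_ij + b0_i + b1_i*t_ij + e_ij`
#' with `GS_i` the subject's summed gene expression, random intercept
#' `b0_i ~ N(0, sigma2_b0)`, random slope `b1_i ~ N(0, sigma2_b1)`, and
#' errors with AR(1) correlation `rho_eps^|k-l|` in measurement index
#' and variance `sigma2_eps`. Visit times are uniform on `t_range` and
#' sorted within subject.
#'
#' Defaults state the evaluation world: 30 subjects, 30 genes, 4
#' visits on (1, 10), `sigma2_G = 0.5`, `rho_G = 0.5`, `B2 = 0.3`,
#' `rho_eps = 0.5`, random-intercept variance 1 and random-slope
#' variance 2, unit error variance, and a null gene-set effect
#' (`B1 = B3 = 0`).
#'
#' @param I subjects (>= 2).
#' @param P genes in the set (>= 2).
#' @param n_repeats visits per subject.
#' @param rho_G within-set gene correlation in `[0, 1)`.
#' @param sigma2_G gene variance.
#' @param lambda_exp rate of the truncated exponential for gene means.
#' @param exp_trunc upper truncation bound for gene means.
#' @param B1 gene main effect (scalar applied to all genes).
#' @param B2 time effect.
#' @param B3 gene-by-time interaction (scalar applied to all genes).
#' @param sigma2_b0,sigma2_b1 random intercept / slope variances.
#' @param rho_eps within-subject error autocorrelation in `[0, 1)`.
#' @param sigma2_eps error variance.
#' @param t_range visit-time range.
#' @param gene_cor_structure `"cs"` (compound symmetry) or `"ar1"`.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(I = 30L, P = 30L, n_repeats = 4L,
                              rho_G = 0.5, sigma2_G = 0.5,
                              lambda_exp = 0.7, exp_trunc = 5,
                              B1 = 0, B2 = 0.3, B3 = 0,
                              sigma2_b0 = 1, sigma2_b1 = 2,
                              rho_eps = 0.5, sigma2_eps = 1,
                              t_range = c(1, 10),
                              gene_cor_structure = c("cs", "ar1")) {
  gene_cor_structure <- match.arg(gene_cor_structure)
  if (I < 2L || P < 2L)
    llct_error("I and P must both be >= 2", "llct_parameter_error")
  if (n_repeats < 1L)
    llct_error("n_repeats must be >= 1", "llct_parameter_error")
  if (rho_G < 0 || rho_G >= 1 || rho_eps < 0 || rho_eps >= 1)
    llct_error("rho_G and rho_eps must lie in [0, 1)", "llct_parameter_error")
  if (sigma2_G <= 0 || sigma2_eps <= 0 || sigma2_b0 < 0 || sigma2_b1 < 0)
    llct_error("variances must be positive", "llct_parameter_error")
  if (gene_cor_structure == "cs" && rho_G > 0 && rho_G < 1) {
    # CS validity: rho > -1/(P-1); nonneg rho always fine
  }
  structure(list(I = as.integer(I), P = as.integer(P),
                 n_repeats = as.integer(n_repeats), rho_G = rho_G,
                 sigma2_G = sigma2_G, lambda_exp = lambda_exp,
                 exp_trunc = exp_trunc, B1 = B1, B2 = B2, B3 = B3,
                 sigma2_b0 = sigma2_b0, sigma2_b1 = sigma2_b1,
                 rho_eps = rho_eps, sigma2_eps = sigma2_eps,
                 t_range = t_range,
                 gene_cor_structure = gene_cor_structure),
            class = "simulation_config")
}

# inverse-CDF draw from Exp(rate) truncated to [0, hi]
rtrunc_exp <- function(n, rate, hi) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * hi))) / rate
}

gene_cov_matrix <- function(config) {
  P <- config$P
  R <- if (config$gene_cor_structure == "cs") {
    matrix(config$rho_G, P, P)
  } else {
    config$rho_G^abs(outer(seq_len(P), seq_len(P), `-`))
  }
  diag(R) <- 1
  config$sigma2_G * R
}

#' Simulate a gene-set expression matrix
#'
#' Rows (subjects) are independent draws from `MVN(M_G, Sigma_G)`; the
#' mean vector `M_G` is drawn once per call from the truncated
#' exponential, i.e. redrawn for every simulated gene set.
#'
#' @param config a [simulation_config].
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return `I x P` numeric matrix.
#' @export
simulate_gene_expressions <- function(config, seed = NULL) {
  draw <- function() {
    Sig <- gene_cov_matrix(config)
    ch <- tryCatch(chol(Sig), error = function(e)
      llct_error("gene covariance is not positive definite",
                 "llct_parameter_error"))
    mu <- rtrunc_exp(config$P, config$lambda_exp, config$exp_trunc)
    Z <- matrix(stats::rnorm(config$I * config$P), config$I)
    sweep(Z %*% ch, 2L, mu, `+`)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate the longitudinal phenotype given gene expressions
#'
#' @param G `I x P` gene expression matrix.
#' @param config a [simulation_config].
#' @param seed optional integer seed.
#' @return a [longitudinal_dataset] with a single phenotype `y`.
#' @export
simulate_phenotype <- function(G, config, seed = NULL) {
  draw <- function() {
    I <- nrow(G); n <- config$n_repeats
    GS <- rowSums(G)
    Rt <- config$rho_eps^abs(outer(seq_len(n), seq_len(n), `-`))
    ch <- chol(config$sigma2_eps * Rt)
    visits <- vector("list", I)
    for (i in seq_len(I)) {
      t_i <- sort(stats::runif(n, config$t_range[1], config$t_range[2]))
      b0 <- stats::rnorm(1, 0, sqrt(config$sigma2_b0))
      b1 <- stats::rnorm(1, 0, sqrt(config$sigma2_b1))
      eps <- drop(crossprod(ch, stats::rnorm(n)))
      y <- config$B1 * GS[i] + config$B2 * t_i +
        config$B3 * GS[i] * t_i + b0 + b1 * t_i + eps
      visits[[i]] <- list(times = t_i, Y = matrix(y, ncol = 1L),
                          W = matrix(0, n, 0L))
    }
    longitudinal_dataset(sprintf("S%04d", seq_len(I)), visits,
                         phenotype_names = "y")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate one paired dataset
#'
#' @param config a [simulation_config].
#' @param seed integer seed; `(config, seed)` fully determines the
#'   output.
#' @return list with `dataset` ([longitudinal_dataset]), `expression`
#'   ([expression_matrix]) and `config`.
#' @export
simulate_dataset <- function(config, seed = 1L) {
  with_seed(seed, {
    G <- simulate_gene_expressions(config)
    ds <- simulate_phenotype(G, config)
    em <- expression_matrix(ds$subject_ids,
                            sprintf("g%03d", seq_len(config$P)), G)
    list(dataset = ds, expression = em, config = config)
  })
}

#' Empirical rejection rate of the two-step test
#'
#' Simulates `n_sets` independent gene sets from `config`, runs the
#' full two-step pipeline (Step 1 slope extraction, Step 2 shrinkage
#' linear combination test with subject-permutation p-values) on each,
#' and returns the fraction of p-values at or below `alpha` with an
#' exact (Clopper-Pearson) 95% binomial confidence interval.
#'
#' @param config a [simulation_config].
#' @param n_sets simulated gene sets (>= 50 for a meaningful rate).
#' @param n_perm permutations per set.
#' @param alpha nominal level.
#' @param seed master seed; per-set seeds are derived from it.
#' @param spec a [time_design_spec].
#' @return list with `rate`, `ci` (length 2), `alpha`, `n_sets` and the
#'   vector `p_values`.
#' @export
estimate_rejection_rate <- function(config, n_sets = 500L, n_perm = 199L,
                                    alpha = 0.05, seed = 1L,
                                    spec = time_design_spec()) {
  p_values <- vapply(seq_len(n_sets), function(s) {
    sim_seed <- derive_seed(seed, s)
    sim <- simulate_dataset(config, sim_seed)
    tb <- assemble_trend_block(sim$dataset, spec)
    gb <- expand_gene_block(sim$expression, sim$expression$gene_ids,
                            tb$Q, tb$subject_ids)
    permutation_pvalue(gb, tb, n_perm = n_perm,
                       seed = derive_seed(sim_seed, 1L))$p_value
  }, numeric(1))
  k <- sum(p_values <= alpha)
  ci <- stats::binom.test(k, n_sets)$conf.int
  list(rate = k / n_sets, ci = as.numeric(ci), alpha = alpha,
       n_sets = n_sets, p_values = p_values)
}
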