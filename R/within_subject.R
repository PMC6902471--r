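# Step 1: per-subject least-squares time-trend estimation and assembly of
# the stacked coefficient block and the row-duplicated gene block.

#' Time design specification
#'
#' Controls the per-subject polynomial time design `Z_i`. By default the
#' design is `[1, t]` and only the time-trend rows (not the intercept)
#' are passed on to the between-subject test, because the test targets
#' correlation between gene expressions and *trends*. Setting
#' `pass_intercept = TRUE` additionally passes the fitted baseline
#' level, which is what the time-course "unwounded baseline" comparison
#' uses (there `degree = 0` is allowed).
#'
#' @param degree polynomial degree of the time design (>= 1; `degree = 0`
#'   is permitted only together with `include_intercept = TRUE` and
#'   `pass_intercept = TRUE`, giving an intercept-only baseline test).
#' @param include_intercept include a column of ones in `Z_i`.
#' @param pass_intercept pass the intercept coefficient row to Step 2.
#' @param center_time center times at their per-subject mean before
#'   building powers (numerical conditioning only; off by default so
#'   time enters raw).
#' @return an object of class `time_design_spec`.
#' @export
time_design_spec <- function(degree = 1L, include_intercept = TRUE,
                             pass_intercept = FALSE, center_time = FALSE) {
  degree <- as.integer(degree)
  if (degree < 0L)
    llct_error("polynomial degree must be >= 0", "llct_parameter_error")
  if (degree == 0L && !(include_intercept && pass_intercept))
    llct_error("degree 0 requires include_intercept and pass_intercept",
               "llct_parameter_error")
  structure(list(degree = degree, include_intercept = include_intercept,
                 pass_intercept = pass_intercept, center_time = center_time),
            class = "time_design_spec")
}

#' Build the polynomial time design matrix for one subject
#'
#' Columns are `[1 (if intercept), t, t^2, ..., t^degree]` in that fixed
#' order.
#'
#' @param times numeric vector of the subject's visit times.
#' @param spec a [time_design_spec].
#' @return numeric matrix with `length(times)` rows.
#' @export
build_time_design <- function(times, spec = time_design_spec()) {
  stopifnot(length(times) >= 1L, all(is.finite(times)))
  t <- if (spec$center_time) times - mean(times) else times
  cols <- list()
  if (spec$include_intercept) cols$`(Intercept)` <- rep(1, length(t))
  if (spec$degree >= 1L)
    for (d in seq_len(spec$degree)) cols[[paste0("t^", d)]] <- t^d
  do.call(cbind, cols)
}

#' Fit one subject's phenotype time trends by OLS
#'
#' Solves `Y = Z beta + W gamma + eps` jointly across the concatenated
#' design `[Z | W]`, for all phenotype columns at once. The covariate
#' coefficients `gamma` are estimated jointly (not by residualisation)
#' but are never passed to Step 2.
#'
#' @param Y `n_i x M` phenotype matrix.
#' @param Z `n_i x Q_full` time design (see [build_time_design]).
#' @param W optional `n_i x Q'` time-varying covariate matrix.
#' @param subject id used in error messages.
#' @return list with `beta` (`Q_full x M`) and `gamma` (`Q' x M`).
#' @export
fit_subject_trends <- function(Y, Z, W = NULL, subject = "?") {
  Y <- as.matrix(Y)
  X <- if (is.null(W) || ncol(as.matrix(W)) == 0L) Z else cbind(Z, as.matrix(W))
  if (nrow(Y) != nrow(X))
    llct_error("design/response row mismatch", "llct_parameter_error")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    llct_error(sprintf("rank-deficient design for subject '%s' (%d visits, %d parameters)",
                       subject, nrow(X), ncol(X)),
               "llct_identifiability_error")
  coef <- qr.coef(qx, Y)
  qz <- ncol(Z)
  list(beta = coef[seq_len(qz), , drop = FALSE],
       gamma = if (ncol(X) > qz) coef[-seq_len(qz), , drop = FALSE]
               else matrix(0, 0L, ncol(Y)))
}

#' Assemble the stacked trend-coefficient block (Step 1 output)
#'
#' Fits every subject's trends and stacks the coefficient rows that are
#' passed on to Step 2 into an `(I_eff * Q) x M` matrix, with subject
#' `i`'s rows occupying positions `(i-1)*Q + 1 ... i*Q`. Subjects whose
#' design cannot be identified (too few visits for the number of
#' parameters, or duplicated times making the design rank-deficient)
#' are excluded and listed with reasons; `Q` must be common to all
#' retained subjects, so no per-subject design reduction is attempted.
#'
#' @param dataset a [longitudinal_dataset].
#' @param spec a [time_design_spec].
#' @return an object of class `trend_block`: list with `values`
#'   (`(I_eff*Q) x M`), `Q`, `subject_ids` (retained, in order) and
#'   `excluded_subjects` (data frame of subject/reason).
#' @export
assemble_trend_block <- function(dataset, spec = time_design_spec()) {
  M <- length(dataset$phenotype_names)
  keep <- character(0); rows <- list(); excl <- list()
  pass_rows <- NULL
  for (sid in dataset$subject_ids) {
    v <- dataset$visits[[sid]]
    Z <- build_time_design(v$times, spec)
    p_full <- ncol(Z) + ncol(v$W)
    if (length(v$times) < p_full) {
      excl[[sid]] <- sprintf("%d visits < %d parameters",
                             length(v$times), p_full)
      next
    }
    fit <- tryCatch(fit_subject_trends(v$Y, Z, v$W, subject = sid),
                    llct_identifiability_error = function(e) NULL)
    if (is.null(fit)) {
      excl[[sid]] <- "rank-deficient design (e.g. duplicated times)"
      next
    }
    if (is.null(pass_rows)) {
      pass_rows <- if (spec$include_intercept && !spec$pass_intercept)
        seq_len(nrow(fit$beta))[-1] else seq_len(nrow(fit$beta))
    }
    keep <- c(keep, sid)
    rows[[sid]] <- fit$beta[pass_rows, , drop = FALSE]
  }
  if (length(keep) == 0L)
    llct_error("all subjects excluded; nothing to analyse",
               "llct_empty_analysis_error")
  Q <- length(pass_rows)
  values <- do.call(rbind, rows)
  dimnames(values) <- list(NULL, dataset$phenotype_names)
  structure(list(values = values, Q = Q, subject_ids = keep,
                 excluded_subjects = data.frame(
                   subject = names(excl),
                   reason = unlist(excl, use.names = FALSE),
                   stringsAsFactors = FALSE)),
            class = "trend_block")
}

#' @export
print.trend_block <- function(x, ...) {
  cat(sprintf("trend_block: %d subjects x Q=%d rows each, %d phenotype column(s)\n",
              length(x$subject_ids), x$Q, ncol(x$values)))
  if (nrow(x$excluded_subjects))
    cat(sprintf("  %d subject(s) excluded\n", nrow(x$excluded_subjects)))
  invisible(x)
}

#' Build the row-duplicated gene block for one gene set
#'
#' Subsets the expression matrix to the set's genes (silently dropping,
#' with logged counts, genes absent from the matrix and genes with zero
#' variance across the retained subjects) and repeats each subject's
#' gene row `Q` consecutive times, so the block is row-conformable with
#' the stacked trend block.
#'
#' @param expression an [expression_matrix].
#' @param genes member gene ids of the set.
#' @param Q rows per subject (from the trend block).
#' @param subject_ids retained subjects, in trend-block order.
#' @return an object of class `expanded_gene_block`: list with `values`
#'   (`(I*Q) x P`), `gene_ids`, `Q`, `subject_ids`, and drop counts
#'   `n_absent`, `n_constant`.
#' @export
expand_gene_block <- function(expression, genes, Q, subject_ids) {
  stopifnot(Q >= 1L)
  genes <- unique(as.character(genes))
  present <- genes[genes %in% expression$gene_ids]
  n_absent <- length(genes) - length(present)
  sub <- expression$values[subject_ids, present, drop = FALSE]
  v <- apply(sub, 2L, stats::var)
  keep <- present[v > 0]
  n_constant <- length(present) - length(keep)
  if (n_absent + n_constant > 0L)
    message(sprintf("gene set: %d absent, %d constant gene(s) dropped",
                    n_absent, n_constant))
  if (length(keep) == 0L)
    llct_error("no usable genes remain in this gene set",
               "llct_empty_set_error")
  sub <- sub[, keep, drop = FALSE]
  idx <- rep(seq_along(subject_ids), each = Q)
  structure(list(values = sub[idx, , drop = FALSE], gene_ids = keep,
                 Q = as.integer(Q), subject_ids = subject_ids,
                 n_absent = n_absent, n_constant = n_constant),
            class = "expanded_gene_block")
}
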