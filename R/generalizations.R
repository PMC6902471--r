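# Generalizations: family-clustered permutation, and the time-course mode
# where gene expressions are the repeatedly measured outcomes.

#' Family / cluster structure
#'
#' @param subject_ids analyzed subjects, in analysis order.
#' @param labels family label per subject (same order, or named by
#'   subject id).
#' @return an object of class `family_structure`.
#' @export
family_structure <- function(subject_ids, labels) {
  subject_ids <- as.character(subject_ids)
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    if (!all(subject_ids %in% names(labels)))
      llct_error("family labels must cover all analyzed subjects",
                 "llct_parameter_error")
    labels <- labels[subject_ids]
  } else if (length(labels) != length(subject_ids)) {
    llct_error("one family label required per subject",
               "llct_parameter_error")
  }
  fam_order <- unique(labels)
  if (length(fam_order) < 2L)
    llct_error("at least 2 families required", "llct_parameter_error")
  members <- lapply(fam_order, function(f) which(labels == f))
  structure(list(family_of_subject = stats::setNames(labels, subject_ids),
                 family_ids = fam_order, members = members,
                 sizes = lengths(members)),
            class = "family_structure")
}

#' Family-clustered permutation p-value
#'
#' Permutation replicates exchange whole families' gene-expression
#' sub-blocks: family labels are permuted among families of equal size
#' (subjects within a family keep their order and move together
#' relative to their trend rows), preserving the within-family
#' correlation structure under the null. With every family a singleton
#' this reduces exactly to the ordinary subject permutation, replicate
#' for replicate under the same seed. The add-one p-value rule applies.
#'
#' @inheritParams permutation_pvalue
#' @param families a [family_structure] whose subject order matches the
#'   blocks' subject order.
#' @return as [permutation_pvalue].
#' @export
family_permutation_pvalue <- function(G_block, B_block, families,
                                      n_perm = 1000L, seed = 1L, Q = NULL,
                                      shrinkage = "auto",
                                      rank_tolerance = 1e-10,
                                      standardize = FALSE) {
  if (!inherits(families, "family_structure"))
    llct_error("families must be a family_structure", "llct_parameter_error")
  if (is.null(Q))
    Q <- if (inherits(G_block, "expanded_gene_block")) G_block$Q
         else if (inherits(B_block, "trend_block")) B_block$Q else 1L
  classes <- split(seq_along(families$members), families$sizes)
  if (!any(lengths(classes) >= 2L))
    llct_error(paste("no two families of equal size: family-preserving",
                     "permutation is infeasible"),
               "llct_infeasible_error")
  members <- families$members
  I_expect <- sum(families$sizes)
  draw_perm <- function(I) {
    if (I != I_expect)
      llct_error("family structure does not cover the analyzed subjects",
                 "llct_parameter_error")
    assign <- seq_along(members)
    for (cl in classes)
      if (length(cl) >= 2L) assign[cl] <- cl[sample.int(length(cl))]
    pi <- integer(I)
    for (f in seq_along(members)) pi[members[[f]]] <- members[[assign[f]]]
    pi
  }
  perm_engine(G_block, B_block, Q, n_perm, seed, draw_perm,
              shrinkage = shrinkage, rank_tolerance = rank_tolerance,
              standardize = standardize)
}

#' Gene set analysis with family-clustered subjects
#'
#' As [analyze_gene_sets] but with the permutation unit being the
#' family (taken from the dataset's `family_labels`).
#'
#' @inheritParams analyze_gene_sets
#' @export
analyze_gene_sets_family <- function(dataset, expression, collection,
                                     spec = time_design_spec(),
                                     n_perm = 1000L, seed = 1L,
                                     shrinkage = "auto",
                                     rank_tolerance = 1e-10,
                                     standardize = FALSE) {
  check_paired(dataset, expression)
  if (is.null(dataset$family_labels))
    llct_error("dataset carries no family labels", "llct_parameter_error")
  tb <- assemble_trend_block(dataset, spec)
  fams <- family_structure(tb$subject_ids,
                           dataset$family_labels[tb$subject_ids])
  analyze_sets_with_blocks(tb, expression, collection, n_perm, seed,
                           shrinkage, rank_tolerance, standardize,
                           perm_fun = family_permutation_pvalue,
                           families = fams)
}

#' Time-course gene set analysis
#'
#' The role-swapped mode for designs where gene expressions are the
#' repeatedly measured outcomes. Step 1 fits, per subject (sample
#' series), the time trend of every gene in the tested set (genes play
#' the role of the phenotypes); Step 2 tests the maximum correlation
#' between linear combinations of the subjects' covariate values and
#' linear combinations of the stacked gene-trend coefficients, with
#' subject permutation. An optional closed time window restricts the
#' visits used (stage-wise analysis); with
#' `time_design_spec(degree = 0, pass_intercept = TRUE)` the test
#' compares fitted baseline levels instead of trends.
#'
#' @param expr_long long-format expression data frame with columns
#'   `subject`, `time`, `gene`, `value`.
#' @param covariates per-subject covariate data: data frame or matrix
#'   with one row per subject (rownames or a `subject` column) and one
#'   column per covariate; covariates must vary across subjects.
#' @param collection a [gene_set_collection].
#' @param spec a [time_design_spec].
#' @param window optional `c(lo, hi)` closed time interval.
#' @inheritParams analyze_gene_sets
#' @return as [analyze_gene_sets].
#' @export
time_course_analyze <- function(expr_long, covariates, collection,
                                spec = time_design_spec(),
                                window = NULL, n_perm = 1000L, seed = 1L,
                                shrinkage = "auto", rank_tolerance = 1e-10,
                                standardize = FALSE) {
  need <- c("subject", "time", "gene", "value")
  if (!all(need %in% names(expr_long)))
    llct_error("expr_long needs columns subject, time, gene, value",
               "llct_format_error")
  expr_long$subject <- as.character(expr_long$subject)
  expr_long$gene <- as.character(expr_long$gene)
  if (!is.null(window)) {
    expr_long <- expr_long[expr_long$time >= window[1] &
                           expr_long$time <= window[2], , drop = FALSE]
    if (spec$degree >= 1L &&
        length(unique(expr_long$time)) < 2L)
      llct_error("time window contains fewer than 2 distinct times",
                 "llct_design_error")
    if (nrow(expr_long) == 0L)
      llct_error("time window contains no observations", "llct_design_error")
  }
  covariates <- as.data.frame(covariates)
  if ("subject" %in% names(covariates)) {
    rownames(covariates) <- as.character(covariates$subject)
    covariates$subject <- NULL
  }
  subj <- unique(expr_long$subject)
  if (!all(subj %in% rownames(covariates)))
    llct_error("covariates missing for some subjects", "llct_parameter_error")
  covm <- as.matrix(covariates[subj, , drop = FALSE])
  storage.mode(covm) <- "double"
  if (any(apply(covm, 2L, stats::var) == 0))
    llct_error("zero-variance covariate: nothing to correlate",
               "llct_degenerate_error")

  all_genes <- unique(expr_long$gene)
  nsets <- length(collection$sets)
  out <- data.frame(set = vapply(collection$sets, `[[`, character(1), "name"),
                    genes_used = NA_integer_, statistic = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    prioritization_score = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  details <- vector("list", nsets)
  for (j in seq_len(nsets)) {
    res <- tryCatch({
      genes <- intersect(collection$sets[[j]]$genes, all_genes)
      if (length(genes) == 0L)
        llct_error("no genes of this set measured", "llct_empty_set_error")
      ds <- tc_build_dataset(expr_long, subj, genes)
      tb <- assemble_trend_block(ds, spec)
      idx <- match(tb$subject_ids, subj)
      cb <- covm[rep(idx, each = tb$Q), , drop = FALSE]
      pv <- permutation_pvalue(cb, tb, n_perm = n_perm,
                               seed = derive_seed(
                                 seed, hash_string(collection$sets[[j]]$name)),
                               Q = tb$Q,
                               shrinkage = shrinkage,
                               rank_tolerance = rank_tolerance,
                               standardize = standardize)
      st <- lct_statistic(cb, tb, shrinkage, rank_tolerance, standardize)
      list(genes = genes, pv = pv, st = st)
    }, llct_error = function(e) e)
    if (inherits(res, "llct_error")) {
      out$status[j] <- conditionMessage(res)
      next
    }
    out$genes_used[j] <- length(res$genes)
    out$statistic[j] <- res$pv$statistic
    out$p_value[j] <- res$pv$p_value
    details[[j]] <- list(loadings_covariates = res$st$loadings_genes,
                         loadings_gene_trends = res$st$loadings_trends,
                         gene_ids = res$genes)
  }
  ok <- !is.na(out$p_value)
  if (any(ok)) {
    out$q_value[ok] <- bh_fdr(out$p_value[ok])
    out$prioritization_score[ok] <- prioritization_scores(out$p_value[ok])
  }
  attr(out, "details") <- details
  out
}

# assemble a longitudinal_dataset in which the tested set's genes play
# the role of the M phenotypes
tc_build_dataset <- function(expr_long, subj, genes) {
  el <- expr_long[expr_long$gene %in% genes, , drop = FALSE]
  visits <- lapply(subj, function(s) {
    es <- el[el$subject == s, , drop = FALSE]
    times <- sort(unique(es$time))
    Y <- matrix(NA_real_, length(times), length(genes),
                dimnames = list(NULL, genes))
    Y[cbind(match(es$time, times), match(es$gene, genes))] <- es$value
    keep <- stats::complete.cases(Y)
    list(times = times[keep], Y = Y[keep, , drop = FALSE],
         W = matrix(0, sum(keep), 0L))
  })
  longitudinal_dataset(subj, visits, phenotype_names = genes)
}
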