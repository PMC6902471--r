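# Readers/writers for the delimited formats the tool touches, plus the
# domain containers they validate into.

llct_error <- function(msg, class) {
  stop(structure(class = c(class, "llct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

read_table_auto <- function(path, delim = "auto") {
  if (identical(delim, "auto")) delim <- detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    na.strings = c("NA", ""))
}

#' Longitudinal phenotype dataset
#'
#' Container for per-subject phenotype trajectories: for every subject an
#' ordered vector of visit times, an `n_i x M` matrix of phenotype values,
#' and an optional `n_i x Q'` matrix of time-varying covariates. Subjects
#' may have different numbers of visits (unbalanced designs are the normal
#' case for this method).
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param visits named list (one entry per subject, same order as
#'   `subject_ids`) of lists with elements `times` (numeric), `Y`
#'   (numeric matrix, rows = visits, columns = phenotypes) and `W`
#'   (numeric matrix of time-varying covariates, possibly 0 columns).
#' @param phenotype_names,covariate_names column labels.
#' @param family_labels optional character vector (named by subject id)
#'   assigning each subject to a family/cluster.
#' @return an object of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(subject_ids, visits, phenotype_names,
                                 covariate_names = character(0),
                                 family_labels = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    llct_error("duplicated subject identifiers", "llct_format_error")
  if (length(visits) != length(subject_ids))
    llct_error("one visit record required per subject", "llct_format_error")
  M <- length(phenotype_names)
  if (M < 1L) llct_error("at least one phenotype required", "llct_format_error")
  for (i in seq_along(visits)) {
    v <- visits[[i]]
    n_i <- length(v$times)
    if (n_i < 1L)
      llct_error(sprintf("subject '%s' has no visits", subject_ids[i]),
                 "llct_format_error")
    if (!all(is.finite(v$times)))
      llct_error(sprintf("non-finite time for subject '%s'", subject_ids[i]),
                 "llct_format_error")
    if (!is.matrix(v$Y) || nrow(v$Y) != n_i || ncol(v$Y) != M)
      llct_error(sprintf("phenotype matrix shape mismatch for subject '%s'",
                         subject_ids[i]), "llct_format_error")
    if (!is.matrix(v$W) || nrow(v$W) != n_i ||
        ncol(v$W) != length(covariate_names))
      llct_error(sprintf("covariate matrix shape mismatch for subject '%s'",
                         subject_ids[i]), "llct_format_error")
  }
  if (!is.null(family_labels)) {
    family_labels <- as.character(family_labels)
    if (is.null(names(family_labels))) names(family_labels) <- subject_ids
    if (!all(subject_ids %in% names(family_labels)))
      llct_error("family labels must cover all subjects", "llct_format_error")
    family_labels <- family_labels[subject_ids]
  }
  names(visits) <- subject_ids
  structure(list(subject_ids = subject_ids, visits = visits,
                 phenotype_names = phenotype_names,
                 covariate_names = covariate_names,
                 family_labels = family_labels),
            class = "longitudinal_dataset")
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  n_i <- vapply(x$visits, function(v) length(v$times), integer(1))
  cat(sprintf("longitudinal_dataset: %d subjects, %d phenotype(s), %d covariate(s)\n",
              length(x$subject_ids), length(x$phenotype_names),
              length(x$covariate_names)))
  cat(sprintf("  visits per subject: %d-%d (total %d)\n",
              min(n_i), max(n_i), sum(n_i)))
  if (!is.null(x$family_labels))
    cat(sprintf("  %d families\n", length(unique(x$family_labels))))
  invisible(x)
}

#' Gene expression matrix
#'
#' Subjects-by-genes matrix of expression values with identifiers.
#' Zero-variance (constant) genes are flagged in attribute
#' `constant_genes` but kept; they are dropped later, per gene set.
#'
#' @param subject_ids,gene_ids identifiers; `gene_ids` must be unique.
#' @param values numeric matrix, `length(subject_ids)` rows.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(subject_ids, gene_ids, values) {
  subject_ids <- as.character(subject_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    llct_error("duplicated gene identifiers", "llct_format_error")
  values <- as.matrix(values)
  if (nrow(values) != length(subject_ids) || ncol(values) != length(gene_ids))
    llct_error("expression matrix shape mismatch", "llct_format_error")
  if (!all(is.finite(values)))
    llct_error("non-finite expression values", "llct_format_error")
  dimnames(values) <- list(subject_ids, gene_ids)
  v <- apply(values, 2L, stats::var)
  structure(list(subject_ids = subject_ids, gene_ids = gene_ids,
                 values = values),
            constant_genes = gene_ids[v == 0],
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d subjects x %d genes\n",
              length(x$subject_ids), length(x$gene_ids)))
  invisible(x)
}

#' Gene set collection
#'
#' @param sets list of lists with elements `name`, `description`, `genes`.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    llct_error("duplicated gene set names", "llct_format_error")
  if (any(vapply(sets, function(s) length(s$genes) == 0L, logical(1))))
    llct_error("empty gene set", "llct_format_error")
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1))
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a long-format phenotype table
#'
#' Expects one row per subject visit. Visits with a missing time are
#' dropped; visits with any missing phenotype value are dropped whole
#' (Step 1 fits all phenotypes of a subject jointly over the same visit
#' matrix). Subjects left with no usable visit are excluded with a
#' warning. Rows are grouped by subject in order of first appearance and
#' sorted by time within subject.
#'
#' @param path delimited text file (tab or comma; auto-detected).
#' @param subject_col,time_col column names for the subject id and visit
#'   time.
#' @param phenotype_cols character vector of phenotype columns; `NULL`
#'   means every column not otherwise claimed.
#' @param covariate_cols optional time-varying covariate columns.
#' @param family_col optional family/cluster label column (constant
#'   within subject).
#' @param delim `"auto"`, `"\t"` or `","`.
#' @return a [longitudinal_dataset].
#' @export
read_long_phenotypes <- function(path, subject_col = "subject",
                                 time_col = "time", phenotype_cols = NULL,
                                 covariate_cols = character(0),
                                 family_col = NULL, delim = "auto") {
  df <- read_table_auto(path, delim)
  need <- c(subject_col, time_col, covariate_cols, family_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    llct_error(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "llct_format_error")
  if (is.null(phenotype_cols))
    phenotype_cols <- setdiff(names(df), need)
  if (length(phenotype_cols) == 0L)
    llct_error("no phenotype columns found", "llct_format_error")
  if (!all(phenotype_cols %in% names(df)))
    llct_error("missing phenotype column(s)", "llct_format_error")
  all_subjects <- unique(as.character(df[[subject_col]]))
  tm <- df[[time_col]]
  if (!is.numeric(tm)) {
    suppressWarnings(tm_num <- as.numeric(tm))
    if (any(!is.na(tm) & is.na(tm_num)))
      llct_error("non-numeric time values", "llct_format_error")
    tm <- tm_num
  }
  df[[time_col]] <- tm

  keep_t <- !is.na(df[[time_col]])
  if (any(!keep_t))
    message(sprintf("dropped %d visit(s) with missing time", sum(!keep_t)))
  df <- df[keep_t, , drop = FALSE]

  ph <- as.matrix(df[, phenotype_cols, drop = FALSE])
  storage.mode(ph) <- "double"
  keep_p <- stats::complete.cases(ph)
  if (any(!keep_p))
    message(sprintf("dropped %d visit(s) with missing phenotype value(s)",
                    sum(!keep_p)))
  df <- df[keep_p, , drop = FALSE]
  ph <- ph[keep_p, , drop = FALSE]

  sid <- as.character(df[[subject_col]])
  subj_order <- unique(sid)
  visits <- vector("list", length(subj_order))
  fam <- if (!is.null(family_col)) character(length(subj_order)) else NULL
  keep_subj <- logical(length(subj_order))
  for (i in seq_along(subj_order)) {
    rows <- which(sid == subj_order[i])
    if (length(rows) == 0L) next
    ord <- rows[order(df[[time_col]][rows])]
    W <- as.matrix(df[ord, covariate_cols, drop = FALSE])
    storage.mode(W) <- "double"
    visits[[i]] <- list(times = df[[time_col]][ord],
                        Y = ph[ord, , drop = FALSE], W = W)
    if (!is.null(fam)) fam[i] <- as.character(df[[family_col]][ord[1]])
    keep_subj[i] <- TRUE
  }
  dropped <- length(setdiff(all_subjects, subj_order[keep_subj]))
  if (dropped > 0L)
    warning(sprintf("%d subject(s) excluded: no usable visits", dropped))
  longitudinal_dataset(subj_order[keep_subj], visits[keep_subj],
                       phenotype_names = phenotype_cols,
                       covariate_names = covariate_cols,
                       family_labels = if (!is.null(fam)) fam[keep_subj])
}

#' Read a subjects-by-genes expression table
#'
#' First column is the subject identifier; remaining columns are genes.
#'
#' @inheritParams read_long_phenotypes
#' @return an [expression_matrix].
#' @export
read_expression_matrix <- function(path, delim = "auto") {
  if (identical(delim, "auto")) delim <- detect_delim(path)
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  genes <- header[-1]
  if (anyDuplicated(genes))
    llct_error("duplicated gene column in expression file",
               "llct_format_error")
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  em <- expression_matrix(as.character(df[[1]]), genes, vals)
  cg <- attr(em, "constant_genes")
  if (length(cg))
    message(sprintf("%d constant (zero-variance) gene(s) flagged", length(cg)))
  em
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix]; values are written at full
#' precision so a read round-trip is bit-identical.
#'
#' @param em an [expression_matrix].
#' @param path output path.
#' @export
write_expression_matrix <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject", em$gene_ids), collapse = "\t"), con)
  for (i in seq_along(em$subject_ids)) {
    writeLines(paste(c(em$subject_ids[i],
                       sprintf("%.17g", em$values[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member gene ids.
#'
#' @param path GMT file.
#' @return a [gene_set_collection] (empty file gives an empty collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      llct_error(sprintf("GMT line %d has fewer than 3 fields", i),
                 "llct_format_error")
    list(name = f[1], description = f[2], genes = f[-(1:2)])
  })
  gene_set_collection(sets)
}

#' Write per-set test results as tab-separated text
#'
#' Columns, in fixed order: `set`, `genes_used`, `statistic`, `p_value`,
#' `q_value`, `prioritization_score`, `status`. Numbers are written at
#' full precision (17 significant digits) so parsed values round-trip.
#'
#' @param results a data frame as returned by [analyze_gene_sets].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  if (NROW(results) == 0L)
    llct_error("no results to write", "llct_parameter_error")
  cols <- c("set", "genes_used", "statistic", "p_value", "q_value",
            "prioritization_score", "status")
  out <- results[, cols]
  for (cc in c("statistic", "p_value", "q_value", "prioritization_score"))
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.17g", out[[cc]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Check that a dataset and an expression matrix are paired
#'
#' Pairing requires the exact same subject id sequence, in the same
#' order; anything else fails loudly rather than silently realigning.
#'
#' @param dataset a [longitudinal_dataset].
#' @param expression an [expression_matrix].
#' @export
check_paired <- function(dataset, expression) {
  if (!identical(dataset$subject_ids, expression$subject_ids))
    llct_error("subject id sequences of phenotype and expression data differ",
               "llct_pairing_error")
  invisible(TRUE)
}
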