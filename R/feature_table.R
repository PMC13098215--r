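#' Sample-by-feature table with per-feature class
#'
#' The central container of the package: a samples x features table holding
#' genus-level taxon relative abundances, targeted metabolite abundances and
#' categorical clinical covariates side by side. Taxon and metabolite columns
#' are numeric and non-negative; clinical columns are categorical (character
#' or factor). Each feature carries a class label used to route it through
#' preprocessing, screening and modeling.
#'
#' @param values data.frame (or matrix, coerced) with samples as rows and
#'   features as columns. Row names are sample IDs, column names feature IDs.
#' @param feature_class character vector, one of `"taxon"`, `"metabolite"`,
#'   `"clinical"` per column of `values` (recycled if length 1).
#' @param relative logical; if `TRUE` the taxon block is declared to be
#'   relative abundance and every taxon row must sum to 1 within `1e-6`.
#' @param check_nonnegative require numeric features to be non-negative
#'   (`TRUE` for raw abundances; [clr_transform()] disables it for its
#'   log-ratio output).
#' @return An object of class `feature_table`: a list with elements `values`
#'   (data.frame), `feature_class` (named character) and `relative` (logical).
#' @examples
#' ft <- feature_table(
#'   data.frame(taxA = c(0.6, 0.3), taxB = c(0.4, 0.7), row.names = c("s1", "s2")),
#'   feature_class = "taxon", relative = TRUE)
#' ft
#' @export
feature_table <- function(values, feature_class, relative = FALSE,
                          check_nonnegative = TRUE) {
  if (is.matrix(values)) values <- as.data.frame(values)
  if (!is.data.frame(values)) stop("`values` must be a data.frame or matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("feature table must have at least one sample and one feature")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("sample IDs (row names) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("feature IDs (column names) must be present and unique")
  feature_class <- rep_len(as.character(feature_class), ncol(values))
  bad <- setdiff(unique(feature_class), c("taxon", "metabolite", "clinical"))
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  names(feature_class) <- colnames(values)
  num <- feature_class != "clinical"
  numblock <- values[, num, drop = FALSE]
  if (length(numblock) && !all(vapply(numblock, is.numeric, logical(1))))
    stop("taxon and metabolite columns must be numeric")
  if (length(numblock)) {
    m <- as.matrix(numblock)
    if (anyNA(m) || any(!is.finite(m))) stop("non-finite values in numeric features")
    if (check_nonnegative && any(m < 0))
      stop("taxon and metabolite abundances must be non-negative")
  }
  if (relative) {
    taxa <- as.matrix(values[, feature_class == "taxon", drop = FALSE])
    if (ncol(taxa) && any(abs(rowSums(taxa) - 1) > 1e-6))
      stop("relative-abundance taxon rows must sum to 1 within 1e-6")
  }
  structure(list(values = values, feature_class = feature_class,
                 relative = relative),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$feature_class)
  cat(sprintf("feature_table: %d samples x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              if (isTRUE(x$relative)) ", taxa as relative abundance" else ""))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by sample and/or feature
#'
#' @param x a [feature_table()].
#' @param i sample index (row subscript).
#' @param j feature index (column subscript; names, positions or logical).
#' @param ... ignored.
#' @return a `feature_table` with the selected samples/features.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  vals <- x$values[i, j, drop = FALSE]
  feature_table(vals, x$feature_class[colnames(vals)], relative = FALSE,
                check_nonnegative = FALSE)
}

#' Extract a numeric matrix of selected feature classes
#'
#' @param x a [feature_table()].
#' @param classes feature classes to include (clinical columns are excluded
#'   unless requested, in which case they are one-hot encoded via
#'   [encode_clinical()]).
#' @return numeric matrix, samples x features.
#' @export
ft_matrix <- function(x, classes = c("taxon", "metabolite")) {
  stopifnot(inherits(x, "feature_table"))
  keep <- names(x$feature_class)[x$feature_class %in% setdiff(classes, "clinical")]
  m <- as.matrix(x$values[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  if ("clinical" %in% classes) {
    cl <- encode_clinical(x)
    if (ncol(cl)) m <- cbind(m, cl)
  }
  m
}

#' One-hot encode the clinical block
#'
#' Each categorical clinical covariate becomes one 0/1 indicator column per
#' level, named `<feature>=<level>`. Used wherever clinical features enter a
#' numeric computation (boosted trees, correlation networks).
#'
#' @param x a [feature_table()].
#' @return numeric 0/1 matrix (zero columns when there is no clinical block).
#' @export
encode_clinical <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  feats <- names(x$feature_class)[x$feature_class == "clinical"]
  out <- matrix(0, nrow(x$values), 0, dimnames = list(rownames(x$values), NULL))
  for (f in feats) {
    v <- as.character(x$values[[f]])
    levs <- sort(unique(v))
    ind <- vapply(levs, function(l) as.numeric(v == l), numeric(length(v)))
    ind <- matrix(ind, ncol = length(levs),
                  dimnames = list(rownames(x$values), paste0(f, "=", levs)))
    out <- cbind(out, ind)
  }
  out
}

#' Build the model matrix fed to the classifier
#'
#' Numeric taxon and metabolite columns as-is plus one-hot encoded clinical
#' covariates.
#'
#' @param x a [feature_table()].
#' @return numeric matrix, samples x features.
#' @export
build_model_matrix <- function(x) {
  ft_matrix(x, classes = c("taxon", "metabolite", "clinical"))
}

#' Read a feature table from a tab-delimited file
#'
#' Expects a header row of feature names and a first column of sample IDs,
#' the layout written by [write_cohort_fixture()].
#'
#' @param path file path.
#' @param feature_class class assigned to every column (single string).
#' @param relative passed to [feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, feature_class, relative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-ID column plus feature columns in ", path)
  rownames(df) <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  feature_table(df, feature_class, relative = relative)
}

#' Write one block of a feature table as TSV
#'
#' @param x a [feature_table()].
#' @param path output file.
#' @param classes which feature classes to write.
#' @param id_column name of the first (sample ID) column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, classes = c("taxon", "metabolite", "clinical"),
                                id_column = "sample_id") {
  stopifnot(inherits(x, "feature_table"))
  keep <- names(x$feature_class)[x$feature_class %in% classes]
  df <- cbind(stats::setNames(data.frame(rownames(x$values), stringsAsFactors = FALSE),
                              id_column),
              x$values[, keep, drop = FALSE])
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write ", path)
  invisible(path)
}

#' Sample metadata constructor
#'
#' One record per sample: outcome group (infectious NF, non-infectious NF, or
#' no fever) and collection time point, plus any extra covariate columns.
#'
#' @param sample_id character vector of unique sample IDs.
#' @param outcome outcome group per sample.
#' @param timepoint `"baseline"` or `"onset"` per sample (recycled).
#' @param ... further equal-length covariate vectors (batch, center, ...).
#' @return data.frame with class `sample_metadata`, row names = sample IDs.
#' @export
sample_metadata <- function(sample_id, outcome,
                            timepoint = "onset", ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample IDs must be unique")
  outcome <- as.character(outcome)
  bad <- setdiff(unique(outcome), nf_outcome_levels())
  if (length(bad)) stop("unknown outcome group(s): ", paste(bad, collapse = ", "))
  df <- data.frame(sample_id = sample_id,
                   outcome = factor(outcome, levels = nf_outcome_levels()),
                   timepoint = rep_len(as.character(timepoint), length(sample_id)),
                   ..., stringsAsFactors = FALSE)
  rownames(df) <- sample_id
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Outcome group labels used throughout the package
#' @return character vector of the three outcome levels.
#' @export
nf_outcome_levels <- function() c("infectious NF", "non-infectious NF", "no fever")

# Align metadata to a feature table; error if any sample lacks a record.
align_metadata <- function(table, metadata) {
  ids <- rownames(table$values)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}
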