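#' Prevalence and mean-abundance filter
#'
#' Removes low-information taxa before modeling: a taxon is retained only if
#' it is present (value > 0) in at least `min_prevalence` of samples AND its
#' abundance statistic is at least `min_abundance`. Both comparisons are
#' inclusive, i.e. a feature sitting exactly on a threshold is kept (the
#' removal rule is strictly "below"). Clinical covariates are never filtered;
#' by default the rule applies to taxa only.
#'
#' @param table a [feature_table()] with taxa as relative abundance.
#' @param min_prevalence minimum fraction of samples in which a feature must
#'   be non-zero (default 0.10).
#' @param min_abundance minimum relative abundance (default 0.001, i.e. 0.1%).
#' @param abundance_stat `"mean"` (default) or `"max"`: the per-feature
#'   statistic compared against `min_abundance`.
#' @param classes feature classes the filter applies to (default `"taxon"`).
#' @return the filtered `feature_table`; attribute `"removal_log"` is a
#'   data.frame with one row per dropped feature (feature, prevalence,
#'   abundance, reason).
#' @export
prevalence_abundance_filter <- function(table, min_prevalence = 0.10,
                                        min_abundance = 0.001,
                                        abundance_stat = c("mean", "max"),
                                        classes = "taxon") {
  stopifnot(inherits(table, "feature_table"))
  abundance_stat <- match.arg(abundance_stat)
  if (nrow(table$values) == 0L || ncol(table$values) == 0L)
    stop("empty feature table")
  fc <- table$feature_class
  target <- names(fc)[fc %in% classes & fc != "clinical"]
  if (!length(target)) return(structure(table, removal_log = empty_removal_log()))
  m <- as.matrix(table$values[, target, drop = FALSE])
  prev <- colMeans(m > 0)
  abun <- if (abundance_stat == "mean") colMeans(m) else apply(m, 2, max)
  drop <- prev < min_prevalence | abun < min_abundance
  log <- data.frame(feature = target[drop],
                    prevalence = unname(prev[drop]),
                    abundance = unname(abun[drop]),
                    reason = ifelse(prev[drop] < min_prevalence,
                                    "prevalence", "abundance")[seq_len(sum(drop))],
                    stringsAsFactors = FALSE)
  keep <- setdiff(colnames(table$values), target[drop])
  out <- table[, keep]
  out$relative <- FALSE  # filtering breaks the unit-sum constraint
  structure(out, removal_log = log)
}

empty_removal_log <- function() {
  data.frame(feature = character(), prevalence = numeric(),
             abundance = numeric(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Dataset-wide pseudocount for zero replacement
#'
#' Half the smallest non-zero value in the block, the replacement used before
#' any log-based step (CLR, log2 fold differences).
#'
#' @param m non-negative numeric matrix.
#' @return scalar pseudocount.
#' @export
pseudocount <- function(m) {
  pos <- m[m > 0]
  if (!length(pos)) stop("all values are zero: no non-zero minimum exists")
  min(pos) / 2
}

# CLR of a non-negative matrix: zero replacement by the dataset-wide
# pseudocount, then per-row log-ratio to the geometric mean.
clr_matrix <- function(m) {
  if (any(m < 0)) stop("CLR requires non-negative input")
  eps <- pseudocount(m)
  m[m == 0] <- eps
  lg <- log(m)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Centered log-ratio transform of the taxon block
#'
#' Zeros in the taxon block are replaced with half the smallest non-zero
#' value of the entire block (a single dataset-wide pseudocount), then each
#' sample row x is mapped to `log(x / geometric mean(x))`. Transformed rows
#' sum to zero, and the transform is invariant to per-sample rescaling of the
#' raw row. Metabolite and clinical columns pass through unchanged.
#'
#' @param table a [feature_table()] with a non-negative taxon block.
#' @param classes feature classes to transform (default `"taxon"`).
#' @return a `feature_table` with the selected block CLR-transformed (and no
#'   longer flagged as relative abundance).
#' @export
clr_transform <- function(table, classes = "taxon") {
  stopifnot(inherits(table, "feature_table"))
  target <- names(table$feature_class)[table$feature_class %in% classes]
  if (!length(target)) return(table)
  m <- as.matrix(table$values[, target, drop = FALSE])
  tr <- clr_matrix(m)
  vals <- table$values
  vals[, target] <- tr
  out <- feature_table(vals, table$feature_class, relative = FALSE,
                       check_nonnegative = FALSE)
  attr(out, "clr") <- classes
  out
}

#' Greedy collinearity pruning
#'
#' Scans features in column order; whenever a pair of numeric features has a
#' Pearson correlation above `r_cut`, the later column is dropped. Signed
#' correlation is used by default (only strong positive collinearity prunes),
#' matching a removal rule stated as r > 0.9; set `absolute = TRUE` to prune
#' strong negative collinearity too. A feature with zero variance has an
#' undefined correlation; it is treated as r = 0 (never pruned for
#' collinearity) and logged.
#'
#' @param table a [feature_table()] with at least 2 samples.
#' @param r_cut correlation threshold (strictly above prunes; default 0.9).
#' @param absolute compare `|r|` instead of signed r.
#' @param classes feature classes subject to pruning (default taxa and
#'   metabolites).
#' @return the pruned `feature_table`; attribute `"removal_log"` pairs each
#'   dropped feature with its retained partner and the offending r; attribute
#'   `"constant_features"` lists zero-variance features encountered.
#' @export
prune_collinear <- function(table, r_cut = 0.9, absolute = FALSE,
                            classes = c("taxon", "metabolite")) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2L) stop("need at least 2 samples to correlate")
  target <- names(table$feature_class)[table$feature_class %in% classes]
  if (length(target) < 2L)
    return(structure(table, removal_log = data.frame(
      dropped = character(), kept = character(), r = numeric()),
      constant_features = character()))
  m <- as.matrix(table$values[, target, drop = FALSE])
  const <- target[apply(m, 2, stats::sd) == 0]
  suppressWarnings(cc <- stats::cor(m))
  cc[!is.finite(cc)] <- 0  # zero-variance columns: r undefined -> 0
  cmp <- if (absolute) abs(cc) else cc
  dropped <- character(); kept_partner <- character(); rs <- numeric()
  alive <- rep(TRUE, length(target))
  tol <- 1e-12  # roundoff guard so r == r_cut up to float error is kept
  for (j in seq_along(target)[-1]) {
    prior <- which(alive[seq_len(j - 1L)])
    if (!length(prior)) next
    hits <- prior[cmp[prior, j] > r_cut + tol]
    if (length(hits)) {
      alive[j] <- FALSE
      dropped <- c(dropped, target[j])
      kept_partner <- c(kept_partner, target[hits[1L]])
      rs <- c(rs, cc[hits[1L], j])
    }
  }
  keep <- setdiff(colnames(table$values), target[!alive])
  out <- table[, keep]
  out$relative <- table$relative && all(alive)
  structure(out,
            removal_log = data.frame(dropped = dropped, kept = kept_partner,
                                     r = rs, stringsAsFactors = FALSE),
            constant_features = const)
}
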