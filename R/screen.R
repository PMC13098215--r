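#' Pearson chi-squared test of independence
#'
#' Pearson chi-squared without continuity correction, df = (r-1)(c-1).
#' Rows/columns with a zero margin are dropped with a warning before
#' testing.
#'
#' @param contingency non-negative integer matrix of counts (>= 2 rows and
#'   columns with positive margins).
#' @return list: `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' # prolonged cephalosporin exposure across three outcome groups
#' chi_square(rbind(yes = c(30, 10, 2), no = c(15, 5, 12)))
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns before chi-squared test")
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least a 2x2 table with positive margins")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table. The sample odds ratio `(ad)/(bc)` is reported
#' by default; `or = "mle"` returns the conditional maximum-likelihood
#' estimate instead.
#'
#' @param contingency 2x2 non-negative integer matrix.
#' @param or `"sample"` (default) or `"mle"`.
#' @return list: `p_value`, `odds_ratio`.
#' @export
fisher_exact <- function(contingency, or = c("sample", "mle")) {
  or <- match.arg(or)
  m <- as.matrix(contingency)
  if (!all(dim(m) == c(2L, 2L)))
    stop("fisher_exact handles 2x2 tables only; use chi_square for larger tables")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  res <- stats::fisher.test(m)
  oratio <- if (or == "mle") unname(res$estimate)
            else (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p_value = res$p.value, odds_ratio = oratio)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value from the Wilcoxon rank-sum distribution when both
#' samples have at most 8 values and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction. Two
#' identical constant samples give p = 1 with a warning.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list: `U` (statistic for sample `a`), `p_value`,
#'   `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups need at least one value")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (ties && length(unique(c(a, b))) == 1L) {
    warning("all values identical: p = 1")
    return(list(U = U, p_value = 1, exact = FALSE))
  }
  if (!ties && na <= 8L && nb <= 8L) {
    p <- if (U <= na * nb / 2) 2 * stats::pwilcox(U, na, nb)
         else 2 * (1 - stats::pwilcox(U - 1, na, nb))
    return(list(U = U, p_value = min(1, p), exact = TRUE))
  }
  N <- na + nb
  tie_tab <- table(c(a, b))
  tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_corr)
  mu <- na * nb / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Univariate feature screen for the binary NF outcome
#'
#' Routes each feature to a test by class -- categorical clinical covariates
#' to chi-squared (or Fisher's exact when the table is 2x2 and any expected
#' cell count is below 5), numeric taxa/metabolites to Mann-Whitney -- and
#' retains features with p strictly below the threshold. The comparison is
#' the two neutropenic-fever classes by default, matching the binary
#' classification outcome.
#'
#' @param table a [feature_table()] (raw, untransformed).
#' @param metadata a [sample_metadata()] covering every sample.
#' @param pair the two outcome groups compared.
#' @param p_threshold retention threshold (strict `<`; default 0.3).
#' @return data.frame of class `screen_result`: feature, class, test,
#'   statistic, p, retained. Features with a single distinct value are
#'   excluded and listed in attribute `"excluded"`.
#' @export
screen_features <- function(table, metadata,
                            pair = c("infectious NF", "non-infectious NF"),
                            p_threshold = 0.3) {
  stopifnot(inherits(table, "feature_table"), length(pair) == 2L)
  metadata <- align_metadata(table, metadata)
  keep <- metadata$outcome %in% pair
  if (length(unique(metadata$outcome[keep])) < 2L)
    stop("both outcome classes must be present")
  grp <- droplevels(factor(metadata$outcome[keep], levels = pair))
  vals <- table$values[keep, , drop = FALSE]
  fc <- table$feature_class
  rows <- list(); excluded <- character(0)
  for (f in colnames(vals)) {
    v <- vals[[f]]
    if (length(unique(v)) < 2L) { excluded <- c(excluded, f); next }
    if (fc[[f]] == "clinical") {
      tab <- table(factor(as.character(v)), grp)
      use_fisher <- all(dim(tab) == 2L) &&
        any(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected < 5)
      if (use_fisher) {
        res <- fisher_exact(tab)
        rows[[f]] <- data.frame(feature = f, class = "clinical",
                                test = "fisher_exact",
                                statistic = res$odds_ratio, p = res$p_value)
      } else {
        res <- chi_square(tab)
        rows[[f]] <- data.frame(feature = f, class = "clinical",
                                test = "chi_square",
                                statistic = res$statistic, p = res$p_value)
      }
    } else {
      res <- suppressWarnings(mann_whitney(v[grp == pair[1]], v[grp == pair[2]]))
      rows[[f]] <- data.frame(feature = f, class = fc[[f]],
                              test = "mann_whitney",
                              statistic = res$U, p = res$p_value)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) stop("no testable features")
  out$retained <- out$p < p_threshold
  structure(out, excluded = excluded, p_threshold = p_threshold,
            pair = pair, class = c("screen_result", "data.frame"))
}
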