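#' Shannon diversity per sample
#'
#' `H = -sum p_i log p_i` over the positive entries of each row, after
#' normalizing the row to proportions. Natural log by default.
#'
#' @param x a [feature_table()] or a non-negative numeric matrix
#'   (samples x taxa).
#' @param base logarithm base (default `exp(1)`).
#' @return named numeric vector, one diversity value per sample.
#' @examples
#' shannon_index(matrix(rep(1, 4), 1))  # log(4)
#' @export
shannon_index <- function(x, base = exp(1)) {
  m <- if (inherits(x, "feature_table")) ft_matrix(x, "taxon") else as.matrix(x)
  if (any(m < 0)) stop("abundances must be non-negative")
  if (any(rowSums(m) == 0)) stop("all-zero sample row(s)")
  vegan::diversity(m, index = "shannon", base = base)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Omnibus H uses the standard tie correction (via [stats::kruskal.test]).
#' Dunn's z for a pair (i, j) compares mean ranks with the pooled,
#' tie-corrected variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`.
#' Pairwise p-values are two-sided normal and reported both unadjusted and
#' BH-adjusted.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups, each >= 2 values).
#' @return list: `H`, `df`, `p_value`, and `pairwise` (data.frame with
#'   group pair, z, p, p_adj).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    v <- (N * (N + 1) / 12 - tie_term) * (1 / n_g[pr[1]] + 1 / n_g[pr[2]])
    (mean_rank[pr[1]] - mean_rank[pr[2]]) / sqrt(v)
  })
  p <- 2 * stats::pnorm(-abs(z))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = as.numeric(z), p = as.numeric(p),
                             p_adj = stats::p.adjust(p, "BH"),
                             stringsAsFactors = FALSE))
}

#' Between-sample community distances
#'
#' Bray-Curtis dissimilarity, or phylogeny-aware unweighted / weighted
#' (normalized) UniFrac. UniFrac metrics need a rooted tree whose tip labels
#' cover every taxon in the table.
#'
#' @param x a [feature_table()] or numeric abundance matrix (samples x taxa).
#' @param metric one of `"bray_curtis"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param tree a rooted `phylo` tree (required for the UniFrac metrics).
#' @return a `dist` object over the samples.
#' @export
community_distances <- function(x, metric = c("bray_curtis",
                                              "unweighted_unifrac",
                                              "weighted_unifrac"),
                                tree = NULL) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "feature_table")) ft_matrix(x, "taxon") else as.matrix(x)
  if (metric == "bray_curtis") return(vegan::vegdist(m, method = "bray"))
  if (is.null(tree)) stop("UniFrac metrics require a phylogenetic tree")
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop("UniFrac metrics require a rooted tree")
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  otu <- phyloseq::otu_table(t(m), taxa_are_rows = TRUE)
  ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(tree))
  phyloseq::UniFrac(ps, weighted = metric == "weighted_unifrac",
                    normalized = TRUE)
}

#' Principal coordinate ordination of a distance matrix
#'
#' Classical multidimensional scaling; axes with negative eigenvalues are
#' truncated at zero and reported.
#'
#' @param d a `dist` object.
#' @param k number of axes.
#' @return list: `points` (samples x k), `eig` (all eigenvalues),
#'   `negative_eig` (count truncated), `explained` (variance fraction per
#'   returned axis, from the positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = 2) {
  cs <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- cs$eig
  neg <- sum(eig < 0)
  pos <- pmax(eig, 0)
  list(points = cs$points, eig = eig, negative_eig = neg,
       explained = pos[seq_len(k)] / sum(pos))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in Anderson's
#' formulation, computed with `vegan::adonis2`. The p-value is
#' `(1 + #{permuted F >= observed F}) / (1 + n_perm)`. With `exact = TRUE`
#' every distinct permutation of the labels is enumerated, giving the exact
#' permutation p-value on small designs. `strata` restricts permutations to
#' within-stratum exchanges, the adjustment used for nuisance covariates such
#' as batch or sequencing center.
#'
#' @param d a `dist` object or square symmetric matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of permutations (default 999; < 99 warns).
#' @param seed integer seed for the permutation stream.
#' @param strata optional factor of permutation blocks.
#' @param exact enumerate all permutations instead of sampling.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`, `df`,
#'   `n_perm`, `R2`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL, strata = NULL,
                      exact = FALSE) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  if (!exact && n_perm < 99) warning("fewer than 99 permutations: p-value is unstable")
  n <- attr(d, "Size")
  if (length(groups) != n) stop("label length does not match distance matrix")
  if (!is.null(seed)) set.seed(seed)
  perm <- if (exact) {
    ctrl <- permute::how(blocks = strata)
    suppressMessages(permute::allPerms(n, control = ctrl))
  } else if (!is.null(strata)) {
    permute::how(nperm = n_perm, blocks = strata)
  } else {
    n_perm
  }
  df <- data.frame(group = groups)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = perm)
  np <- if (is.matrix(perm)) nrow(perm) else n_perm
  structure(list(pseudo_F = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
                 df = c(between = fit$Df[1L], within = fit$Df[2L]),
                 R2 = fit$R2[1L], n_perm = np, exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d/%d), p = %.4g (%s permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value,
              if (isTRUE(x$exact)) "all" else format(x$n_perm)))
  invisible(x)
}

#' Pairwise post hoc PERMANOVA with BH correction
#'
#' Runs [permanova()] on every group pair and adjusts the p-values with
#' Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @return data.frame: group pair, pseudo-F, raw and BH-adjusted p.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL,
                               strata = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  groups <- droplevels(as.factor(groups))
  dm <- as.matrix(d)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    keep <- groups %in% pr
    sub <- stats::as.dist(dm[keep, keep])
    fit <- permanova(sub, groups[keep], n_perm = n_perm, seed = seed,
                     strata = if (!is.null(strata)) strata[keep])
    c(F = fit$pseudo_F, p = fit$p_value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             pseudo_F = res["F", ], p = res["p", ],
             p_adj = stats::p.adjust(res["p", ], "BH"),
             stringsAsFactors = FALSE)
}

#' Two-group differential abundance for volcano display
#'
#' For each taxon/metabolite feature: log2 fold difference of group means
#' with a dataset-wide pseudocount (half the smallest non-zero value of the
#' analyzed block), a Mann-Whitney p-value, its BH adjustment, and flags at
#' the two display thresholds P < 0.05 and P < 0.3 (the univariate retention
#' rule).
#'
#' @param table a [feature_table()] (raw abundances, not CLR).
#' @param groups outcome label per sample.
#' @param pair length-2 character: the two groups to compare (fold =
#'   first over second).
#' @return data.frame: feature, class, log2_fold, p, p_adj, sig_05, sig_30.
#' @export
volcano_differential <- function(table, groups,
                                 pair = c("infectious NF", "non-infectious NF")) {
  stopifnot(inherits(table, "feature_table"), length(pair) == 2L)
  groups <- as.character(groups)
  absent <- setdiff(pair, unique(groups))
  if (length(absent)) stop("group(s) absent: ", paste(absent, collapse = ", "))
  m <- ft_matrix(table, c("taxon", "metabolite"))
  eps <- pseudocount(m)
  in1 <- groups == pair[1]; in2 <- groups == pair[2]
  lfc <- log2((colMeans(m[in1, , drop = FALSE]) + eps) /
              (colMeans(m[in2, , drop = FALSE]) + eps))
  p <- apply(m, 2, function(v) mann_whitney(v[in1], v[in2])$p_value)
  fc <- table$feature_class[colnames(m)]
  data.frame(feature = colnames(m), class = unname(fc),
             log2_fold = unname(lfc), p = unname(p),
             p_adj = stats::p.adjust(p, "BH"),
             sig_05 = unname(p < 0.05), sig_30 = unname(p < 0.3),
             stringsAsFactors = FALSE)
}
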