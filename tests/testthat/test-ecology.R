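test_that("Shannon index matches closed forms and ignores zeros", {
  expect_equal(unname(shannon_index(matrix(rep(1, 4), 1))), log(4))
  expect_equal(unname(shannon_index(matrix(c(1, 0, 0), 1))), 0)
  expect_equal(unname(shannon_index(matrix(c(0.5, 0.5, 0), 1))), log(2))
  expect_equal(unname(shannon_index(matrix(rep(1, 4), 1), base = 2)), 2)
  expect_error(shannon_index(matrix(0, 1, 3)), "zero")
})

test_that("Kruskal-Wallis H matches the hand-ranked value and Dunn p-values are BH-monotone", {
  kd <- kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                     rep(c("a", "b", "c"), each = 3))
  expect_equal(kd$H, 7.2)
  expect_equal(kd$p_value,
               stats::kruskal.test(1:9, rep(c("a", "b", "c"), each = 3))$p.value)
  expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p))
  expect_equal(order(kd$pairwise$p_adj), order(kd$pairwise$p))
  expect_error(kruskal_dunn(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis omnibus p is uniform under the null", {
  ps <- vapply(1:500, function(r) {
    set.seed(r)
    kruskal_dunn(rnorm(30), rep(c("a", "b", "c"), 10))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("distances satisfy metric invariants and tiny closed forms", {
  # Bray-Curtis of disjoint compositions is 1
  m <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  expect_equal(as.numeric(community_distances(m, "bray_curtis")), 1)
  # identical samples at distance 0 for all metrics
  tree <- ape::read.tree(text = "((t1:1,t2:1):0,(t3:1,t4:1):0);")
  eq <- rbind(a = c(0.25, 0.25, 0.25, 0.25), b = c(0.25, 0.25, 0.25, 0.25))
  colnames(eq) <- paste0("t", 1:4)
  for (met in c("bray_curtis", "unweighted_unifrac", "weighted_unifrac")) {
    d <- community_distances(eq, met, tree = tree)
    expect_equal(max(as.matrix(d)), 0)
  }
  # disjoint taxa on a star tree share no branches: unweighted UniFrac = 1
  disj <- rbind(a = c(0.5, 0.5, 0, 0), b = c(0, 0, 0.5, 0.5))
  colnames(disj) <- paste0("t", 1:4)
  expect_equal(as.numeric(community_distances(disj, "unweighted_unifrac",
                                              tree = tree)), 1)
  # taxa absent from the tree are reported by name
  bad <- disj; colnames(bad)[4] <- "t9"
  expect_error(community_distances(bad, "weighted_unifrac", tree = tree), "t9")
  # metric invariants on simulated data
  co <- mini_cohort()
  dm <- as.matrix(community_distances(co$table, "bray_curtis"))
  expect_equal(dm, t(dm), tolerance = 1e-12)
  expect_equal(max(abs(diag(dm))), 0)
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("weighted UniFrac on a star tree equals the normalized L1 closed form", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):0,(t3:1,t4:1):0);")
  set.seed(4)
  a <- abs(rnorm(4)); a <- a / sum(a)
  b <- abs(rnorm(4)); b <- b / sum(b)
  m <- rbind(a = a, b = b); colnames(m) <- paste0("t", 1:4)
  got <- as.numeric(community_distances(m, "weighted_unifrac", tree = tree))
  expect_equal(got, sum(abs(a - b)) / sum(a + b), tolerance = 1e-10)
})

test_that("unweighted UniFrac agrees with an independent implementation", {
  set.seed(9)
  tree <- ape::rtree(8)
  m <- matrix(rbinom(3 * 8, 1, 0.6) * runif(24), 3, 8,
              dimnames = list(paste0("s", 1:3), tree$tip.label))
  m[1, 1] <- 0.5  # guarantee non-empty samples
  m <- m / rowSums(m)
  got <- as.matrix(community_distances(m, "unweighted_unifrac", tree = tree))
  ref <- as.matrix(picante::unifrac(m, tree))
  expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("PERMANOVA pseudo-F and exact p match the brute-force enumeration oracle", {
  set.seed(12)
  m <- matrix(abs(rnorm(6 * 5)), 6)
  m <- m / rowSums(m)
  rownames(m) <- paste0("s", 1:6)
  d <- community_distances(m, "bray_curtis")
  g <- rep(c("x", "y"), each = 3)
  res <- permanova(d, g, exact = TRUE)
  expect_equal(res$pseudo_F, bruteforce_pseudo_f(d, g), tolerance = 1e-10)
  expect_equal(res$p_value, bruteforce_permanova_p(d, g), tolerance = 1e-10)
  expect_error(permanova(d, rep("x", 6)), "2 groups")
  expect_warning(permanova(d, g, n_perm = 50, seed = 1), "99")
})

test_that("pairwise PERMANOVA BH-adjusts monotonically", {
  co <- mini_cohort()
  d <- community_distances(co$table, "bray_curtis")
  pw <- pairwise_permanova(d, co$metadata$outcome, n_perm = 199, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p))
  # BH is monotone: adjusted p is non-decreasing in raw p
  expect_true(all(diff(pw$p_adj[order(pw$p)]) >= -1e-12))
})

test_that("PCoA truncates negative eigenvalues and reports them", {
  co <- mini_cohort()
  d <- community_distances(co$table, "bray_curtis")
  ord <- pcoa_ordination(d, k = 2)
  expect_equal(dim(ord$points), c(nrow(co$table$values), 2))
  expect_true(all(ord$explained >= 0))
})

test_that("volcano stage recovers signs, nulls and planted folds", {
  co <- mini_cohort()
  g <- co$metadata$outcome
  vd <- volcano_differential(co$table, g)
  expect_setequal(vd$feature,
                  names(co$table$feature_class)[co$table$feature_class != "clinical"])
  expect_true(all(vd$p_adj >= vd$p))
  expect_error(volcano_differential(co$table, g, pair = c("infectious NF", "zzz")),
               "absent")
  # identical group distributions: fold ~ 0 and p well away from significance
  nullft <- feature_table(data.frame(f = c(1:10, 1:10),
                                     row.names = sprintf("s%02d", 1:20)),
                          "metabolite")
  nv <- volcano_differential(nullft, rep(c("infectious NF", "non-infectious NF"),
                                         each = 10))
  expect_equal(nv$log2_fold, 0, tolerance = 1e-12)
  expect_gt(nv$p, 0.9)
  # a feature present only in group 1 has a positive fold bounded by the
  # pseudocount rule
  onesided <- feature_table(
    data.frame(f = c(rep(0.4, 10), rep(0, 10)),
               g = rep(0.8, 20), row.names = sprintf("s%02d", 1:20)),
    "metabolite")
  ov <- suppressWarnings(
    volcano_differential(onesided, rep(c("infectious NF", "non-infectious NF"),
                                       each = 10)))
  eps <- 0.2  # half the smallest non-zero value (0.4 / 2)
  expect_gt(ov$log2_fold[ov$feature == "f"], 0)
  expect_lte(ov$log2_fold[ov$feature == "f"], log2((0.4 + eps) / eps))
  # planted 4x shift recovered within +-0.5 log2 units (median over reps)
  errs <- vapply(1:100, function(r) {
    cc <- generate_cohort(cohort_config(group_sizes = c(60, 60, 2), n_taxa = 20,
                                        n_metabolites = 0, n_clinical = 0,
                                        effect_table = list(taxon_010 = log(4)),
                                        seed = 300 + r))
    v <- volcano_differential(cc$table, cc$metadata$outcome)
    v$log2_fold[v$feature == "taxon_010"] - 2
  }, numeric(1))
  expect_lt(abs(stats::median(errs)), 0.5)
})
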