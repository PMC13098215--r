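# Small shared fixtures, built in code at load time.

# deterministic mini cohort used across modules
mini_cohort <- function(seed = 3) {
  generate_cohort(cohort_config(group_sizes = c(10, 10, 5), n_taxa = 20,
                                n_metabolites = 6, n_clinical = 2,
                                seed = seed))
}

# planted-effect configuration matching the recovery study conditions:
# 5 biomarkers (3 mid-rank taxa + 2 metabolites) with log-scale shift 1.5
# in the infectious-NF group, 30 samples per NF class
planted_effects <- function(shift = 1.5) {
  list(taxon_005 = shift, taxon_008 = shift, taxon_012 = shift,
       butyrate = shift, lactate = shift)
}

recovery_config <- function(seed) {
  cohort_config(group_sizes = c(30, 30, 10), n_taxa = 40,
                effect_table = planted_effects(), seed = seed)
}

# binary design matrix + labels for the two NF groups of a cohort
nf_xy <- function(cohort, table = cohort$table) {
  keep <- cohort$metadata$outcome != "no fever"
  list(x = build_model_matrix(table)[keep, , drop = FALSE],
       y = as.numeric(cohort$metadata$outcome[keep] == "infectious NF"))
}

# independent brute-force PERMANOVA pseudo-F from the sum-of-squares
# decomposition of a distance matrix (oracle; no vegan)
bruteforce_pseudo_f <- function(dm, groups) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  ss_within <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# exact permutation p-value by enumerating every distinct assignment of
# group labels (oracle for small designs)
bruteforce_permanova_p <- function(dm, groups) {
  n <- length(groups)
  f_obs <- bruteforce_pseudo_f(dm, groups)
  idx1 <- utils::combn(n, sum(groups == unique(groups)[1]))
  fs <- apply(idx1, 2, function(i) {
    g <- rep(unique(groups)[2], n)
    g[i] <- unique(groups)[1]
    bruteforce_pseudo_f(dm, g)
  })
  mean(fs >= f_obs - 1e-12)
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
bruteforce_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  us <- apply(sets, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force two-level extraction: keep edges with an endpoint that is a
# biomarker or a direct neighbor of one (independent set construction)
bruteforce_two_level_edges <- function(edges, biomarkers) {
  nb <- unique(c(edges$to[edges$from %in% biomarkers],
                 edges$from[edges$to %in% biomarkers]))
  zone <- union(biomarkers, setdiff(nb, biomarkers))
  keep <- edges$from %in% zone | edges$to %in% zone
  ek <- edges[keep, c("from", "to")]
  sort(paste(pmin(ek$from, ek$to), pmax(ek$from, ek$to)))
}

# exhaustive Newman modularity over all partitions of a small graph
bruteforce_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  parts <- list(list(1L))
  for (v in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      c(lapply(seq_along(p), function(k) { p[[k]] <- c(p[[k]], v); p }),
        list(c(p, list(v))))
    }), recursive = FALSE)
  }
  best <- -Inf
  for (p in parts) {
    memb <- integer(n)
    for (k in seq_along(p)) memb[p[[k]]] <- k
    best <- max(best, igraph::modularity(g, memb))
  }
  best
}
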