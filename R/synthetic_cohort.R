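#' Configuration for a synthetic neutropenic-fever cohort
#'
#' Describes a three-group cohort (infectious NF / non-infectious NF / no
#' fever) with sparse, overdispersed genus-level taxon counts, log-normal
#' targeted metabolites, and categorical clinical covariates. Group effects
#' are planted through `effect_table`, a named list mapping a feature to its
#' per-group multiplicative shift on the log scale (length-3 numeric, one
#' entry per outcome group in the order of [nf_outcome_levels()]; a length-1
#' entry is shorthand for a shift in the infectious-NF group only). For
#' clinical covariates the shift acts as a per-group log-odds increment on
#' the covariate's last level.
#'
#' @param group_sizes integer vector of 3 group sizes, each >= 2. Default
#'   `c(45, 15, 14)`, the onset cohort composition.
#' @param n_taxa number of genus-level taxa.
#' @param n_metabolites number of metabolites; the first 10 take the names of
#'   the targeted panel (2-HG, acetic acid, butyrate, glyceric acid,
#'   ketoleucine, lactate, malate, pentanoic acid, propionic acid, succinate).
#' @param n_clinical number of categorical clinical covariates (2-4 levels).
#' @param sequencing_depth reads per sample for the multinomial draw.
#' @param dispersion Dirichlet concentration scalar (> 0); smaller values
#'   give more overdispersed compositions.
#' @param effect_table named list of planted per-group log-scale shifts.
#' @param sparsity expected fraction of structurally absent taxa per sample,
#'   realized by zeroing Dirichlet-mean entries before renormalization.
#' @param met_sigma log-scale SD of metabolite noise.
#' @param timepoint label recorded in the metadata (`"onset"` or
#'   `"baseline"`); cohorts are single-time-point.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort. Independent substreams per block, so e.g. changing
#'   `n_metabolites` does not perturb the taxon draws.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(45, 15, 14), n_taxa = 40,
                          n_metabolites = 10, n_clinical = 4,
                          sequencing_depth = 10000, dispersion = 50,
                          effect_table = list(), sparsity = 0.25,
                          met_sigma = 1, timepoint = "onset", seed = 1) {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 3L || any(group_sizes < 2L))
    stop("group_sizes must be 3 counts, each >= 2")
  if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (n_taxa < 2) stop("need at least 2 taxa")
  if (n_metabolites < 0 || n_clinical < 0) stop("negative feature counts")
  effect_table <- lapply(effect_table, function(s) {
    s <- as.numeric(s)
    if (length(s) == 1L) s <- c(s, 0, 0)
    if (length(s) != 3L || any(!is.finite(s)))
      stop("effect_table entries must be finite, length 1 or 3")
    s
  })
  structure(list(group_sizes = group_sizes, n_taxa = n_taxa,
                 n_metabolites = n_metabolites, n_clinical = n_clinical,
                 sequencing_depth = sequencing_depth, dispersion = dispersion,
                 effect_table = effect_table, sparsity = sparsity,
                 met_sigma = met_sigma, timepoint = timepoint,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

metabolite_panel <- function() {
  c("2-HG", "acetic acid", "butyrate", "glyceric acid", "ketoleucine",
    "lactate", "malate", "pentanoic acid", "propionic acid", "succinate")
}

cohort_feature_names <- function(config) {
  taxa <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  mets <- character(0)
  if (config$n_metabolites > 0) {
    panel <- metabolite_panel()
    mets <- if (config$n_metabolites <= length(panel)) {
      panel[seq_len(config$n_metabolites)]
    } else {
      c(panel, sprintf("metab_%02d", seq.int(length(panel) + 1L,
                                             config$n_metabolites)))
    }
  }
  clin <- if (config$n_clinical > 0) sprintf("clin_%d", seq_len(config$n_clinical))
          else character(0)
  list(taxa = taxa, metabolites = mets, clinical = clin)
}

# per-feature planted shift matrix: features x 3 groups
shift_matrix <- function(config, features) {
  s <- matrix(0, length(features), 3, dimnames = list(features, NULL))
  for (f in names(config$effect_table)) {
    if (f %in% features) s[f, ] <- config$effect_table[[f]]
  }
  s
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Taxa: per-group Dirichlet mean proportions (a log-normal base profile
#' scaled by `exp(shift)` and renormalized), per-sample structural zeroing at
#' rate `sparsity`, a Dirichlet draw with concentration
#' `dispersion * mean`, and a multinomial read count at the configured depth,
#' returned as relative abundance (rows sum to 1 exactly). Metabolites:
#' log-normal with per-group log-mean shifts. Clinical: categorical draws
#' whose group-conditional probabilities tilt by the configured log-odds.
#'
#' @param config a [cohort_config()].
#' @return list of class `nf_cohort`: `table` (a [feature_table()], taxa as
#'   relative abundance), `metadata` (a [sample_metadata()]), and `truth`
#'   (list: `true_biomarkers` — features with a non-zero planted shift,
#'   `effect_table`, `groups` — named group assignment per sample).
#' @examples
#' co <- generate_cohort(cohort_config(group_sizes = c(5, 5, 5), n_taxa = 12,
#'                                     seed = 42))
#' co$table
#' co$truth$true_biomarkers
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  nm <- cohort_feature_names(config)
  n <- sum(config$group_sizes)
  grp <- rep(nf_outcome_levels(), times = config$group_sizes)
  ids <- sprintf("S%03d", seq_len(n))
  gidx <- rep(1:3, times = config$group_sizes)

  # taxa substream; base profile is a fixed Zipf rank-abundance curve
  # (taxon_001 most abundant) so a planted shift on a given taxon has a
  # seed-independent realized strength
  set.seed(config$seed + 1L)
  base <- seq_len(config$n_taxa)^-1
  base <- base / sum(base)
  tshift <- shift_matrix(config, nm$taxa)
  gmeans <- lapply(1:3, function(g) {
    m <- base * exp(tshift[, g])
    m / sum(m)
  })
  rel <- matrix(0, n, config$n_taxa, dimnames = list(ids, nm$taxa))
  for (i in seq_len(n)) {
    m <- gmeans[[gidx[i]]]
    if (config$sparsity > 0) {
      mask <- stats::rbinom(config$n_taxa, 1L, 1 - config$sparsity)
      if (all(mask == 0L)) mask[which.max(m)] <- 1L
      m <- m * mask
      m <- m / sum(m)
    }
    p <- rdirichlet_one(config$dispersion * m)
    counts <- stats::rmultinom(1L, size = config$sequencing_depth, prob = p)[, 1L]
    rel[i, ] <- counts / config$sequencing_depth
  }

  # metabolite substream
  met <- matrix(numeric(0), n, 0, dimnames = list(ids, NULL))
  if (config$n_metabolites > 0) {
    set.seed(config$seed + 2L)
    mu <- stats::rnorm(config$n_metabolites, log(10), 1)
    mshift <- shift_matrix(config, nm$metabolites)
    met <- matrix(0, n, config$n_metabolites, dimnames = list(ids, nm$metabolites))
    for (i in seq_len(n)) {
      z <- stats::rnorm(config$n_metabolites)
      met[i, ] <- exp(mu + mshift[, gidx[i]] + config$met_sigma * z)
    }
  }

  # clinical substream
  clin <- NULL
  if (config$n_clinical > 0) {
    set.seed(config$seed + 3L)
    cshift <- shift_matrix(config, nm$clinical)
    clin <- as.data.frame(matrix(NA_character_, n, config$n_clinical,
                                 dimnames = list(ids, nm$clinical)),
                          stringsAsFactors = FALSE)
    for (j in seq_len(config$n_clinical)) {
      k <- sample(2:4, 1L)
      base_logit <- log(rdirichlet_one(rep(2, k)))
      for (i in seq_len(n)) {
        lo <- base_logit
        lo[k] <- lo[k] + cshift[j, gidx[i]]
        pr <- exp(lo) / sum(exp(lo))
        clin[i, j] <- paste0("L", sample.int(k, 1L, prob = pr))
      }
    }
  }

  vals <- as.data.frame(rel)
  fc <- rep("taxon", config$n_taxa)
  if (config$n_metabolites > 0) {
    vals <- cbind(vals, as.data.frame(met))
    fc <- c(fc, rep("metabolite", config$n_metabolites))
  }
  if (!is.null(clin)) {
    vals <- cbind(vals, clin)
    fc <- c(fc, rep("clinical", config$n_clinical))
  }
  colnames(vals) <- c(nm$taxa, nm$metabolites, nm$clinical)
  table <- feature_table(vals, fc, relative = TRUE)
  metadata <- sample_metadata(ids, grp, timepoint = config$timepoint)
  planted <- names(config$effect_table)[vapply(config$effect_table,
                                               function(s) any(s != 0), logical(1))]
  truth <- list(true_biomarkers = planted,
                effect_table = config$effect_table,
                groups = stats::setNames(grp, ids))
  structure(list(table = table, metadata = metadata, truth = truth,
                 config = config),
            class = "nf_cohort")
}

#' @export
print.nf_cohort <- function(x, ...) {
  cat(sprintf("nf_cohort: %d samples (%s), %d features, %d planted biomarkers\n",
              nrow(x$table$values),
              paste(x$config$group_sizes, collapse = "/"),
              ncol(x$table$values), length(x$truth$true_biomarkers)))
  invisible(x)
}

#' Write a cohort to plain-text fixture files
#'
#' Emits `taxa.tsv`, `metabolites.tsv`, `metadata.tsv` (outcome, time point
#' and the categorical clinical covariates) and `truth.json` into `dir`; the
#' set round-trips through [read_cohort()].
#'
#' @param cohort an `nf_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nf_cohort"))
  if (nrow(cohort$table$values) == 0L) stop("refusing to write an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$table, file.path(dir, "taxa.tsv"), classes = "taxon")
  write_feature_table(cohort$table, file.path(dir, "metabolites.tsv"),
                      classes = "metabolite")
  md <- cohort$metadata
  clin <- names(cohort$table$feature_class)[cohort$table$feature_class == "clinical"]
  mdf <- cbind(data.frame(sample_id = md$sample_id,
                          outcome = as.character(md$outcome),
                          timepoint = md$timepoint, stringsAsFactors = FALSE),
               cohort$table$values[md$sample_id, clin, drop = FALSE])
  utils::write.table(mdf, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_fixture()]
#'
#' @param dir directory containing `taxa.tsv`, `metabolites.tsv`,
#'   `metadata.tsv` and optionally `truth.json`.
#' @return list of class `nf_cohort` with `table`, `metadata`, `truth`
#'   (`NULL` when no `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  taxa <- read_feature_table(file.path(dir, "taxa.tsv"), "taxon", relative = TRUE)
  mets <- read_feature_table(file.path(dir, "metabolites.tsv"), "metabolite")
  md <- utils::read.delim(file.path(dir, "metadata.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  clin_cols <- setdiff(colnames(md), c("sample_id", "outcome", "timepoint"))
  vals <- cbind(taxa$values,
                mets$values[rownames(taxa$values), , drop = FALSE])
  fc <- c(rep("taxon", ncol(taxa$values)), rep("metabolite", ncol(mets$values)))
  if (length(clin_cols)) {
    clin <- md[match(rownames(vals), md$sample_id), clin_cols, drop = FALSE]
    rownames(clin) <- rownames(vals)
    clin[] <- lapply(clin, as.character)
    vals <- cbind(vals, clin)
    fc <- c(fc, rep("clinical", length(clin_cols)))
  }
  table <- feature_table(vals, fc, relative = TRUE)
  metadata <- sample_metadata(md$sample_id, md$outcome, md$timepoint)
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(true_biomarkers = as.character(tr$true_biomarkers),
                  effect_table = lapply(tr$effect_table, as.numeric),
                  groups = stats::setNames(as.character(tr$groups), names(tr$groups)))
  }
  structure(list(table = table, metadata = metadata, truth = truth,
                 config = NULL),
            class = "nf_cohort")
}
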