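#' Boosted-tree model configuration
#'
#' The seven tuned parameters of the gradient-boosted tree classifier
#' (binary objective, tree booster). `nrounds` is the cap on boosting
#' rounds; the round count actually used in a split is chosen by repeated
#' cross-validation (see [run_single_split()]).
#'
#' @param nrounds maximum boosting rounds (>= 1).
#' @param max_depth maximum tree depth.
#' @param min_child_weight minimum child hessian weight.
#' @param subsample row subsample fraction, in (0, 1].
#' @param colsample_bytree column subsample fraction, in (0, 1].
#' @param eta learning rate, in (0, 1].
#' @param gamma minimum split loss reduction (>= 0).
#' @param colsample_bynode per-split-node column subsample fraction. This is
#'   a fixed structural setting, not one of the seven tuned parameters: taxa
#'   and the metabolites they produce are strongly redundant, and without
#'   per-node feature subsampling (the decorrelation device of random
#'   forests) gain importance collapses onto whichever of a redundant group
#'   a tree tries first, making aggregate importance unstable.
#' @return a `model_config` list.
#' @export
model_config <- function(nrounds = 60, max_depth = 3, min_child_weight = 1,
                         subsample = 0.8, colsample_bytree = 0.5,
                         eta = 0.3, gamma = 0, colsample_bynode = 0.3) {
  if (nrounds < 1) stop("nrounds must be >= 1")
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  if (colsample_bytree <= 0 || colsample_bytree > 1)
    stop("colsample_bytree must be in (0, 1]")
  if (colsample_bynode <= 0 || colsample_bynode > 1)
    stop("colsample_bynode must be in (0, 1]")
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(nrounds = as.integer(round(nrounds)),
                 max_depth = as.integer(round(max_depth)),
                 min_child_weight = min_child_weight, subsample = subsample,
                 colsample_bytree = colsample_bytree, eta = eta,
                 gamma = gamma, colsample_bynode = colsample_bynode),
            class = "model_config")
}

xgb_params <- function(config, seed = 0L) {
  list(objective = "binary:logistic", booster = "gbtree",
       max_depth = config$max_depth,
       min_child_weight = config$min_child_weight,
       subsample = config$subsample,
       colsample_bytree = config$colsample_bytree,
       colsample_bynode = if (is.null(config$colsample_bynode)) 1
                          else config$colsample_bynode,
       eta = config$eta, gamma = config$gamma,
       nthread = 1L, seed = as.integer(seed))
}

#' Variable-selection variant specification
#'
#' The four preprocessing variants compared before model building:
#' A = all raw variables; B = CLR-transformed taxa; C = univariate screening
#' at P < 0.3; D = CLR transform of the taxa retained by the screen.
#'
#' @param id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return list: `id`, `clr_applied`, `univariate_screened`.
#' @export
variant_spec <- function(id = c("A", "B", "C", "D")) {
  id <- match.arg(id)
  list(id = id, clr_applied = id %in% c("B", "D"),
       univariate_screened = id %in% c("C", "D"))
}

#' Apply a variable-selection variant to a feature table
#'
#' Screening (variants C, D) runs [screen_features()] on the raw table over
#' the two compared outcome groups and keeps retained features only; the CLR
#' transform (variants B, D) is then applied to the taxon block of the
#' (possibly reduced) table, so variant D is exactly
#' `clr(screen-retained columns)`.
#'
#' @param table a [feature_table()] of raw values.
#' @param metadata a [sample_metadata()].
#' @param id variant id, `"A"`-`"D"`.
#' @param pair the two outcome groups of the binary comparison.
#' @param p_threshold screening threshold (default 0.3).
#' @return list: `table` (transformed `feature_table`), `screen`
#'   (a `screen_result` or `NULL`), `spec`.
#' @export
apply_variant <- function(table, metadata, id = "D",
                          pair = c("infectious NF", "non-infectious NF"),
                          p_threshold = 0.3) {
  spec <- variant_spec(id)
  scr <- NULL
  out <- table
  if (spec$univariate_screened) {
    scr <- screen_features(out, metadata, pair = pair, p_threshold = p_threshold)
    keep <- scr$feature[scr$retained]
    if (!length(keep)) stop("univariate screen retained no features")
    out <- out[, keep]
  }
  if (spec$clr_applied) out <- clr_transform(out)
  list(table = out, screen = scr, spec = spec)
}

# Rank-based AUROC via pROC; y is 0/1, higher score = positive class.
auroc <- function(y, score) {
  as.numeric(pROC::auc(response = y, predictor = score, levels = c(0, 1),
                       direction = "<", quiet = TRUE))
}

# Average precision (area under the precision-recall curve, step-wise).
average_precision <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- y[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

# Stratified train/test split: per class, round(test_frac * n) test samples
# (at least 1, at most n - 1).
stratified_split <- function(y, test_frac = 0.2) {
  test <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    k <- min(length(idx) - 1L, max(1L, round(test_frac * length(idx))))
    test <- c(test, sample(idx, k))
  }
  sort(test)
}

# Class-stratified fold assignment: every fold receives both classes
# (fold count is capped at the minority class size, floor 2).
make_stratified_folds <- function(y, k) {
  k <- max(2L, min(k, min(table(y))))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

# Boosting-round selection: median best iteration over `cv_repeats`
# early-stopped stratified 5-fold CV runs on the training data.
select_nrounds_cv <- function(dtrain, y, params, nrounds, cv_folds, cv_repeats) {
  best <- integer(cv_repeats)
  for (r in seq_len(cv_repeats)) {
    cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = nrounds,
                          folds = make_stratified_folds(y, cv_folds),
                          metrics = "auc", early_stopping_rounds = 10L,
                          verbose = 0)
    bi <- cv$early_stop$best_iteration
    best[r] <- if (is.null(bi) || !length(bi)) nrounds else bi
  }
  max(1L, as.integer(round(stats::median(best))))
}

#' Train and evaluate one stratified 80/20 split
#'
#' Splits the samples into training (80%) and test (20%) portions stratified
#' by outcome, chooses the boosting-round count by fivefold cross-validation
#' with `cv_repeats` repeats on the training portion (median best iteration
#' across early-stopped repeats), fits the final booster on the full
#' training portion, and evaluates AUROC and average precision on the
#' held-out test portion. Per-feature gain importance is rescaled so the top
#' feature of the split scores 1.
#'
#' @param x numeric matrix, samples x features (see [build_model_matrix()]).
#' @param y 0/1 outcome (1 = positive class), length `nrow(x)`.
#' @param config a [model_config()].
#' @param split_seed integer seed; identical seeds give identical splits and
#'   metrics.
#' @param test_frac held-out fraction (default 0.2).
#' @param cv_folds,cv_repeats cross-validation design for round selection.
#' @return list: `model` (xgboost booster), `auroc`, `avg_precision`,
#'   `importance` (named, max-normalized, 0 for unused features),
#'   `nrounds_used`, `test_index`.
#' @export
run_single_split <- function(x, y, config = model_config(), split_seed = 1,
                             test_frac = 0.2, cv_folds = 5, cv_repeats = 10) {
  y <- as.numeric(y)
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L || min(table(y)) < 5L)
    stop("each class needs at least 5 samples")
  seed <- as.integer(split_seed)
  for (attempt in 0:5) {
    set.seed(seed + attempt)
    test <- stratified_split(y, test_frac)
    if (length(unique(y[test])) == 2L && length(unique(y[-test])) == 2L) break
    message("degenerate split for seed ", seed + attempt, "; retrying")
  }
  params <- xgb_params(config, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(x[-test, , drop = FALSE],
                                 label = y[-test], nthread = 1L)
  nr <- select_nrounds_cv(dtrain, y[-test], params, config$nrounds,
                          cv_folds, cv_repeats)
  bst <- xgboost::xgb.train(params = params, data = dtrain, nrounds = nr,
                            verbose = 0)
  pred <- stats::predict(bst, x[test, , drop = FALSE])
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  it <- xgboost::xgb.importance(model = bst)
  if (nrow(it)) {
    g <- it$Gain / max(it$Gain)
    imp[it$Feature] <- g
  }
  list(model = bst, auroc = auroc(y[test], pred),
       avg_precision = average_precision(y[test], pred),
       importance = imp, nrounds_used = nr, test_index = test)
}

#' Aggregate model over repeated stratified splits
#'
#' Runs [run_single_split()] on `n_splits` independent stratified 80/20
#' splits (seeds `base_seed + 1 ... base_seed + n_splits`) and pools the
#' results: mean test AUROC with its SD, variance and 95% CI half-width
#' (`1.96 * SD / sqrt(n_splits)`), mean average precision, and per-feature
#' importance averaged across splits with 0 contributed by splits in which a
#' feature went unused.
#'
#' @inheritParams run_single_split
#' @param n_splits number of independent splits (default 100; < 10 warns).
#' @param base_seed base of the per-split seed sequence.
#' @return object of class `aggregate_report`: per-split `auroc` and
#'   `avg_precision` vectors, `mean_auroc`, `sd_auroc`, `var_auroc`,
#'   `ci_halfwidth`, `mean_avg_precision`, `importance` (named mean
#'   importance), `n_splits`, `config`.
#' @export
run_aggregate <- function(x, y, config = model_config(), n_splits = 100,
                          base_seed = 1, test_frac = 0.2, cv_folds = 5,
                          cv_repeats = 10) {
  if (n_splits < 10) warning("fewer than 10 splits: aggregate metrics are unstable")
  aucs <- numeric(n_splits); aps <- numeric(n_splits)
  impm <- matrix(0, n_splits, ncol(x), dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n_splits)) {
    res <- run_single_split(x, y, config, split_seed = base_seed + i,
                            test_frac = test_frac, cv_folds = cv_folds,
                            cv_repeats = cv_repeats)
    aucs[i] <- res$auroc; aps[i] <- res$avg_precision
    impm[i, ] <- res$importance
  }
  s <- stats::sd(aucs)
  structure(list(auroc = aucs, avg_precision = aps,
                 mean_auroc = mean(aucs), sd_auroc = s, var_auroc = s^2,
                 ci_halfwidth = 1.96 * s / sqrt(n_splits),
                 mean_avg_precision = mean(aps),
                 importance = colMeans(impm), n_splits = n_splits,
                 config = config, base_seed = base_seed),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf(paste0("aggregate_report: %d splits | AUROC %.3f ",
                     "(CI half-width %.4f, SD %.3f) | avg precision %.3f\n"),
              x$n_splits, x$mean_auroc, x$ci_halfwidth, x$sd_auroc,
              x$mean_avg_precision))
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(x$importance > 0)))]
  if (length(top))
    cat("top importance:",
        paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Select biomarkers by mean importance threshold
#'
#' Features whose mean importance (averaged across splits) is at or above
#' the threshold -- the inclusive rule used to seed the reduced "final"
#' model.
#'
#' @param report an [run_aggregate()] report.
#' @param threshold selection threshold (default 0.3, inclusive).
#' @return object of class `biomarker_set`: `features`, `importance` (their
#'   mean scores), `threshold`, `empty` flag.
#' @export
select_biomarkers <- function(report, threshold = 0.3) {
  stopifnot(inherits(report, "aggregate_report"))
  imp <- report$importance
  sel <- imp >= threshold - 1e-12  # roundoff guard: exactly-at-threshold selects
  feats <- names(imp)[sel]
  structure(list(features = feats, importance = imp[sel],
                 threshold = threshold, empty = !any(sel)),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  if (x$empty) cat(sprintf("biomarker_set: empty (no mean importance >= %.2f)\n",
                           x$threshold))
  else cat(sprintf("biomarker_set (threshold %.2f): %s\n", x$threshold,
                   paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Fit one final booster on all samples
#'
#' Chooses the boosting-round count by the same repeated CV as
#' [run_single_split()] (here on the full data) and fits a single booster,
#' e.g. for SHAP interpretation of the final reduced model.
#'
#' @inheritParams run_single_split
#' @param seed integer seed.
#' @return an xgboost booster.
#' @export
fit_final_model <- function(x, y, config = model_config(), seed = 1,
                            cv_folds = 5, cv_repeats = 10) {
  y <- as.numeric(y)
  set.seed(seed)
  params <- xgb_params(config, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  nr <- select_nrounds_cv(dtrain, y, params, config$nrounds, cv_folds,
                          cv_repeats)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nr, verbose = 0)
}

#' SHAP attribution summary for a fitted booster
#'
#' Per-sample, per-feature additive SHAP values on the log-odds scale
#' (TreeSHAP via the booster's `predcontrib` prediction). For every sample
#' the SHAP values plus the base value equal the model's margin prediction.
#' Features are ranked by mean |SHAP|; the direction summary is the sign of
#' the correlation between a feature's values and its SHAP values (positive:
#' high values push toward the positive class).
#'
#' @param model an xgboost booster fitted on the columns of `x`.
#' @param x numeric matrix with exactly the model's features.
#' @return list: `shap` (samples x features), `base_value`,
#'   `mean_abs_shap` (named, sorted decreasing), `ranking` (feature names by
#'   decreasing mean |SHAP|), `direction` (named -1/0/1).
#' @export
shap_summary <- function(model, x) {
  stopifnot(is.matrix(x))
  contrib <- tryCatch(stats::predict(model, x, predcontrib = TRUE),
                      error = function(e)
                        stop("feature mismatch between model and table: ",
                             conditionMessage(e)))
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  bias <- contrib[, bias_col]
  shap <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
  if (!identical(colnames(shap), colnames(x)))
    stop("feature mismatch between model and table")
  mas <- sort(colMeans(abs(shap)), decreasing = TRUE)
  direction <- vapply(colnames(shap), function(f) {
    if (stats::sd(x[, f]) == 0 || stats::sd(shap[, f]) == 0) return(0)
    sign(stats::cor(x[, f], shap[, f]))
  }, numeric(1))
  list(shap = shap, base_value = unname(bias[1]), mean_abs_shap = mas,
       ranking = names(mas), direction = direction)
}

#' Default hyperparameter search space
#'
#' Bounds for the seven tuned parameters used by [coarse_to_fine_tune()].
#'
#' @return named list of `c(lower, upper)` bounds.
#' @export
default_search_space <- function() {
  list(nrounds = c(50, 500), max_depth = c(2, 8), min_child_weight = c(1, 10),
       subsample = c(0.5, 1), colsample_bytree = c(0.5, 1),
       eta = c(0.01, 0.3), gamma = c(0, 5))
}

sample_space <- function(space, n) {
  cfgs <- lapply(seq_len(n), function(i) {
    v <- lapply(space, function(b) stats::runif(1, b[1], b[2]))
    v$nrounds <- round(v$nrounds); v$max_depth <- round(v$max_depth)
    v
  })
  cfgs
}

#' Coarse-to-fine hyperparameter search
#'
#' Iterative random search with range refinement: up to `max_random_iter`
#' configurations are sampled uniformly from the current space and scored by
#' stratified fivefold cross-validation AUROC; each parameter's range then
#' shrinks to the span of the top decile of that round. Refinement stops
#' when every range shrank by less than 10% or after 3 rounds, and a final
#' grid (at most `grid_points` <= 3 points per parameter) on the refined
#' space is evaluated. The best configuration over every evaluation is
#' returned with the full trace. Deterministic for a given seed.
#'
#' @inheritParams run_single_split
#' @param search_space named list of `c(lower, upper)` bounds for the 7
#'   parameters (see [default_search_space()]).
#' @param max_random_iter evaluations per random-search round (default 500).
#' @param seed integer seed.
#' @param grid_points points per parameter in the final grid (1-3).
#' @return list: `config` (best [model_config()]), `cv_auc` (its score),
#'   `trace` (data.frame of every evaluated configuration and score).
#' @export
coarse_to_fine_tune <- function(x, y, search_space = default_search_space(),
                                max_random_iter = 500, seed = 1,
                                cv_folds = 5, grid_points = 2) {
  stopifnot(is.matrix(x), grid_points >= 1, grid_points <= 3)
  space <- search_space[names(default_search_space())]
  if (any(vapply(space, is.null, logical(1))))
    stop("search_space must bound all 7 parameters")
  for (p in names(space)) {
    if (length(space[[p]]) != 2L || space[[p]][1] > space[[p]][2])
      stop("inverted or malformed bounds for ", p)
  }
  y <- as.numeric(y)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  evaluate <- function(cfg) {
    config <- model_config(nrounds = cfg$nrounds, max_depth = cfg$max_depth,
                           min_child_weight = cfg$min_child_weight,
                           subsample = cfg$subsample,
                           colsample_bytree = cfg$colsample_bytree,
                           eta = max(cfg$eta, 1e-4), gamma = cfg$gamma)
    set.seed(seed)  # identical folds for every evaluated configuration
    cv <- xgboost::xgb.cv(params = xgb_params(config, seed = seed),
                          data = dtrain, nrounds = config$nrounds,
                          folds = make_stratified_folds(y, cv_folds),
                          metrics = "auc", early_stopping_rounds = 10L,
                          verbose = 0)
    unname(cv$early_stop$best_score)
  }
  trace <- list()
  record <- function(phase, cfg, score) {
    trace[[length(trace) + 1L]] <<- data.frame(phase = phase,
      as.data.frame(cfg), cv_auc = score)
  }
  widths <- function(sp) vapply(sp, function(b) diff(b), numeric(1))
  if (all(widths(space) == 0)) {
    cfg <- lapply(space, `[`, 1)
    cfg$nrounds <- round(cfg$nrounds); cfg$max_depth <- round(cfg$max_depth)
    score <- evaluate(cfg)
    record("collapsed", cfg, score)
    return(list(config = do.call(model_config, cfg), cv_auc = score,
                trace = do.call(rbind, trace)))
  }
  set.seed(seed)
  best_cfg <- NULL; best_score <- -Inf
  for (round_i in 1:3) {
    cfgs <- sample_space(space, max_random_iter)
    scores <- vapply(cfgs, evaluate, numeric(1))
    for (k in seq_along(cfgs)) record(paste0("random_", round_i),
                                      cfgs[[k]], scores[k])
    if (max(scores) > best_score) {
      best_score <- max(scores); best_cfg <- cfgs[[which.max(scores)]]
    }
    top <- cfgs[order(scores, decreasing = TRUE)[
      seq_len(max(1L, ceiling(0.1 * length(cfgs))))]]
    old_w <- widths(space)
    for (p in names(space)) {
      v <- vapply(top, function(c) as.numeric(c[[p]]), numeric(1))
      space[[p]] <- range(v)
    }
    shrink <- ifelse(old_w > 0, 1 - widths(space) / old_w, 0)
    if (all(shrink < 0.10)) break
  }
  grid_vals <- lapply(space, function(b) {
    if (diff(b) == 0) b[1] else seq(b[1], b[2], length.out = grid_points)
  })
  grid <- expand.grid(grid_vals, KEEP.OUT.ATTRS = FALSE)
  grid <- unique(grid)
  for (k in seq_len(nrow(grid))) {
    cfg <- as.list(grid[k, ])
    cfg$nrounds <- round(cfg$nrounds); cfg$max_depth <- round(cfg$max_depth)
    score <- evaluate(cfg)
    record("grid", cfg, score)
    if (score > best_score) { best_score <- score; best_cfg <- cfg }
  }
  list(config = do.call(model_config, best_cfg), cv_auc = best_score,
       trace = do.call(rbind, trace))
}

#' End-to-end variant pipeline on a cohort table
#'
#' Applies a variable-selection variant, builds the numeric model matrix,
#' restricts to the two compared outcome groups (positive class = first
#' element of `pair`), and runs the aggregate model.
#'
#' @inheritParams apply_variant
#' @inheritParams run_aggregate
#' @return list: `report` (an `aggregate_report`), `screen`, `x`, `y`,
#'   `variant`.
#' @export
run_variant_pipeline <- function(table, metadata, variant = "D",
                                 pair = c("infectious NF", "non-infectious NF"),
                                 config = model_config(), n_splits = 100,
                                 base_seed = 1, p_threshold = 0.3,
                                 cv_folds = 5, cv_repeats = 10) {
  metadata <- align_metadata(table, metadata)
  av <- apply_variant(table, metadata, variant, pair = pair,
                      p_threshold = p_threshold)
  keep <- metadata$outcome %in% pair
  x <- build_model_matrix(av$table)[keep, , drop = FALSE]
  y <- as.numeric(metadata$outcome[keep] == pair[1])
  report <- run_aggregate(x, y, config = config, n_splits = n_splits,
                          base_seed = base_seed, cv_folds = cv_folds,
                          cv_repeats = cv_repeats)
  list(report = report, screen = av$screen, x = x, y = y, variant = variant)
}
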