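# Cost-weighted AdaBoost tree ensemble. The detector is AdaBoost.M1 over
# depth-limited CART weak learners (rpart), with the false-positive
# misclassification cost realized as asymmetric initial observation weights:
# non-seizure rows enter with weight fp_cost, seizure rows with weight 1, so
# that misclassifying background (a false alarm) costs fp_cost times as much
# in the weighted training error. The false-negative cost stays unweighted.

#' Detector hyperparameters
#'
#' @param learning_rate Shrinkage applied to each weak learner's vote weight.
#' @param n_learners Maximum number of weak learners (boosting rounds).
#' @param max_depth Maximum tree depth per weak learner.
#' @param fp_cost Misclassification cost multiplier for false positives
#'   (>= 1); false negatives are unweighted.
#' @return List of class `gtbm_params`.
#' @export
gtbm_params <- function(learning_rate = 0.1, n_learners = 100, max_depth = 3,
                        fp_cost = 1) {
  stopifnot(learning_rate > 0, n_learners >= 1, max_depth >= 1, fp_cost >= 1)
  structure(list(learning_rate = learning_rate,
                 n_learners = as.integer(n_learners),
                 max_depth = as.integer(max_depth), fp_cost = fp_cost),
            class = "gtbm_params")
}

#' Default hyperparameter grid (600 combinations)
#'
#' 5 learning rates x 4 ensemble sizes x 5 depths x 6 false-positive costs.
#'
#' @return List of [gtbm_params()].
#' @export
param_grid_default <- function() {
  .make_grid(learning_rate = c(0.05, 0.1, 0.2, 0.5, 1.0),
             n_learners = c(50, 100, 200, 500),
             max_depth = c(1, 2, 3, 5, 10),
             fp_cost = c(1, 2, 5, 10, 20, 50))
}

#' Reduced hyperparameter grid (24 combinations)
#'
#' Desk-scale grid for the cross-validation harnesses: 2 learning rates x 2
#' ensemble sizes x 2 depths x 3 false-positive costs.
#'
#' @return List of [gtbm_params()].
#' @export
param_grid_reduced <- function() {
  .make_grid(learning_rate = c(0.1, 0.5), n_learners = c(20, 50),
             max_depth = c(1, 2), fp_cost = c(1, 5, 20))
}

.make_grid <- function(...) {
  df <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    do.call(gtbm_params, as.list(df[i, ])))
}

#' Train the cost-weighted AdaBoost ensemble
#'
#' AdaBoost.M1 with CART weak learners: each round fits a depth-limited tree
#' to the weighted sample, earns a vote `alpha = learning_rate * 0.5 *
#' log((1 - err) / err)` from its weighted error, and up-weights its
#' misclassifications. Boosting stops early when a round is perfect or no
#' better than chance. Training is deterministic given the data.
#'
#' @param x Standardized feature matrix (no `NA`; masked entries imputed 0).
#' @param y Binary labels (0/1 or logical), both classes present.
#' @param params A [gtbm_params()].
#' @return List of class `gtbm_ensemble`: `trees`, `alphas`, `params`.
#' @export
train_gtbm <- function(x, y, params = gtbm_params()) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0L, 1L))
  w <- ifelse(y == 0L, params$fp_cost, 1)
  w <- w / sum(w)
  ctrl <- rpart::rpart.control(maxdepth = params$max_depth, cp = 0,
                               minsplit = 2, minbucket = 1, xval = 0,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  trees <- list()
  alphas <- numeric()
  xmat <- as.matrix(x)
  for (m in seq_len(params$n_learners)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    miss <- (.rpart_vote(fit, xmat) > 0) != (y == 1L)
    err <- sum(w[miss])
    if (err <= 0) {            # perfect weak learner: it decides alone
      trees[[m]] <- fit
      alphas[m] <- 1
      break
    }
    if (err >= 0.5) {          # no better than chance: stop boosting
      if (m == 1L) { trees[[m]] <- fit; alphas[m] <- 1e-3 }
      break
    }
    alpha <- params$learning_rate * 0.5 * log((1 - err) / err)
    trees[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(alpha * 2 * miss)   # e^{+a} if missed, 1 otherwise
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, params = params),
            class = "gtbm_ensemble")
}

# vectorized traversal of an rpart classification tree (matrix input).
# Valid for trees grown with maxcompete = 0 / maxsurrogate = 0 and numeric
# predictors: the splits matrix then has exactly one row per internal node,
# in frame order. Returns +1 for class "1", -1 for class "0".
.rpart_vote <- function(tree, x) {
  frame <- tree$frame
  n <- nrow(x)
  out <- numeric(n)
  internal <- which(frame$var != "<leaf>")
  if (!length(internal))
    return(rep(if (frame$yval[1L] == 2) 1 else -1, n))
  split_row <- integer(nrow(frame))
  split_row[internal] <- seq_along(internal)
  splits <- tree$splits
  node_of <- as.integer(rownames(frame))
  frow_of <- setNames(seq_len(nrow(frame)), node_of)

  recurse <- function(fr, idx) {
    if (!length(idx)) return(invisible())
    if (frame$var[fr] == "<leaf>") {
      out[idx] <<- if (frame$yval[fr] == 2) 1 else -1
      return(invisible())
    }
    sr <- split_row[fr]
    v <- as.character(frame$var[fr])
    thr <- splits[sr, "index"]
    goes_left <- if (splits[sr, "ncat"] < 0) x[idx, v] < thr
                 else x[idx, v] >= thr
    node <- node_of[fr]
    recurse(frow_of[[as.character(2L * node)]], idx[goes_left])
    recurse(frow_of[[as.character(2L * node + 1L)]], idx[!goes_left])
  }
  recurse(1L, seq_len(n))
  out
}

.gtbm_score <- function(ens, x) {
  x <- as.matrix(x)
  s <- numeric(nrow(x))
  for (m in seq_along(ens$trees))
    s <- s + ens$alphas[m] * .rpart_vote(ens$trees[[m]], x)
  s
}

#' Bundle an ensemble with its normalization and schema
#'
#' Predictions on unstandardized data are an error by construction: the
#' bundle refuses to exist without stored normalization parameters, and
#' [predict.model_bundle()] standardizes internally with them.
#'
#' @param ensemble A [train_gtbm()] result.
#' @param norm A [zscore_fit()] result.
#' @param feature_names Feature schema (canonical 11 names).
#' @return List of class `model_bundle`.
#' @export
model_bundle <- function(ensemble, norm, feature_names = names(norm$center)) {
  stopifnot(inherits(ensemble, "gtbm_ensemble"), inherits(norm, "norm_params"))
  structure(list(ensemble = ensemble, params = ensemble$params, norm = norm,
                 feature_names = feature_names),
            class = "model_bundle")
}

#' Fit the detector on raw (unstandardized) training rows
#'
#' Fits z-score parameters on the training rows, standardizes and imputes,
#' trains the cost-weighted ensemble, and returns the bundle holding both.
#'
#' @param x Raw feature matrix of the training rows (`NA` = masked).
#' @param y Binary labels.
#' @param params A [gtbm_params()].
#' @return A [model_bundle()].
#' @export
fit_detector <- function(x, y, params = gtbm_params()) {
  norm <- zscore_fit(x)
  xs <- zscore_apply(norm, x)
  model_bundle(train_gtbm(xs, y, params), norm)
}

#' Predict binary labels on a feature grid
#'
#' Standardizes the grid features with the bundle's stored normalization
#' parameters (columns aligned by name), imputes masked entries at the
#' training mean, and thresholds the ensemble score. Rows whose features are
#' all masked are predicted 0.
#'
#' @param object A [model_bundle()].
#' @param grid A `feature_grid`, or a raw feature matrix.
#' @param ... Unused.
#' @return Integer 0/1 vector.
#' @export
predict.model_bundle <- function(object, grid, ...) {
  x <- if (inherits(grid, "feature_grid")) grid$features else grid
  if (!all(object$feature_names %in% colnames(x)))
    stop("schema error: grid features do not match the model's feature names")
  all_masked <- !rowSums(is.finite(x[, object$feature_names, drop = FALSE]))
  xs <- zscore_apply(object$norm, x)
  s <- .gtbm_score(object$ensemble, xs)
  out <- as.integer(s > 0)
  out[all_masked] <- 0L
  out
}

.bundle_format_version <- 1L

#' Save / load a model bundle
#'
#' The bundle is persisted as a versioned archive (R serialization) holding
#' the ensemble, the stored normalization parameters, the hyperparameters and
#' the feature schema. Loading refuses archives with a different format
#' version or feature schema.
#'
#' @param bundle A [model_bundle()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(list(format_version = .bundle_format_version,
               feature_names = bundle$feature_names,
               bundle = bundle), path)
  invisible(path)
}

#' @rdname save_bundle
#' @param expected_features Feature schema the caller requires (default: the
#'   canonical 11 names when the archive holds 11 features).
#' @return `load_bundle`: the [model_bundle()].
#' @export
load_bundle <- function(path, expected_features = NULL) {
  arc <- readRDS(path)
  if (!identical(arc$format_version, .bundle_format_version))
    stop(sprintf("bundle format version %s not supported",
                 arc$format_version))
  if (!inherits(arc$bundle, "model_bundle"))
    stop("archive does not contain a model bundle")
  if (!is.null(expected_features) &&
      !identical(arc$feature_names, expected_features))
    stop("schema mismatch: archive feature names differ from expected")
  arc$bundle
}

#' Gini feature importance
#'
#' Per-feature total decrease in Gini node impurity, averaged over all trees
#' in the ensemble; with a list of bundles, additionally averaged over
#' bundles. Features never used in a split score 0, the smallest possible
#' value.
#'
#' @param bundle A [model_bundle()], [train_gtbm()] result, or a list of
#'   bundles.
#' @return Named numeric vector (length 11 for the canonical schema).
#' @export
importance <- function(bundle) {
  if (inherits(bundle, "model_bundle"))
    return(.importance_one(bundle$ensemble, bundle$feature_names))
  if (inherits(bundle, "gtbm_ensemble"))
    return(.importance_one(bundle, NULL))
  stopifnot(is.list(bundle), length(bundle) >= 1L)
  per <- lapply(bundle, importance)
  Reduce(`+`, per) / length(per)
}

.importance_one <- function(ens, feat_names) {
  if (is.null(feat_names))
    feat_names <- setdiff(attr(ens$trees[[1L]]$terms, "term.labels"), ".y")
  acc <- setNames(numeric(length(feat_names)), feat_names)
  for (tr in ens$trees) {
    vi <- tr$variable.importance
    if (!is.null(vi)) {
      common <- intersect(names(vi), feat_names)
      acc[common] <- acc[common] + vi[common]
    }
  }
  pmax(acc / length(ens$trees), 0)
}

# selection order: sensitivity desc, FP count asc, learning rate desc,
# n_learners asc (computational efficiency), then depth and cost asc to make
# the order total
.rank_params <- function(tab) {
  order(-tab$mean_sensitivity, tab$mean_fp, -tab$learning_rate,
        tab$n_learners, tab$max_depth, tab$fp_cost)
}

#' Grid-search hyperparameter optimization
#'
#' Scores every parameter combination on every fold at the event level and
#' selects the winner by the rules: highest mean sensitivity, then lowest
#' mean false-positive count, then higher learning rate, then fewer learners
#' (computational efficiency), then lower depth, then lower cost - a total
#' order, so the winner is unique.
#'
#' @param folds List of folds; each fold is a list with `x_train`, `y_train`
#'   (raw training rows + labels), `x_test`, `test_times` (raw test rows on
#'   the grid), `truth` (event matrix of true seizure intervals in the test
#'   span), and `hours` (recorded hours of the test span).
#' @param grid List of [gtbm_params()] (non-empty).
#' @param margin_s Event-matching margin (s).
#' @return List: `best` (the winning [gtbm_params()]), `table` (per-
#'   combination mean scores, for audit), `fold_scores` (list, per combination
#'   x fold).
#' @export
grid_search <- function(folds, grid, margin_s = 120) {
  if (!length(grid)) stop("empty hyperparameter grid")
  stopifnot(length(folds) >= 1L)
  nc <- length(grid)
  sens <- matrix(NA_real_, nc, length(folds))
  fps <- matrix(NA_real_, nc, length(folds))
  fold_scores <- vector("list", nc)
  for (ci in seq_len(nc)) {
    p <- grid[[ci]]
    reports <- vector("list", length(folds))
    for (fi in seq_along(folds)) {
      f <- folds[[fi]]
      bundle <- fit_detector(f$x_train, f$y_train, p)
      pred <- predict(bundle, f$x_test)
      rep <- score_prediction(pred, f$test_times, f$truth,
                              recording_hours = f$hours, margin_s = margin_s,
                              night = f$night)
      reports[[fi]] <- rep
      sens[ci, fi] <- rep$sensitivity
      fps[ci, fi] <- rep$fp
    }
    fold_scores[[ci]] <- reports
  }
  tab <- data.frame(
    learning_rate = vapply(grid, `[[`, 0, "learning_rate"),
    n_learners = vapply(grid, `[[`, 0L, "n_learners"),
    max_depth = vapply(grid, `[[`, 0L, "max_depth"),
    fp_cost = vapply(grid, `[[`, 0, "fp_cost"),
    mean_sensitivity = rowMeans(sens),
    mean_fp = rowMeans(fps))
  best_i <- .rank_params(tab)[1L]
  list(best = grid[[best_i]], best_index = best_i, table = tab,
       fold_scores = fold_scores)
}
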