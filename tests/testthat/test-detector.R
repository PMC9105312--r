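# linearly separable in f1 with a clear margin; optional label noise makes
# the problem unseparable for the cost-monotonicity checks
make_toy <- function(n = 200, seed = 61, noise = 0) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(f1 = c(runif(n / 2, -2, -0.5), runif(n / 2, 0.5, 2)),
             f2 = rnorm(n))
  if (noise > 0) {
    flip <- sample(n, round(noise * n))
    y[flip] <- 1L - y[flip]
  }
  list(x = x, y = y)
}

test_that("training achieves zero error on separable data; single class errors", {
  toy <- make_toy()
  xs <- zscore_apply(zscore_fit(toy$x), toy$x)
  ens <- train_gtbm(xs, toy$y, gtbm_params(0.5, 10, 1, 1))
  score <- ictalwear:::.gtbm_score(ens, xs)
  expect_equal(as.integer(score > 0), toy$y)
  expect_error(train_gtbm(xs, rep(1L, nrow(xs)), gtbm_params()),
               "single class")
})

test_that("higher FP cost never increases training false positives", {
  toy <- make_toy(n = 400, noise = 0.15)
  xs <- zscore_apply(zscore_fit(toy$x), toy$x)
  fp_count <- vapply(c(1, 5, 20, 50), function(cost) {
    ens <- train_gtbm(xs, toy$y, gtbm_params(0.2, 30, 2, cost))
    pred <- ictalwear:::.gtbm_score(ens, xs) > 0
    sum(pred & toy$y == 0L)
  }, 0)
  expect_true(all(diff(fp_count) <= 0))
})

test_that("a one-round depth-1 model equals the exhaustive weighted stump", {
  toy <- make_toy(n = 120, seed = 62, noise = 0.05)
  x <- toy$x; y <- toy$y
  w <- ifelse(y == 0L, 10, 1); w <- w / sum(w)
  # exhaustive search over all split points on both features, minimizing
  # weighted Gini impurity of the two children (rpart's criterion)
  best <- list(gini = Inf)
  for (j in 1:2) for (thr in sort(unique(x[, j]))) {
    left <- x[, j] < thr
    for (side in 1:2) {
      wl <- sum(w[left]); wr <- sum(w[!left])
      if (wl == 0 || wr == 0) next
      p1l <- sum(w[left & y == 1]) / wl
      p1r <- sum(w[!left & y == 1]) / wr
      gini <- wl * 2 * p1l * (1 - p1l) + wr * 2 * p1r * (1 - p1r)
      if (gini < best$gini)
        best <- list(gini = gini, j = j, thr = thr,
                     pred_left = as.integer(p1l > p1r))
    }
  }
  oracle_pred <- ifelse(x[, best$j] < best$thr, best$pred_left,
                        1L - best$pred_left)
  ens <- train_gtbm(x, y, gtbm_params(1, 1, 1, 10))
  got <- as.integer(ictalwear:::.gtbm_score(ens, x) > 0)
  expect_equal(got, oracle_pred)
})

test_that("prediction aligns columns by name and handles masked rows", {
  toy <- make_toy()
  bundle <- fit_detector(toy$x, toy$y, gtbm_params(0.5, 10, 1, 1))
  p1 <- predict(bundle, toy$x)
  expect_equal(p1, toy$y)
  # shuffled column order with correct names gives identical output
  shuffled <- toy$x[, c("f2", "f1")]
  expect_identical(predict(bundle, shuffled), p1)
  # schema mismatch errors
  bad <- toy$x; colnames(bad) <- c("a", "b")
  expect_error(predict(bundle, bad), "schema")
  # all-masked rows are predicted 0
  xm <- toy$x; xm[1:5, ] <- NA
  expect_true(all(predict(bundle, xm)[1:5] == 0L))
})

test_that("training and prediction are reproducible across runs", {
  toy <- make_toy(n = 300, noise = 0.2)
  b1 <- fit_detector(toy$x, toy$y, gtbm_params(0.2, 25, 3, 5))
  b2 <- fit_detector(toy$x, toy$y, gtbm_params(0.2, 25, 3, 5))
  expect_identical(predict(b1, toy$x), predict(b2, toy$x))
  expect_identical(b1$ensemble$alphas, b2$ensemble$alphas)
})

test_that("parameter selection follows the stated total order", {
  tab <- function(...) as.data.frame(list(...))
  # highest sensitivity wins
  t1 <- tab(learning_rate = c(0.1, 0.1), n_learners = c(50L, 50L),
            max_depth = c(1L, 1L), fp_cost = c(1, 1),
            mean_sensitivity = c(1.0, 0.5), mean_fp = c(10, 0))
  expect_equal(ictalwear:::.rank_params(t1)[1], 1L)
  # equal sensitivity: fewer false positives wins
  t2 <- t1; t2$mean_sensitivity <- c(1, 1); t2$mean_fp <- c(7, 3)
  expect_equal(ictalwear:::.rank_params(t2)[1], 2L)
  # full tie on scores: higher learning rate wins
  t3 <- t2; t3$mean_fp <- c(3, 3); t3$learning_rate <- c(0.1, 0.5)
  expect_equal(ictalwear:::.rank_params(t3)[1], 2L)
  # ... then lower number of trees
  t4 <- t3; t4$learning_rate <- c(0.5, 0.5); t4$n_learners <- c(200L, 50L)
  expect_equal(ictalwear:::.rank_params(t4)[1], 2L)
  # the order is total: a unique winner for any table
  set.seed(63)
  t5 <- tab(learning_rate = rep(0.1, 4), n_learners = rep(50L, 4),
            max_depth = c(1L, 2L, 1L, 2L), fp_cost = c(1, 1, 5, 5),
            mean_sensitivity = rep(0.8, 4), mean_fp = rep(2, 4))
  expect_length(ictalwear:::.rank_params(t5)[1], 1L)
  expect_equal(ictalwear:::.rank_params(t5)[1], 1L)  # depth then cost asc
  expect_error(grid_search(list(), list()), "empty|folds")
})

test_that("bundle persistence round trips and rejects schema mismatches", {
  toy <- make_toy()
  bundle <- fit_detector(toy$x, toy$y, gtbm_params(0.5, 5, 1, 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bundle, path)
  back <- load_bundle(path, expected_features = c("f1", "f2"))
  expect_identical(predict(back, toy$x), predict(bundle, toy$x))
  expect_error(load_bundle(path, expected_features = feature_names()),
               "schema mismatch")
  saveRDS(list(format_version = 99L, bundle = bundle), path)
  expect_error(load_bundle(path), "version")
})

test_that("default and reduced grids have the declared cardinality", {
  expect_length(param_grid_default(), 600L)
  expect_length(param_grid_reduced(), 24L)
})

test_that("Gini importance: unused features 0, stumps concentrate, planted
           signal group dominates", {
  toy <- make_toy()
  # single stump splits on f1 only
  b <- fit_detector(toy$x, toy$y, gtbm_params(1, 1, 1, 1))
  imp <- importance(b)
  expect_gt(imp[["f1"]], 0)
  expect_equal(imp[["f2"]], 0)

  # planted signal: only the EDA columns carry class information
  set.seed(64)
  n <- 400
  x <- matrix(rnorm(n * 11), n, 11, dimnames = list(NULL, feature_names()))
  y <- rep(0:1, each = n / 2)
  eda_cols <- grep("^f_eda", feature_names())
  x[, eda_cols] <- x[, eda_cols] + 2 * y
  b2 <- fit_detector(x, y, gtbm_params(0.3, 40, 2, 1))
  imp2 <- importance(b2)
  expect_gt(mean(imp2[eda_cols]),
            mean(imp2[grep("^f_acc", feature_names())]))
  expect_gt(mean(imp2[eda_cols]),
            mean(imp2[grep("^f_bvp", feature_names())]))
  expect_true(all(imp2 >= 0) && length(imp2) == 11L)

  # averaging over a list of bundles
  imp3 <- importance(list(b2, b2))
  expect_equal(imp3, imp2)
})
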