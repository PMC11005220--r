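test_that("the stratified 70/30 split reproduces the study arithmetic", {
  # 17 animals over 5 age groups (3,3,3,4,4) -> train 11 / test 6
  sp <- split_cohort(17, 0.7, stratify_by = seventeen_ages(), seed = 1)
  expect_length(sp$train, 11)
  expect_length(sp$test, 6)
  expect_setequal(c(sp$train, sp$test), 1:17)
  # every age group represented in training
  expect_setequal(unique(seventeen_ages()[sp$train]), c(6, 20, 56, 64, 80))

  sp2 <- split_cohort(10, 0.7, seed = 3)
  expect_length(sp2$train, 7)
  expect_length(sp2$test, 3)

  # determinism and seed sensitivity
  expect_identical(sp, split_cohort(17, 0.7, seventeen_ages(), seed = 1))
  expect_false(identical(sp$train,
                         split_cohort(17, 0.7, seventeen_ages(),
                                      seed = 2)$train))

  expect_warning(sp3 <- split_cohort(5, 0.7, stratify_by = c(1, 1, 1, 1, 2),
                                     seed = 1),
                 "stratum of size 1")
  expect_true(5 %in% sp3$train)
})

test_that("forest fits honor degenerate targets and the leaf-mean bound", {
  X <- with_seed(5, data.frame(a = stats::rnorm(30), b = stats::rnorm(30)))
  m <- fit_forest(X, rep(40, 30), forest_hyperparams(n_trees = 50, seed = 2))
  expect_equal(predict(m, X), rep(40, 30))
  expect_equal(m$oob_rmse, 0)
  expect_equal(unname(importance_incnodepurity(m)$IncNodePurity), c(0, 0))

  y <- with_seed(6, stats::rnorm(30, 50, 20))
  m2 <- fit_forest(X, y, forest_hyperparams(n_trees = 100, seed = 3))
  newx <- with_seed(7, data.frame(a = stats::rnorm(50, 3),
                                  b = stats::rnorm(50, -3)))
  p <- predict(m2, newx)
  expect_true(all(p >= min(y) & p <= max(y)))

  # bit-identical refit under the same seed
  m3 <- fit_forest(X, y, forest_hyperparams(n_trees = 100, seed = 3))
  expect_identical(predict(m3, newx), p)
  expect_identical(importance_incnodepurity(m3), importance_incnodepurity(m2))
})

test_that("an informative feature dominates the importance ranking", {
  hits <- vapply(1:20, function(s) {
    X <- with_seed(s, data.frame(sig = stats::rnorm(40),
                                 n1 = stats::rnorm(40),
                                 n2 = stats::rnorm(40)))
    y <- ifelse(X$sig > 0, 10, 0)  # noiseless step of one feature
    m <- fit_forest(X, y, forest_hyperparams(n_trees = 100,
                                             seed = mix_seed(s, 9)))
    importance_incnodepurity(m)$feature[1] == "sig"
  }, TRUE)
  expect_true(all(hits))
})

test_that("a single stump's importance equals the hand-computed SSE drop", {
  # {(x=0, y=0) x3, (x=1, y=6) x3}: root SSE 54, children pure -> delta 54
  X <- data.frame(x = c(0, 0, 0, 1, 1, 1), flat = rep(1, 6))
  y <- c(0, 0, 0, 6, 6, 6)
  m <- fit_forest(X, y, forest_hyperparams(n_trees = 1, m_try = 2,
                                           min_leaf = 1, bootstrap = FALSE,
                                           max_nodes = 2, seed = 1))
  imp <- importance_incnodepurity(m)
  expect_equal(imp$IncNodePurity[imp$feature == "x"], 54)
  expect_equal(imp$IncNodePurity[imp$feature == "flat"], 0)  # never split on
})

test_that("stump splits match the exhaustive brute-force oracle", {
  for (s in 1:20) {
    n <- with_seed(s, sample(6:12, 1))
    X <- with_seed(mix_seed(s, 1),
                   data.frame(matrix(stats::rnorm(n * 3), n, 3)))
    y <- with_seed(mix_seed(s, 2), stats::rnorm(n))
    m <- fit_forest(X, y,
                    forest_hyperparams(n_trees = 1, m_try = 3, min_leaf = 1,
                                       bootstrap = FALSE, max_nodes = 2,
                                       seed = s))
    oracle <- brute_force_split(X, y)
    imp <- importance_incnodepurity(m)
    expect_equal(imp$IncNodePurity[1], oracle$delta, tolerance = 1e-8)
    # the engine's chosen feature attains the optimal SSE decrease (exact
    # cross-feature ties happen at small n when the same points separate)
    expect_true(match(imp$feature[1], names(X)) %in% oracle$optimal_features)
  }
})

test_that("duplicating a feature splits its importance but conserves the sum", {
  base_imp <- dup_imp <- numeric(50)
  for (s in 1:50) {
    X <- with_seed(s, data.frame(sig = stats::rnorm(30),
                                 noise = stats::rnorm(30)))
    y <- 2 * X$sig + with_seed(mix_seed(s, 3), stats::rnorm(30, 0, 0.3))
    # all features visible at every split, so duplication cannot change
    # which points are separable, only who gets the credit
    m1 <- fit_forest(X, y, forest_hyperparams(n_trees = 100, m_try = 2,
                                              seed = mix_seed(s, 4)))
    X2 <- X; X2$sig_copy <- X$sig
    m2 <- fit_forest(X2, y, forest_hyperparams(n_trees = 100, m_try = 3,
                                               seed = mix_seed(s, 5)))
    i1 <- importance_incnodepurity(m1)
    i2 <- importance_incnodepurity(m2)
    base_imp[s] <- i1$IncNodePurity[i1$feature == "sig"]
    dup_imp[s] <- sum(i2$IncNodePurity[i2$feature %in% c("sig", "sig_copy")])
  }
  expect_lt(abs(mean(dup_imp) / mean(base_imp) - 1), 0.1)
  # and the copies individually carry less than the original on average
  expect_lt(mean(dup_imp) / 2, mean(base_imp))
})

test_that("the sparse clock selects k features and records its CV honestly", {
  lf <- ladder_features(4, seed = 33)
  expect_error(train_sparse_clock(lf$features, k = 20),
               "exceeds 14 available")
  clk <- suppressWarnings(
    train_sparse_clock(lf$features, n_trees = 100, seed = 11))
  expect_length(clk$selected_features, 6)
  expect_true(all(clk$selected_features %in% feature_columns()))
  expect_equal(clk$selected_features, clk$importance$feature[1:6])
  expect_equal(length(clk$split$train), floor(0.7 * 20))
  expect_equal(nrow(clk$cv_results), 5 * nrow(unique(
    clk$cv_results[, c("m_try", "min_leaf")])))
  expect_true(all(clk$cv_results$RMSE >= 0))

  # determinism of the whole two-stage construction
  clk2 <- suppressWarnings(
    train_sparse_clock(lf$features, n_trees = 100, seed = 11))
  expect_identical(clk$selected_features, clk2$selected_features)
  expect_identical(clk$test_metrics, clk2$test_metrics)
  expect_identical(predict_ee_age(clk, lf$features)$per_animal,
                   predict_ee_age(clk2, lf$features)$per_animal)
})

test_that("small training sets reduce folds with a warning, as in a 17-animal cohort", {
  coh <- simulate_cohort(cohort_spec(
    data.frame(label = paste0(c(6, 20, 56, 64, 80), "w"),
               age_weeks = c(6, 20, 56, 64, 80),
               n = c(3, 3, 3, 4, 4),
               intervention_shift_weeks = 0), seed = 8))
  rhy <- lapply(coh$recordings, cosinor_fit_recording)
  ft <- build_feature_table(coh$recordings, rhy)
  expect_equal(nrow(ft), 17)
  expect_warning(
    clk <- train_sparse_clock(ft, n_trees = 50, seed = 2,
                              hp_grid = data.frame(m_try = 2, min_leaf = 2)),
    "folds of size")
  expect_length(clk$split$train, 11)
  expect_length(clk$split$test, 6)
})

test_that("prediction enforces the feature schema", {
  lf <- ladder_features(2, seed = 41)
  clk <- suppressWarnings(
    train_sparse_clock(lf$features, n_trees = 50, seed = 3,
                       hp_grid = data.frame(m_try = 2, min_leaf = 2)))
  expect_error(predict_ee_age(clk, lf$features[0, ]), "empty feature table")
  broken <- lf$features[, setdiff(colnames(lf$features),
                                  clk$selected_features[1])]
  expect_error(predict_ee_age(clk, broken), clk$selected_features[1])
  pred <- predict_ee_age(clk, lf$features)
  expect_true(all(pred$per_animal$ee_age_weeks >= 6 &
                    pred$per_animal$ee_age_weeks <= 80))
})

test_that("feature column order does not change clock accuracy materially", {
  lf <- ladder_features(3, seed = 51)
  rmse_diff <- vapply(1:5, function(s) {
    ft <- lf$features
    perm <- with_seed(s, sample(feature_columns()))
    ft_perm <- ft[, c("animal_id", perm, "age_weeks", "group")]
    attr(ft_perm, "feature_cols") <- perm
    a <- suppressWarnings(train_sparse_clock(
      ft, n_trees = 100, seed = s,
      hp_grid = data.frame(m_try = 3, min_leaf = 2)))
    b <- suppressWarnings(train_sparse_clock(
      ft_perm, n_trees = 100, seed = s,
      hp_grid = data.frame(m_try = 3, min_leaf = 2)))
    abs(a$test_metrics[["RMSE"]] - b$test_metrics[["RMSE"]])
  }, 0)
  expect_lt(mean(rmse_diff), 1)  # weeks
})
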