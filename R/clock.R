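# The energy-expenditure aging clock: a bagged regression-tree age model on
# the 14 metabolic features, IncNodePurity importance ranking, a sparse
# top-6 refit tuned by repeated cross-validation, and metabolic-age
# prediction.

#' Forest hyperparameters
#'
#' @param n_trees number of trees (default 500).
#' @param m_try candidate features per split (default `floor(p/3)`, at
#'   least 1, resolved at fit time when `NULL`).
#' @param min_leaf minimum terminal-node size (default 5).
#' @param bootstrap bootstrap-resample each tree (default `TRUE`; when
#'   `FALSE` every tree sees the full sample, useful for deterministic
#'   single-tree analyses).
#' @param max_nodes optional cap on terminal nodes per tree (e.g. 2 for
#'   depth-1 stumps); `NULL` for unrestricted.
#' @param seed RNG seed for tree growing.
#' @return a `forest_hyperparams` list.
#' @export
forest_hyperparams <- function(n_trees = 500, m_try = NULL, min_leaf = 5,
                               bootstrap = TRUE, max_nodes = NULL,
                               seed = 1) {
  stopifnot(n_trees >= 1, min_leaf >= 1)
  structure(list(n_trees = n_trees, m_try = m_try, min_leaf = min_leaf,
                 bootstrap = bootstrap, max_nodes = max_nodes,
                 seed = as.integer(seed)),
            class = "forest_hyperparams")
}

#' Stratified 70/30 cohort split
#'
#' Deterministic given the seed. The training set receives exactly
#' `floor(train_frac * n)` animals; within strata the per-stratum training
#' counts are the floors of proportional targets, with the remainder
#' distributed by largest fractional part (ties by stratum order), so each
#' age group is represented in training whenever its size permits. A
#' stratum of size 1 goes to training with a warning.
#'
#' @param n cohort size (>= 2).
#' @param train_frac training fraction (default 0.7).
#' @param stratify_by optional vector of length `n` (e.g. age labels).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(n, train_frac = 0.7, stratify_by = NULL, seed = 1) {
  stopifnot(n >= 2, train_frac > 0, train_frac < 1)
  n_train <- floor(train_frac * n)
  if (is.null(stratify_by)) stratify_by <- rep(1, n)
  stopifnot(length(stratify_by) == n)
  strata <- split(seq_len(n), factor(stratify_by,
                                     levels = unique(stratify_by)))
  sizes <- lengths(strata)
  if (any(sizes == 1))
    warning("stratum of size 1 assigned to the training set: ",
            paste(names(strata)[sizes == 1], collapse = ", "))
  target <- train_frac * sizes
  take <- pmin(floor(target), sizes)
  take[sizes == 1] <- 1
  rem <- n_train - sum(take)
  if (rem > 0) {
    frac <- target - floor(target)
    frac[take >= sizes] <- -Inf
    ord <- order(-frac, seq_along(strata))
    for (i in ord) {
      if (rem <= 0) break
      if (take[i] < sizes[i]) { take[i] <- take[i] + 1; rem <- rem - 1 }
    }
  } else if (rem < 0) {
    # size-1 strata forced into training can overshoot; trim largest takes
    ord <- order(-take)
    for (i in ord) {
      if (rem >= 0) break
      if (sizes[i] > 1 && take[i] > 1) { take[i] <- take[i] - 1; rem <- rem + 1 }
    }
  }
  train <- integer(0)
  for (i in seq_along(strata))
    train <- c(train, with_seed(mix_seed(seed, i),
                                sample(strata[[i]], take[i])))
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a bagged regression forest
#'
#' Regression trees grown on bootstrap resamples with the sum-of-squares
#' split criterion over `m_try` randomly chosen candidate features;
#' prediction is the mean over trees. Delegates tree growing to the
#' `randomForest` engine under the package's seeding policy, so identical
#' (data, hyperparameters, seed) give bit-identical forests.
#'
#' @param X numeric feature matrix or data.frame (no missing values).
#' @param y numeric response (age in weeks).
#' @param hp a [forest_hyperparams()].
#' @return object of class `ee_forest` wrapping the fitted engine; carries
#'   `oob_rmse`.
#' @export
fit_forest <- function(X, y, hp = forest_hyperparams()) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  if (anyNA(X) || anyNA(y)) stop("fit_forest requires complete data")
  p <- ncol(X)
  mtry <- hp$m_try %||% max(1, floor(p / 3))
  mtry <- min(max(1, mtry), p)
  args <- list(x = X, y = y, ntree = hp$n_trees, mtry = mtry,
               nodesize = hp$min_leaf, replace = hp$bootstrap,
               sampsize = nrow(X))
  if (!is.null(hp$max_nodes)) args$maxnodes <- hp$max_nodes
  # age ladders legitimately have few unique response values; keep the
  # engine's other warnings audible
  fit <- with_seed(hp$seed, withCallingHandlers(
    do.call(randomForest::randomForest, args),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  structure(list(engine = fit, hp = hp, features = colnames(X),
                 oob_rmse = sqrt(mean((fit$predicted - y)^2))),
            class = "ee_forest")
}

#' @export
predict.ee_forest <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stop(sprintf("schema error: missing feature(s) %s",
                 paste(miss, collapse = ", ")))
  as.numeric(predict(object$engine,
                     newdata = newdata[, object$features, drop = FALSE], ...))
}

#' IncNodePurity variable importance
#'
#' For every split on a feature, the decrease in node sum of squared
#' errors (parent SSE minus child SSEs, computed on in-bag samples),
#' totalled over all trees. Features never split on score 0.
#'
#' @param model an `ee_forest`.
#' @return data.frame (`feature`, `IncNodePurity`) sorted by decreasing
#'   importance; ties keep the canonical [feature_columns()] order, then
#'   input order.
#' @export
importance_incnodepurity <- function(model) {
  stopifnot(inherits(model, "ee_forest"))
  imp <- model$engine$importance[, "IncNodePurity"]
  feats <- model$features
  canon <- match(feats, feature_columns())
  canon[is.na(canon)] <- length(feature_columns()) + seq_len(sum(is.na(canon)))
  ord <- order(-imp, canon)
  data.frame(feature = feats[ord], IncNodePurity = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

.metrics <- function(obs, pred) {
  c(RMSE = sqrt(mean((obs - pred)^2)),
    MAE = mean(abs(obs - pred)),
    R2 = if (stats::var(obs) > 0)
      1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2) else NA_real_)
}

# Balanced fold labels for one CV repeat.
.make_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Train the sparse metabolic-age clock
#'
#' Two-stage construction on a feature table of untreated age-ladder
#' animals: (1) a comprehensive forest on all 14 predictors of the
#' training split ranks features by IncNodePurity; (2) the top `k`
#' features are refit as a sparse forest whose hyperparameters are chosen
#' by `repeats` x `folds` cross-validated RMSE on the training split, then
#' refit on the whole training split and evaluated once on the held-out
#' test split.
#'
#' @param table feature table from [build_feature_table()] (complete, with
#'   `age_weeks`).
#' @param k number of retained predictors (default 6).
#' @param repeats,folds cross-validation design (default 5 x 10; folds are
#'   reduced to the training size with a warning when larger).
#' @param hp_grid data.frame of candidate (`m_try`, `min_leaf`) pairs;
#'   default `m_try` 1..k crossed with `min_leaf` {2, 5}.
#' @param n_trees trees per forest (default 500).
#' @param train_frac training fraction of the initial split (default 0.7,
#'   stratified by age).
#' @param seed master seed; all tree and fold randomness derives from it.
#' @return object of class `ee_clock`: `full_model`, `importance`,
#'   `selected_features`, `sparse_model`, `cv_results`, `best_hp`,
#'   `split`, `test_metrics`, `seed`.
#' @export
train_sparse_clock <- function(table, k = 6, repeats = 5, folds = 10,
                               hp_grid = NULL, n_trees = 500,
                               train_frac = 0.7, seed = 1) {
  fc <- attr(table, "feature_cols") %||% intersect(feature_columns(),
                                                   colnames(table))
  if (k > length(fc))
    stop(sprintf("parameter error: k = %d exceeds %d available features",
                 k, length(fc)))
  if (anyNA(table[, fc])) stop("feature table must be complete")
  n <- nrow(table)
  y <- table$age_weeks
  sp <- split_cohort(n, train_frac, stratify_by = y, seed = mix_seed(seed, 1))
  Xtr <- table[sp$train, fc, drop = FALSE]
  ytr <- y[sp$train]

  full <- fit_forest(Xtr, ytr,
                     forest_hyperparams(n_trees = n_trees,
                                        seed = mix_seed(seed, 2)))
  imp <- importance_incnodepurity(full)
  sel <- imp$feature[seq_len(k)]

  if (is.null(hp_grid))
    hp_grid <- expand.grid(m_try = seq_len(k), min_leaf = c(2, 5))
  n_tr <- length(sp$train)
  eff_folds <- folds
  if (folds > n_tr) {
    warning(sprintf("folds reduced from %d to training size %d", folds, n_tr))
    eff_folds <- n_tr
  }
  if (n_tr / eff_folds < 2)
    warning(sprintf("cross-validation folds of size %d-%d",
                    floor(n_tr / eff_folds), ceiling(n_tr / eff_folds)))

  cv <- list()
  for (r in seq_len(repeats)) {
    fold_id <- .make_folds(n_tr, eff_folds, mix_seed(seed, 100 + r))
    for (g in seq_len(nrow(hp_grid))) {
      pred <- rep(NA_real_, n_tr)
      for (f in seq_len(eff_folds)) {
        hold <- which(fold_id == f)
        if (length(hold) == 0 || length(hold) == n_tr) next
        m <- fit_forest(
          Xtr[-hold, sel, drop = FALSE], ytr[-hold],
          forest_hyperparams(n_trees = n_trees,
                             m_try = hp_grid$m_try[g],
                             min_leaf = hp_grid$min_leaf[g],
                             seed = mix_seed(seed, 1000 + r * 100 + f,
                                             g)))
        pred[hold] <- predict(m, Xtr[hold, sel, drop = FALSE])
      }
      mm <- .metrics(ytr[!is.na(pred)], pred[!is.na(pred)])
      cv[[length(cv) + 1]] <- data.frame(
        repeat_ = r, m_try = hp_grid$m_try[g],
        min_leaf = hp_grid$min_leaf[g],
        RMSE = mm[["RMSE"]], MAE = mm[["MAE"]], R2 = mm[["R2"]])
    }
  }
  cv <- do.call(rbind, cv)
  agg <- stats::aggregate(cv[, c("RMSE", "MAE", "R2")],
                          by = cv[, c("m_try", "min_leaf")], FUN = mean)
  agg <- agg[order(agg$RMSE, agg$m_try, agg$min_leaf), ]
  best <- agg[1, ]

  sparse <- fit_forest(
    Xtr[, sel, drop = FALSE], ytr,
    forest_hyperparams(n_trees = n_trees, m_try = best$m_try,
                       min_leaf = best$min_leaf,
                       seed = mix_seed(seed, 3)))
  test_pred <- predict(sparse, table[sp$test, sel, drop = FALSE])
  structure(list(full_model = full, importance = imp,
                 selected_features = sel, sparse_model = sparse,
                 cv_results = cv, cv_summary = agg,
                 best_hp = list(m_try = best$m_try,
                                min_leaf = best$min_leaf,
                                n_trees = n_trees),
                 split = sp,
                 test_metrics = .metrics(y[sp$test], test_pred),
                 cv_rmse = best$RMSE,
                 seed = seed),
            class = "ee_clock")
}

#' @export
print.ee_clock <- function(x, ...) {
  cat(sprintf(
    "<ee_clock> sparse forest on %d features: %s\n  CV RMSE %.2f wk; test RMSE %.2f, MAE %.2f, R2 %.3f (train %d / test %d)\n",
    length(x$selected_features),
    paste(x$selected_features, collapse = ", "),
    x$cv_rmse, x$test_metrics[["RMSE"]], x$test_metrics[["MAE"]],
    x$test_metrics[["R2"]], length(x$split$train), length(x$split$test)))
  invisible(x)
}

#' Predict metabolic (EE) age
#'
#' Applies the sparse clock to a feature table and summarizes by group.
#'
#' @param clock an `ee_clock`.
#' @param table feature table containing the clock's selected features and
#'   `group` / `animal_id` columns.
#' @return list of class `ee_age_prediction`: `per_animal` (data.frame
#'   with `ee_age_weeks`), `group_summary` (`group`, `n`, `mean`, `sd`),
#'   `deltas` (pairwise mean differences, `group_a` minus `group_b`).
#' @export
predict_ee_age <- function(clock, table) {
  stopifnot(inherits(clock, "ee_clock"))
  if (nrow(as.data.frame(table)) == 0)
    stop("schema error: empty feature table")
  miss <- setdiff(clock$selected_features, colnames(table))
  if (length(miss))
    stop(sprintf("schema error: missing selected feature(s) %s",
                 paste(miss, collapse = ", ")))
  pred <- predict(clock$sparse_model,
                  table[, clock$selected_features, drop = FALSE])
  per <- data.frame(
    animal_id = table$animal_id %||% paste0("animal_", seq_along(pred)),
    group = table$group %||% "all",
    age_weeks = table$age_weeks %||% NA_real_,
    ee_age_weeks = pred, stringsAsFactors = FALSE)
  gs <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), mean = mean(d$ee_age_weeks),
               sd = stats::sd(d$ee_age_weeks), stringsAsFactors = FALSE)))
  rownames(gs) <- NULL
  groups <- gs$group
  deltas <- NULL
  if (length(groups) > 1) {
    cmb <- utils::combn(seq_along(groups), 2)
    deltas <- data.frame(
      group_a = groups[cmb[1, ]], group_b = groups[cmb[2, ]],
      delta = gs$mean[cmb[1, ]] - gs$mean[cmb[2, ]],
      stringsAsFactors = FALSE)
  }
  structure(list(per_animal = per, group_summary = gs, deltas = deltas),
            class = "ee_age_prediction")
}

#' @export
print.ee_age_prediction <- function(x, ...) {
  cat("<ee_age_prediction>\n")
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}
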