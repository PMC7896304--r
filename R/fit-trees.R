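#' Random forest family
#'
#' Probability forests with `mtry` searched over 1..3 and the tree count
#' grown from 1,000 in steps of 500 until the relative gain in mean held-out
#' AUC from the last step falls below 1%; the final count is the last tested
#' one (1,500 when the very first increment already gains < 1%). The
#' `(mtry, n_trees)` pair with the highest mean held-out AUC is kept and its
#' per-fold forests become the final fits.
#'
#' Tree counts are evaluated without refitting: a forest is an average over
#' exchangeable trees, so the prediction of a k-tree forest equals the mean
#' of the first k per-tree predictions of a larger forest grown with the
#' same seed. Forests are grown to the current evaluation cap and extended
#' by further 500-tree forests only if the stopping rule keeps passing.
#'
#' @inheritParams fit_glm_poly
#' @param mtry_grid Candidate numbers of variables per split.
#' @param n_trees_init,n_trees_step Initial tree count and increment.
#' @param gain_tol Relative mean-AUC gain below which growth stops.
#' @param max_steps Safety cap on increments.
#' @param seed Integer seed (per-fold fit seeds derive from it).
#' @return A fits tibble, one row per fold (family `"random_forest"`), with
#'   the search summary in attribute `"search"`.
#' @export
fit_random_forest <- function(occ, predictors = default_predictors(),
                              mtry_grid = 1:3, n_trees_init = 1000,
                              n_trees_step = 500, gain_tol = 0.01,
                              max_steps = 8, seed = 1) {
  check_predictors(occ, predictors)
  y <- as_binary_label(occ$label)
  folds <- cv_folds(occ)
  X <- as.matrix(occ[predictors])

  search <- list()
  per_mtry <- list()
  for (m in mtry_grid) {
    # grow per-fold forests to the first cap (init + one step)
    cap <- n_trees_init + n_trees_step
    forests <- lapply(folds, function(fold) {
      if (!fold$train_ok) return(NULL)
      ranger::ranger(
        x = X[fold$train, , drop = FALSE],
        y = factor(y[fold$train], levels = 0:1),
        num.trees = cap, mtry = m, probability = TRUE,
        num.threads = 1,
        seed = stage_seed(seed, paste0("rf", m, "b", fold$block))
      )
    })
    # per-tree held-out predictions allow AUC at any tree count <= cap
    tree_preds <- lapply(seq_along(folds), function(i) {
      if (is.null(forests[[i]]) || !folds[[i]]$test_ok) return(NULL)
      p <- predict(forests[[i]], X[folds[[i]]$test, , drop = FALSE],
        predict.all = TRUE, num.threads = 1
      )$predictions
      matrix(p[, 2, ], nrow = dim(p)[1]) # prob of class "1", rows x trees
    })
    auc_at <- function(k) {
      aucs <- vapply(seq_along(folds), function(i) {
        tp <- tree_preds[[i]]
        if (is.null(tp)) return(NA_real_)
        evaluate_auc(rowMeans(tp[, seq_len(k), drop = FALSE]),
          y[folds[[i]]$test])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }
    n_cur <- n_trees_init
    auc_cur <- auc_at(n_cur)
    steps <- 0L
    repeat {
      n_next <- n_cur + n_trees_step
      if (n_next > cap) {
        # extend: grow additional step-sized forests and append predictions
        extra <- lapply(seq_along(folds), function(i) {
          fold <- folds[[i]]
          if (is.null(tree_preds[[i]])) return(NULL)
          r2 <- ranger::ranger(
            x = X[fold$train, , drop = FALSE],
            y = factor(y[fold$train], levels = 0:1),
            num.trees = n_trees_step, mtry = m, probability = TRUE,
            num.threads = 1,
            seed = stage_seed(seed, paste0("rf", m, "b", fold$block, "x", n_next))
          )
          p2 <- predict(r2, X[fold$test, , drop = FALSE],
            predict.all = TRUE, num.threads = 1
          )$predictions
          matrix(p2[, 2, ], nrow = dim(p2)[1])
        })
        tree_preds <- lapply(seq_along(folds), function(i) {
          if (is.null(tree_preds[[i]])) return(NULL)
          cbind(tree_preds[[i]], extra[[i]])
        })
        # stored forests stay at their original cap; when the gain rule
        # keeps firing the final fits are regrown at n_final below
        cap <- n_next
      }
      auc_next <- auc_at(n_next)
      gain <- (auc_next - auc_cur) / auc_cur
      steps <- steps + 1L
      n_cur <- n_next
      auc_cur <- auc_next
      if (gain < gain_tol || steps >= max_steps) break
    }
    search[[length(search) + 1]] <- tibble(
      mtry = m, n_trees = n_cur, mean_auc = auc_cur
    )
    per_mtry[[as.character(m)]] <- list(
      forests = forests, n_trees = n_cur, mean_auc = auc_cur
    )
  }
  search <- bind_rows(search)
  best <- per_mtry[[as.character(search$mtry[which.max(search$mean_auc)])]]
  best_mtry <- search$mtry[which.max(search$mean_auc)]

  fits <- bind_rows(lapply(seq_along(folds), function(i) {
    fold <- folds[[i]]
    hyper <- list(mtry = best_mtry, n_trees = best$n_trees)
    forest <- best$forests[[i]]
    if (is.null(forest)) {
      return(new_fit_row(
        occ$species_id[1], "random_forest", fold$block, hyper, NULL,
        NA_real_, NA_real_, length(fold$train)
      ))
    }
    if (forest$num.trees < best$n_trees) {
      # regrow at the selected count (only after multiple increments)
      forest <- ranger::ranger(
        x = X[fold$train, , drop = FALSE],
        y = factor(y[fold$train], levels = 0:1),
        num.trees = best$n_trees, mtry = best_mtry, probability = TRUE,
        num.threads = 1,
        seed = stage_seed(seed, paste0("rff", best_mtry, "b", fold$block))
      )
    }
    model <- list(
      forest = forest, n_trees = best$n_trees, predictors = predictors
    )
    scores <- predict_rf_truncated(model, occ[fold$test, ])
    m <- heldout_metrics(scores, y[fold$test])
    new_fit_row(
      occ$species_id[1], "random_forest", fold$block, hyper, model,
      m$auc, m$threshold, length(fold$train)
    )
  }))
  attr(fits, "search") <- search
  fits
}

predict_rf_truncated <- function(model, newdata) {
  X <- as.matrix(newdata[model$predictors])
  if (model$n_trees >= model$forest$num.trees) {
    p <- predict(model$forest, X, num.threads = 1)$predictions
    return(as.numeric(p[, 2]))
  }
  p <- predict(model$forest, X,
    predict.all = TRUE, num.threads = 1
  )$predictions
  p <- matrix(p[, 2, ], nrow = dim(p)[1])
  rowMeans(p[, seq_len(model$n_trees), drop = FALSE])
}

#' Boosted regression tree family
#'
#' Gradient-boosted trees with the classical slow-learning configuration:
#' shrinkage (learning rate) 0.001 and 5,000 trees, with tree complexity
#' (interaction depth) searched over 1..4. The complexity minimising the
#' summed held-out binomial deviance across the testing blocks is selected,
#' and its per-fold boosters become the final fits.
#'
#' @inheritParams fit_random_forest
#' @param shrinkage Learning rate.
#' @param n_trees Number of boosting rounds.
#' @param complexity_grid Candidate interaction depths.
#' @param max_bin Histogram bins of the tree grower.
#' @return A fits tibble, one row per fold (family `"boosted_trees"`), with
#'   the complexity search in attribute `"search"`.
#' @export
fit_boosted_trees <- function(occ, predictors = default_predictors(),
                              shrinkage = 0.001, n_trees = 5000,
                              complexity_grid = 1:4, seed = 1,
                              max_bin = 64) {
  check_predictors(occ, predictors)
  y <- as_binary_label(occ$label)
  folds <- cv_folds(occ)
  X <- as.matrix(occ[predictors])

  search <- list()
  per_depth <- list()
  for (d in complexity_grid) {
    boosters <- vector("list", length(folds))
    dev_sum <- 0
    any_ok <- FALSE
    for (i in seq_along(folds)) {
      fold <- folds[[i]]
      if (!fold$train_ok) next
      dtrain <- xgboost::xgb.DMatrix(
        X[fold$train, , drop = FALSE],
        label = y[fold$train], nthread = 1
      )
      booster <- xgboost::xgb.train(
        params = list(
          eta = shrinkage, max_depth = d, objective = "binary:logistic",
          nthread = 1, tree_method = "hist", max_bin = max_bin,
          seed = stage_seed(seed, paste0("brt", d, "b", fold$block))
        ),
        data = dtrain, nrounds = n_trees, verbose = 0
      )
      boosters[[i]] <- booster
      p <- as.numeric(predict(booster, xgboost::xgb.DMatrix(
        X[fold$test, , drop = FALSE],
        nthread = 1
      )))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      yt <- y[fold$test]
      dev_sum <- dev_sum - 2 * sum(yt * log(p) + (1 - yt) * log(1 - p))
      any_ok <- TRUE
    }
    if (!any_ok) dev_sum <- Inf
    search[[length(search) + 1]] <- tibble(
      complexity = d, summed_deviance = dev_sum
    )
    per_depth[[as.character(d)]] <- boosters
  }
  search <- bind_rows(search)
  best_d <- search$complexity[which.min(search$summed_deviance)]
  boosters <- per_depth[[as.character(best_d)]]

  fits <- bind_rows(lapply(seq_along(folds), function(i) {
    fold <- folds[[i]]
    hyper <- list(
      shrinkage = shrinkage, n_trees = n_trees, complexity = best_d
    )
    if (is.null(boosters[[i]])) {
      return(new_fit_row(
        occ$species_id[1], "boosted_trees", fold$block, hyper, NULL,
        NA_real_, NA_real_, length(fold$train)
      ))
    }
    model <- list(booster = boosters[[i]], predictors = predictors)
    scores <- predict_fit(
      tibble(family = "boosted_trees", model = list(model)),
      occ[fold$test, ]
    )
    m <- heldout_metrics(scores, y[fold$test])
    new_fit_row(
      occ$species_id[1], "boosted_trees", fold$block, hyper, model,
      m$auc, m$threshold, length(fold$train)
    )
  }))
  attr(fits, "search") <- search
  fits
}
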