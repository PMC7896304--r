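test_that("the polynomial search space has 3^p formulations", {
  occ1 <- toy_occurrence(n = 150, n_vars = 1, seed = 5,
    signal = function(X) 1.5 * X[, 1])
  f1 <- fit_glm_poly(occ1, predictors = "v1")
  expect_equal(nrow(attr(f1, "search")), 3)
  expect_equal(nrow(f1), 6) # one fit per block
  occ3 <- toy_occurrence(n = 200, n_vars = 3, seed = 6)
  f3 <- fit_glm_poly(occ3, predictors = c("v1", "v2", "v3"))
  expect_equal(nrow(attr(f3, "search")), 27)
})

test_that("quadratic truth drives the selected polynomial degree", {
  hits <- vapply(1:8, function(i) {
    occ <- toy_occurrence(
      n = 240, n_vars = 3, seed = 400 + i,
      signal = function(X) 2 - 3 * X[, 1]^2
    )
    fits <- fit_glm_poly(occ, predictors = c("v1", "v2", "v3"))
    fits$hyper[[1]]$degrees[["v1"]] >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("final polynomial fits carry held-out metrics per block", {
  occ <- toy_occurrence(n = 200, n_vars = 2, seed = 9,
    signal = function(X) 2 * X[, 1] + X[, 2])
  fits <- fit_glm_poly(occ, predictors = c("v1", "v2"))
  expect_equal(fits$block, sort(unique(occ$block)))
  expect_true(all(fits$auc >= 0 & fits$auc <= 1, na.rm = TRUE))
  expect_true(all(is.finite(fits$threshold[!is.na(fits$threshold)])))
  # prediction path reproduces probabilities in [0, 1]
  p <- predict_fit(fits[1, ], occ)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("spline fits separate linearly separable data perfectly", {
  occ <- toy_occurrence_sep(n = 200, n_vars = 1, seed = 3,
    rule = function(X) X[, 1] > 0.2)
  fits <- fit_gam_spline(occ, predictors = "v1")
  expect_true(all(fits$auc == 1))
})

test_that("label-shuffled data yields chance-level spline AUC", {
  set.seed(31)
  aucs <- vapply(1:4, function(i) {
    occ <- toy_occurrence(n = 300, n_vars = 2, seed = 500 + i,
      signal = function(X) 2 * X[, 1])
    occ$label <- sample(occ$label) # break the signal
    fits <- fit_gam_spline(occ, predictors = c("v1", "v2"))
    mean(fits$auc, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.1))
})

test_that("monotone truth produces a monotone fitted partial response", {
  hits <- vapply(1:6, function(i) {
    occ <- toy_occurrence(n = 250, n_vars = 2, seed = 600 + i,
      signal = function(X) 2.5 * X[, 1])
    fits <- fit_gam_spline(occ, predictors = c("v1", "v2"))
    grid <- tibble::tibble(
      v1 = seq(quantile(occ$v1, 0.05), quantile(occ$v1, 0.95), length = 41),
      v2 = stats::median(occ$v2)
    )
    p <- predict_fit(fits[1, ], grid)
    all(diff(p) > -1e-8)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("random forest searches mtry 1..3 and stops at 1500 trees", {
  occ <- toy_occurrence_sep(n = 220, n_vars = 3, n_blocks = 6, seed = 12,
    rule = function(X) X[, 1] + X[, 2] > 0)
  fits <- fit_random_forest(occ, predictors = c("v1", "v2", "v3"), seed = 2)
  search <- attr(fits, "search")
  expect_equal(nrow(search), 3)
  expect_setequal(search$mtry, 1:3)
  # strong signal: the first 500-tree increment cannot gain 1%, so the
  # final count is the last tested one
  expect_equal(fits$hyper[[1]]$n_trees, 1500)
  expect_true(all(fits$auc > 0.9, na.rm = TRUE))
})

test_that("noise-only predictors cap random-forest skill near chance", {
  occ <- toy_occurrence(n = 500, n_vars = 3, n_blocks = 10, seed = 77,
    signal = function(X) rep(0, nrow(X)))
  fits <- fit_random_forest(occ, predictors = c("v1", "v2", "v3"), seed = 5)
  expect_lte(mean(fits$auc, na.rm = TRUE), 0.6)
})

test_that("truncated-forest predictions equal a smaller forest's average", {
  occ <- toy_occurrence_sep(n = 150, n_vars = 2, n_blocks = 5, seed = 8)
  X <- as.matrix(occ[c("v1", "v2")])
  y <- factor(as.integer(occ$label == "presence"), levels = 0:1)
  r <- ranger::ranger(
    x = X, y = y, num.trees = 300, mtry = 1, probability = TRUE,
    num.threads = 1, seed = 4
  )
  model <- list(forest = r, n_trees = 200, predictors = c("v1", "v2"))
  trunc <- borderniche:::predict_rf_truncated(model, occ)
  pa <- predict(r, X, predict.all = TRUE, num.threads = 1)$predictions[, 2, ]
  expect_equal(trunc, rowMeans(pa[, 1:200]))
})

test_that("boosted trees evaluate each complexity once per fold", {
  occ <- toy_occurrence_sep(n = 160, n_vars = 2, n_blocks = 4, seed = 14,
    rule = function(X) X[, 1] > 0)
  fits <- fit_boosted_trees(occ, predictors = c("v1", "v2"), seed = 3)
  search <- attr(fits, "search")
  expect_equal(search$complexity, 1:4)
  expect_equal(nrow(search), 4)
  h <- fits$hyper[[1]]
  expect_equal(h$shrinkage, 0.001)
  expect_equal(h$n_trees, 5000)
  expect_true(h$complexity %in% 1:4)
})

test_that("additive truth favours low boosted-tree complexity", {
  picks <- vapply(1:5, function(i) {
    occ <- toy_occurrence(n = 220, n_vars = 2, n_blocks = 5, seed = 700 + i,
      signal = function(X) 1.8 * X[, 1] - 1.2 * X[, 2])
    fits <- fit_boosted_trees(occ, predictors = c("v1", "v2"), seed = i)
    fits$hyper[[1]]$complexity
  }, numeric(1))
  expect_gte(mean(picks <= 2), 0.7)
})

test_that("single-class folds are flagged and the rest proceed", {
  occ <- toy_occurrence(n = 160, n_vars = 2, n_blocks = 4, seed = 21,
    signal = function(X) X[, 1])
  occ$label[occ$block == 2] <- "pseudoabsence" # block 2 held out: one class
  fits <- fit_gam_spline(occ, predictors = c("v1", "v2"))
  expect_true(is.na(fits$auc[fits$block == 2]))
  expect_true(all(!is.na(fits$auc[fits$block != 2])))
})
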