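# Shared fold machinery for the leave-one-block-out model families.

# List of folds: for each block id present in the table, the train/test row
# indices. Blocks whose training remainder is single-class are unusable and
# flagged; AUC/threshold on a single-class held-out block come out NA.
cv_folds <- function(occ) {
  if (anyNA(occ$block)) abort("Occurrence table has unlabelled blocks.")
  blocks <- sort(unique(occ$block))
  y <- as_binary_label(occ$label)
  lapply(blocks, function(b) {
    test <- which(occ$block == b)
    train <- which(occ$block != b)
    list(
      block = b, train = train, test = test,
      train_ok = length(unique(y[train])) == 2,
      test_ok = length(unique(y[test])) == 2
    )
  })
}

check_predictors <- function(occ, predictors) {
  missing <- setdiff(predictors, names(occ))
  if (length(missing) > 0) {
    abort(paste(
      "Occurrence table lacks predictor columns:",
      paste(missing, collapse = ", ")
    ))
  }
}

new_fit_row <- function(species_id, family, block, hyper, model,
                        auc, threshold, n_train) {
  tibble(
    species_id = species_id, family = family, block = block,
    hyper = list(hyper), model = list(model),
    auc = auc, threshold = threshold, n_train = n_train
  )
}

# Held-out AUC/threshold, NA-safe for single-class test blocks.
heldout_metrics <- function(scores, y_test) {
  if (length(unique(y_test)) < 2 || any(!is.finite(scores))) {
    return(list(auc = NA_real_, threshold = NA_real_))
  }
  list(
    auc = evaluate_auc(scores, y_test),
    threshold = select_threshold(scores, y_test)
  )
}

#' Predict occupancy scores from one fitted ensemble member
#'
#' Dispatches on the model family to score new cells (probability scale).
#'
#' @param fit_row One row of a fits tibble.
#' @param newdata Tibble with the predictor columns.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_fit <- function(fit_row, newdata) {
  model <- fit_row$model[[1]]
  switch(fit_row$family,
    glm_poly = predict_glm_poly(model, newdata),
    gam_spline = as.numeric(predict(
      model, newdata = as.data.frame(newdata), type = "response"
    )),
    random_forest = predict_rf_truncated(model, newdata),
    boosted_trees = {
      X <- as.matrix(newdata[model$predictors])
      as.numeric(predict(model$booster, xgboost::xgb.DMatrix(
        X,
        nthread = 1
      )))
    },
    abort(paste("Unknown model family:", fit_row$family))
  )
}
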