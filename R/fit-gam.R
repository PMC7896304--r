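#' Penalised thin-plate spline family
#'
#' Additive logistic model with a roughness-penalised thin-plate regression
#' spline per predictor (Bernoulli response, logit link); smoothing
#' parameters are chosen by the engine's internal criterion (fast REML).
#' One fit per left-out block; a failed smoother flags its fold (NA metrics)
#' and the ensemble proceeds without it.
#'
#' @inheritParams fit_glm_poly
#' @param k Spline basis size per smooth.
#' @return A fits tibble, one row per fold (family `"gam_spline"`).
#' @export
fit_gam_spline <- function(occ, predictors = default_predictors(), k = 10) {
  check_predictors(occ, predictors)
  y <- as_binary_label(occ$label)
  folds <- cv_folds(occ)
  dat <- occ |> mutate(.y = y)
  rhs <- paste(sprintf("s(%s, k = %d)", predictors, k), collapse = " + ")
  f <- as.formula(paste(".y ~", rhs))
  bind_rows(lapply(folds, function(fold) {
    model <- NULL
    if (fold$train_ok) {
      model <- tryCatch(
        suppressWarnings(mgcv::bam(
          f,
          family = binomial(), data = dat[fold$train, ],
          discrete = TRUE
        )),
        error = function(e) NULL
      )
    }
    if (is.null(model)) {
      return(new_fit_row(
        occ$species_id[1], "gam_spline", fold$block, list(k = k),
        NULL, NA_real_, NA_real_, length(fold$train)
      ))
    }
    scores <- as.numeric(predict(
      model,
      newdata = dat[fold$test, ], type = "response"
    ))
    m <- heldout_metrics(scores, y[fold$test])
    new_fit_row(
      occ$species_id[1], "gam_spline", fold$block, list(k = k),
      model, m$auc, m$threshold, length(fold$train)
    )
  }))
}
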