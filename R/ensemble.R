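#' Fit the four-family ensemble for one species
#'
#' Runs the polynomial GLM, thin-plate spline, random forest and boosted
#' tree families on a block-labelled occurrence table; with ten blocks this
#' yields 40 fits per species (10 blocks x 4 families), each carrying its
#' held-out AUC weight and occupancy threshold.
#'
#' @param occ A block-labelled occurrence tibble.
#' @param predictors Predictor variables.
#' @param seed Integer seed for the stochastic families.
#' @param families Which families to fit.
#' @param ... Passed through to the family fitters.
#' @return A fits tibble (rows = blocks x families).
#' @export
fit_species_ensemble <- function(occ, predictors = default_predictors(),
                                 seed = 1,
                                 families = c(
                                   "glm_poly", "gam_spline",
                                   "random_forest", "boosted_trees"
                                 ),
                                 ...) {
  out <- list()
  if ("glm_poly" %in% families) {
    out$glm <- fit_glm_poly(occ, predictors)
  }
  if ("gam_spline" %in% families) {
    out$gam <- fit_gam_spline(occ, predictors)
  }
  if ("random_forest" %in% families) {
    out$rf <- fit_random_forest(occ, predictors, seed = seed)
  }
  if ("boosted_trees" %in% families) {
    out$brt <- fit_boosted_trees(occ, predictors, seed = seed)
  }
  bind_rows(out)
}

#' Projection domain of a species
#'
#' The cells of the zoogeographic realms the species occupies plus their
#' adjacent realms — the region across which its climatic niche is
#' projected.
#'
#' @param species_row One row of a `species_table`.
#' @param regions Output of [gen_regions()].
#' @param grid A [grid_spec()].
#' @return Integer vector of domain cell ids.
#' @export
projection_domain <- function(species_row, regions, grid) {
  map <- regions$map
  occ_realms <- unique(map$realm[match(species_row$presence[[1]], map$cell)])
  radj <- realm_adjacency(grid, map)
  nb <- c(
    radj$realm_b[radj$realm_a %in% occ_realms],
    radj$realm_a[radj$realm_b %in% occ_realms]
  )
  sort(map$cell[map$realm %in% union(occ_realms, nb)])
}

#' AUC-weighted ensemble projection
#'
#' Every usable model scores every domain cell under every supplied climate
#' slice (one slice for the current epoch; one per GCM for a future
#' scenario) and is binarised at its own sensitivity+specificity threshold.
#' The ensemble occupancy fraction of a cell is the AUC-weighted mean of
#' these binary values — better-discriminating models count for more — and
#' the ensemble binary map is `fraction >= 0.5`. Models with missing AUC or
#' threshold (failed folds) are dropped and the weights renormalised over
#' the survivors; fewer than `min_projections` surviving model x slice
#' projections flags the result unreliable.
#'
#' @param fits A fits tibble from [fit_species_ensemble()].
#' @param climate_slices A single climate slice tibble, or a list of slices
#'   (e.g. the three GCM slices of one future scenario).
#' @param domain_cells Integer cell ids to project over.
#' @param min_projections Reliability floor on surviving projections.
#' @return An `ensemble_projection` tibble: `cell`, `row`, `col`,
#'   `fraction`, `binary`, with attributes `n_projections`, `n_models`,
#'   `unreliable`.
#' @export
ensemble_project <- function(fits, climate_slices, domain_cells,
                             min_projections = 20) {
  if (is.data.frame(climate_slices)) climate_slices <- list(climate_slices)
  ok <- !is.na(fits$auc) & !is.na(fits$threshold) &
    !map_lgl(fits$model, is.null)
  usable <- fits[ok, ]
  if (nrow(usable) == 0) abort("No usable model fits to ensemble.")

  num <- NULL
  wsum <- 0
  n_proj <- 0L
  for (slice in climate_slices) {
    newdata <- slice[match(domain_cells, slice$cell), ]
    if (anyNA(newdata$cell)) {
      abort("Some domain cells are missing from a climate slice.")
    }
    for (i in seq_len(nrow(usable))) {
      scores <- predict_fit(usable[i, ], newdata)
      b <- as.numeric(scores >= usable$threshold[i])
      w <- usable$auc[i]
      num <- if (is.null(num)) w * b else num + w * b
      wsum <- wsum + w
      n_proj <- n_proj + 1L
    }
  }
  fraction <- num / wsum
  cells <- climate_slices[[1]][match(domain_cells, climate_slices[[1]]$cell), ]
  out <- tibble(
    cell = domain_cells, row = cells$row, col = cells$col,
    fraction = fraction, binary = fraction >= 0.5
  )
  attr(out, "n_projections") <- n_proj
  attr(out, "n_models") <- nrow(usable)
  attr(out, "unreliable") <- n_proj < min_projections
  class(out) <- c("ensemble_projection", class(out))
  out
}
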