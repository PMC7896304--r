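#' Species richness map from binary projections
#'
#' Per-cell count of species whose binary map marks the cell occupied.
#' Cells never projected by any selected species get richness 0.
#'
#' @param projections Named list (by species id) of `ensemble_projection`
#'   tibbles (or any tibble with `cell` and `binary`).
#' @param grid A [grid_spec()].
#' @param species_ids Optional subset of names to include.
#' @return Tibble `cell`, `row`, `col`, `richness`.
#' @export
richness_map <- function(projections, grid, species_ids = NULL) {
  cells <- grid_cells(grid)
  counts <- integer(n_cells(grid))
  use <- if (is.null(species_ids)) names(projections) else species_ids
  for (sp in use) {
    pr <- projections[[sp]]
    if (is.null(pr)) next
    occ <- pr$cell[pr$binary]
    counts[occ] <- counts[occ] + 1L
  }
  cells |> mutate(richness = counts[.data$cell]) |> select(-"lat")
}

#' Per-cell percentage richness change
#'
#' `100 * (future - current) / current`; cells with zero current richness
#' have undefined change (`NA`) and are excluded downstream.
#'
#' @param current,future Richness tibbles on the same grid.
#' @return Tibble `cell`, `row`, `col`, `current`, `future`, `pct_change`.
#' @export
percent_change_map <- function(current, future) {
  if (!identical(current$cell, future$cell)) {
    abort("Current and future richness maps cover different cells.")
  }
  tibble(
    cell = current$cell, row = current$row, col = current$col,
    current = current$richness, future = future$richness
  ) |>
    mutate(pct_change = if_else(
      .data$current > 0,
      100 * (.data$future - .data$current) / .data$current,
      NA_real_
    ))
}

#' National mean richness change
#'
#' Unweighted mean percentage change over each country's cells with defined
#' change; countries with no defined cell are dropped with a message.
#'
#' @param change Output of [percent_change_map()].
#' @param regions Output of [gen_regions()].
#' @return Tibble `country`, `mean_pct_change`, `n_cells`.
#' @export
national_mean_change <- function(change, regions) {
  joined <- change |>
    inner_join(regions$map |> select("cell", "country"), by = "cell") |>
    filter(!is.na(.data$pct_change))
  dropped <- setdiff(unique(regions$map$country), unique(joined$country))
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d countr%s with no defined richness-change cells omitted.",
      length(dropped), if (length(dropped) == 1) "y" else "ies"
    ))
  }
  joined |>
    group_by(country = .data$country) |>
    summarise(
      mean_pct_change = mean(.data$pct_change),
      n_cells = dplyr::n(), .groups = "drop"
    )
}

#' Regress national richness change on a socioeconomic covariate
#'
#' Gaussian-family univariate linear model of mean percentage richness
#' change on one national covariate: the governance score, log per-capita
#' GDP, or log per-capita CO2 emissions (monetary and emissions covariates
#' are natural-log transformed for their heavy right skew).
#'
#' @param change_table Output of [national_mean_change()].
#' @param covariates A covariate table from [gen_covariates()].
#' @param covariate One of `"governance"`, `"gdp"`, `"co2"`.
#' @param min_countries Fewest countries accepted.
#' @return A `covariate_fit` object (supports [tidy()], [glance()],
#'   `autoplot()`).
#' @export
fit_covariate_model <- function(change_table, covariates,
                                covariate = c("governance", "gdp", "co2"),
                                min_countries = 10) {
  covariate <- match.arg(covariate)
  dat <- change_table |>
    inner_join(covariates, by = "country") |>
    mutate(x = switch(covariate,
      governance = .data$governance,
      gdp = log(.data$gdp_per_capita),
      co2 = log(.data$co2_per_capita)
    ))
  if (nrow(dat) < min_countries) {
    abort(sprintf(
      "Only %d countries available; need at least %d.",
      nrow(dat), min_countries
    ))
  }
  fit <- glm(mean_pct_change ~ x, family = gaussian(), data = dat)
  structure(
    list(
      fit = fit, covariate = covariate, data = dat,
      n_countries = nrow(dat)
    ),
    class = "covariate_fit"
  )
}

#' @export
print.covariate_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  cat(sprintf(
    "<covariate_fit> mean %% richness change ~ %s over %d countries\n",
    x$covariate, x$n_countries
  ))
  cat(sprintf(
    "  slope %.4g (SE %.3g, p = %.3g)\n", cf[2, 1], cf[2, 2], cf[2, 4]
  ))
  invisible(x)
}

#' Tidy a national covariate model
#'
#' @param x A `covariate_fit`.
#' @param conf.level Confidence level of the slope interval.
#' @param ... Unused.
#' @return One tibble row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`, `covariate`.
#' @exportS3Method generics::tidy
tidy.covariate_fit <- function(x, conf.level = 0.95, ...) {
  cf <- summary(x$fit)$coefficients
  ci <- stats::confint.default(x$fit, level = conf.level) # Wald interval
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]), std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]), p.value = unname(cf[, 4]),
    conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]),
    covariate = x$covariate
  )
}

#' Model-level summary of a national covariate model
#'
#' @param x A `covariate_fit`.
#' @param ... Unused.
#' @return One-row tibble: `covariate`, `n_countries`, `slope`, `p.value`,
#'   `r.squared`, `aic`.
#' @exportS3Method generics::glance
glance.covariate_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  r2 <- 1 - x$fit$deviance / x$fit$null.deviance
  tibble(
    covariate = x$covariate, n_countries = x$n_countries,
    slope = cf[2, 1], p.value = cf[2, 4],
    r.squared = r2, aic = AIC(x$fit)
  )
}
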