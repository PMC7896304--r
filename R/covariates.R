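#' Generate national socioeconomic covariates
#'
#' Each country gets six governance indicators (standardized scores clamped
#' to `[-2.5, 2.5]`), per-capita GDP and per-capita CO2 emissions. A built-in
#' latitude gradient of strength `gradient_strength` links all three to the
#' country's mean latitude (higher-latitude countries scoring higher),
#' emulating the real-world pattern that low-latitude countries tend to rank
#' lower for governance, GDP and emissions. With `gradient_strength = 0` the
#' covariates are pure noise.
#'
#' @param regions Output of [gen_regions()].
#' @param seed Integer seed.
#' @param gradient_strength Non-negative strength of the latitude link
#'   (1 gives a strong, clearly recoverable gradient).
#' @param noise_sd Indicator noise standard deviation.
#' @return A tibble: `country`, `mean_lat`, `gov1..gov6`, `governance`
#'   (mean of the six), `gdp_per_capita`, `co2_per_capita`.
#' @export
gen_covariates <- function(regions, seed, gradient_strength = 1,
                           noise_sd = 0.4) {
  if (gradient_strength < 0) abort("`gradient_strength` must be >= 0.")
  set.seed(seed)
  map <- regions$map
  countries <- map |>
    group_by(country = .data$country) |>
    summarise(mean_lat = mean(.data$lat), .groups = "drop")
  # latitude standardized to roughly [-1, 1] about the grid midline
  z <- (countries$mean_lat - mean(range(map$lat))) / (diff(range(map$lat)) / 2)
  if (!is.finite(z[1]) || diff(range(map$lat)) == 0) z <- rep(0, nrow(countries))
  n <- nrow(countries)
  gov <- sapply(1:6, function(j) {
    pmin(2.5, pmax(-2.5, gradient_strength * 1.2 * z + rnorm(n, sd = noise_sd)))
  })
  colnames(gov) <- paste0("gov", 1:6)
  out <- bind_cols(countries, as_tibble(gov)) |>
    mutate(
      governance = rowMeans(across(all_of(paste0("gov", 1:6)))),
      gdp_per_capita = exp(9 + gradient_strength * 1.0 * z +
        rnorm(n, sd = 0.5)),
      co2_per_capita = exp(1 + gradient_strength * 0.8 * z +
        rnorm(n, sd = 0.5))
    )
  class(out) <- c("covariate_table", class(out))
  out
}

#' National governance score
#'
#' Arithmetic mean of the six governance indicators; stays in
#' `[-2.5, 2.5]` because each indicator does.
#'
#' @param covariates A covariate table with columns `gov1..gov6`.
#' @return The input with a (re)computed `governance` column.
#' @export
governance_score <- function(covariates) {
  gov_cols <- paste0("gov", 1:6)
  if (!all(gov_cols %in% names(covariates))) {
    abort("Covariate table must contain the six indicator columns gov1..gov6.")
  }
  covariates |>
    mutate(governance = rowMeans(across(all_of(gov_cols))))
}
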