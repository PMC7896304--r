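#' Canonical bioclimatic variables
#'
#' The pipeline carries eight candidate bioclimatic variables, four of the
#' temperature class and four of the precipitation class, mirroring the usual
#' candidate set for broad-scale niche models: annual means, seasonality
#' (variability) and extremes of both temperature and precipitation.
#'
#' @return A tibble with columns `variable` and `class`
#'   (`"temperature"`/`"precipitation"`).
#' @examples
#' bioclim_vars()
#' @export
bioclim_vars <- function() {
  tibble(
    variable = c(
      "temp_mean", "temp_seasonality", "temp_max_warmest", "temp_min_coldest",
      "prec_mean", "prec_seasonality", "prec_wettest", "prec_driest"
    ),
    class = rep(c("temperature", "precipitation"), each = 4)
  )
}

#' Default predictor set
#'
#' The five-variable predictor pool the pipeline settles on by default:
#' mean annual temperature, temperature seasonality, and precipitation of the
#' wettest month, driest month and its seasonality.
#'
#' @return Character vector of five variable names.
#' @export
default_predictors <- function() {
  c(
    "temp_mean", "temp_seasonality",
    "prec_wettest", "prec_driest", "prec_seasonality"
  )
}

#' Future-climate delta specifications
#'
#' A delta spec describes how each future scenario perturbs the current
#' climate: a per-variable additive `shift` and multiplicative `scale` for
#' each of the four emissions scenarios, plus the per-GCM treatment (three
#' pseudo-GCMs whose multipliers spread the scenario shift, and a
#' spatially-autocorrelated GCM noise term of standard deviation
#' `gcm_noise_sd`). `delta_spec_zero()` zeroes every component, so futures
#' equal the current climate exactly.
#'
#' Default warming levels step up across scenarios (the `rcp85` analogue has
#' the largest mean temperature shift, roughly +3.7 degrees by 2070, `rcp26`
#' the smallest at +1.0) and precipitation shifts are mildly positive for wet
#' variables and negative for dry-month precipitation, emulating
#' wet-get-wetter/dry-get-drier projections.
#'
#' @param gcm_noise_sd Standard deviation of the per-GCM spatial noise added
#'   to every shifted layer.
#' @return A list with elements `shifts` (tibble: scenario, variable, shift,
#'   scale), `gcm_mult` (named multipliers for the three pseudo-GCMs) and
#'   `gcm_noise_sd`.
#' @export
delta_spec_default <- function(gcm_noise_sd = 0.05) {
  scen <- scenario_ids()
  warm <- c(rcp26 = 1.0, rcp45 = 1.8, rcp60 = 2.5, rcp85 = 3.7)
  base <- tibble(
    variable = bioclim_vars()$variable,
    # per +1 degree of scenario warming
    shift_per_deg = c(1, 0.08, 1.1, 1.2, 0.5, 0.15, 1.0, -0.3),
  )
  shifts <- crossing(scenario = scen, base) |>
    mutate(shift = .data$shift_per_deg * warm[.data$scenario], scale = 1) |>
    select("scenario", "variable", "shift", "scale")
  list(
    shifts = shifts,
    gcm_mult = c(gcm1 = 0.85, gcm2 = 1.0, gcm3 = 1.15),
    gcm_noise_sd = gcm_noise_sd
  )
}

#' @rdname delta_spec_default
#' @export
delta_spec_zero <- function() {
  spec <- delta_spec_default(gcm_noise_sd = 0)
  spec$shifts$shift <- 0
  spec$gcm_mult[] <- 1
  spec
}

scenario_ids <- function() c("rcp26", "rcp45", "rcp60", "rcp85")
gcm_ids <- function() c("gcm1", "gcm2", "gcm3")

#' Generate current and future climate surfaces
#'
#' Builds the eight bioclimatic layers on the model grid. Every layer is a
#' deterministic base pattern (a latitudinal gradient for temperature-class
#' variables, a milder longitude/latitude trend for precipitation) plus
#' spatially autocorrelated noise (Gaussian-filtered white noise with filter
#' radius `autocorr_range`, in cells). Precipitation and seasonality layers
#' are kept non-negative via a softplus floor. Future layers are the current
#' layer plus scenario x GCM deltas from `future_delta_spec`; with
#' [delta_spec_zero()] futures are bit-identical to the present. All
#' randomness derives from `seed`.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param autocorr_range Positive filter radius (cells) of the noise field.
#' @param future_delta_spec A delta spec; see [delta_spec_default()].
#' @param noise_sd Noise amplitude of each layer, in units of one tenth of the
#'   layer's base dynamic range (1 keeps local climate variation well below
#'   the scenario warming signal).
#' @return A `climate_table` tibble with columns `epoch` (`current`/`future`),
#'   `scenario`, `gcm`, `cell`, `row`, `col`, `lat` and one column per
#'   bioclimatic variable. The current epoch has `scenario = gcm = "current"`.
#' @examples
#' clim <- gen_climate(grid_spec(8, 8), seed = 1)
#' dplyr::count(clim, epoch, scenario, gcm)
#' @export
gen_climate <- function(grid, seed, autocorr_range = 3,
                        future_delta_spec = delta_spec_default(),
                        noise_sd = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(autocorr_range) || autocorr_range <= 0) {
    abort("`autocorr_range` must be positive.")
  }
  vars <- bioclim_vars()
  cells <- grid_cells(grid)
  nr <- grid$n_rows
  nc <- grid$n_cols

  noise_field <- function(sd_val) {
    m <- matrix(rnorm(nr * nc, sd = sd_val), nr, nc, byrow = FALSE)
    sm <- gaussian_smooth(m, autocorr_range)
    # renormalise so the smoothed field keeps roughly the requested sd
    if (sd(sm) > 0) sm <- sm * sd_val / sd(sm)
    # t() flattens row-major, matching cell id order (cell = row*nc + col + 1)
    as.numeric(t(sm))
  }

  set.seed(seed)

  lat01 <- (cells$lat - grid$lat_south) / (grid$lat_north - grid$lat_south)
  lon01 <- cells$col / max(1L, nc - 1L)
  # temperature profile flat near the equator and steep towards the pole
  # (as on the real Earth): a uniform warming therefore creates novel
  # climates in the tropics instead of merely translating isotherms
  lat_t <- lat01^2

  base <- list(
    temp_mean        = 28 - 30 * lat_t,
    temp_seasonality = 2 + 6 * lat01,
    temp_max_warmest = 34 - 24 * lat_t,
    temp_min_coldest = 22 - 38 * lat_t,
    prec_mean        = 120 - 60 * lat01 + 25 * sin(2 * pi * lon01),
    prec_seasonality = 30 + 25 * (1 - lat01),
    prec_wettest     = 260 - 120 * lat01 + 50 * sin(2 * pi * lon01 + 1),
    prec_driest      = 45 - 25 * lat01 + 15 * cos(2 * pi * lon01)
  )
  nonneg <- c(
    "temp_seasonality", "prec_mean", "prec_seasonality",
    "prec_wettest", "prec_driest"
  )
  # noise scaled to each variable's dynamic range
  amp <- vapply(base, function(b) max(diff(range(b)), 1) / 10, numeric(1))

  layers <- lapply(names(base), function(v) {
    x <- base[[v]] + noise_field(noise_sd * amp[[v]])
    if (v %in% nonneg) x <- log1p(exp(x / 5)) * 5 # softplus floor at 0
    x
  })
  names(layers) <- names(base)

  current <- bind_cols(
    tibble(epoch = "current", scenario = "current", gcm = "current"),
    cells, as_tibble(layers)
  )

  spec <- future_delta_spec
  futures <- list()
  for (sc in scenario_ids()) {
    sh <- spec$shifts |> filter(.data$scenario == sc)
    sh_shift <- setNames(sh$shift, sh$variable)
    sh_scale <- setNames(sh$scale, sh$variable)
    for (g in names(spec$gcm_mult)) {
      fut <- current
      fut$epoch <- "future"
      fut$scenario <- sc
      fut$gcm <- g
      for (v in names(base)) {
        delta <- sh_shift[[v]] * spec$gcm_mult[[g]]
        gnoise <- if (spec$gcm_noise_sd > 0) {
          noise_field(spec$gcm_noise_sd * amp[[v]])
        } else 0
        x <- fut[[v]] * sh_scale[[v]] + delta + gnoise
        if (v %in% nonneg) x <- pmax(x, 0)
        fut[[v]] <- x
      }
      futures[[paste(sc, g, sep = ".")]] <- fut
    }
  }

  out <- bind_rows(current, bind_rows(futures))
  class(out) <- c("climate_table", class(out))
  out
}

#' Extract one climate layer set
#'
#' @param climate A `climate_table` from [gen_climate()].
#' @param epoch `"current"` or `"future"`.
#' @param scenario,gcm Scenario and pseudo-GCM ids (ignored for the current
#'   epoch).
#' @return Tibble of cells with variable columns for the selected slice.
#' @export
climate_slice <- function(climate, epoch = "current",
                          scenario = NULL, gcm = NULL) {
  if (epoch == "current") {
    out <- climate |> filter(.data$epoch == "current")
  } else {
    stopifnot(!is.null(scenario), !is.null(gcm))
    sc <- scenario
    g <- gcm
    out <- climate |>
      filter(.data$epoch == "future", .data$scenario == sc, .data$gcm == g)
  }
  if (nrow(out) == 0) abort("No climate rows match the requested slice.")
  out
}
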