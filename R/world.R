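#' Generate a complete virtual world
#'
#' Convenience wrapper chaining [gen_climate()], [gen_regions()],
#' [gen_species()] and [gen_covariates()] with per-stage seeds derived from
#' one global seed, so every component is reproducible independently.
#'
#' @param grid A [grid_spec()] (or `NULL` to build one from
#'   `n_rows`/`n_cols`).
#' @param n_rows,n_cols Grid size used when `grid` is `NULL`.
#' @param n_realms,n_ecoregions,n_countries Region counts.
#' @param n_species Number of virtual species.
#' @param seed Global seed.
#' @param autocorr_range Climate noise autocorrelation range (cells).
#' @param niche_breadth_range,prevalence_range Species niche parameters; see
#'   [gen_species()].
#' @param barrier_frac Share of borders carrying barriers.
#' @param gradient_strength Latitude gradient of the national covariates.
#' @param future_delta_spec Future-climate delta spec.
#' @param ... Further arguments passed to [gen_species()].
#' @return A list of class `vs_world` with elements `grid`, `climate`,
#'   `regions` (map/borders/border_cells), `species`, `covariates`, `seed`.
#' @examples
#' w <- gen_world(n_rows = 10, n_cols = 10, n_species = 3, seed = 1)
#' w$species
#' @export
gen_world <- function(grid = NULL, n_rows = 20, n_cols = 20,
                      n_realms = 2, n_ecoregions = 12, n_countries = 6,
                      n_species = 10, seed = 1,
                      autocorr_range = 3,
                      niche_breadth_range = c(0.5, 1.5),
                      prevalence_range = c(0.1, 0.4),
                      barrier_frac = 0.15,
                      gradient_strength = 1,
                      future_delta_spec = delta_spec_default(),
                      ...) {
  if (is.null(grid)) grid <- grid_spec(n_rows, n_cols)
  climate <- gen_climate(grid,
    seed = stage_seed(seed, "climate"),
    autocorr_range = autocorr_range,
    future_delta_spec = future_delta_spec
  )
  regions <- gen_regions(grid,
    n_realms = n_realms, n_ecoregions = n_ecoregions,
    n_countries = n_countries, seed = stage_seed(seed, "regions"),
    barrier_frac = barrier_frac
  )
  species <- gen_species(climate, regions,
    n_species = n_species,
    niche_breadth_range = niche_breadth_range,
    prevalence_range = prevalence_range,
    seed = stage_seed(seed, "species"), ...
  )
  covariates <- gen_covariates(regions,
    seed = stage_seed(seed, "covariates"),
    gradient_strength = gradient_strength
  )
  structure(
    list(
      grid = grid, climate = climate, regions = regions,
      species = species, covariates = covariates, seed = seed
    ),
    class = "vs_world"
  )
}

#' @export
print.vs_world <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<vs_world> %dx%d grid, %d realms, %d fragments, %d countries, ",
      "%d borders (%d with barriers), %d species (seed %s)\n"
    ),
    x$grid$n_rows, x$grid$n_cols,
    length(unique(x$regions$map$realm)),
    length(unique(x$regions$map$fragment)),
    length(unique(x$regions$map$country)),
    nrow(x$regions$borders), sum(x$regions$borders$barrier),
    nrow(x$species), format(x$seed)
  ))
  invisible(x)
}

# Deterministic per-stage seed derived from the global seed; keeps every
# stage independently re-runnable. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483646L) + 1L
}
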