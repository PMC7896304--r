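#' Gaussian niche suitability
#'
#' Suitability of each cell for a species with a Gaussian (bell-shaped)
#' response on each of its niche variables:
#' `exp(-sum_v ((x_v - opt_v) / (breadth_v * sd_v))^2 / 2)`,
#' where `sd_v` is the global standard deviation of variable `v` under the
#' current climate (so `breadth` is expressed in global-SD units).
#'
#' @param truth A species truth record (list with `variables`, `optimum`,
#'   `breadth`, `sd_ref`).
#' @param climate_cells Tibble of cells with the niche variable columns.
#' @return Numeric suitability in `[0, 1]`, one per row of `climate_cells`.
#' @export
niche_suitability <- function(truth, climate_cells) {
  z2 <- rep(0, nrow(climate_cells))
  for (v in truth$variables) {
    z <- (climate_cells[[v]] - truth$optimum[[v]]) /
      (truth$breadth[[v]] * truth$sd_ref[[v]])
    z2 <- z2 + z^2
  }
  exp(-z2 / 2)
}

#' Generate virtual species with known climatic niches
#'
#' Each species receives a Gaussian suitability function over a random subset
#' of `truth_vars` (2 or 3 of them by default), with its optimum taken from
#' the current climate of a randomly chosen cell (so the optimum is
#' attainable) and its breadth drawn from `niche_breadth_range` (in units of
#' each variable's global SD). A prevalence `p` drawn from `prevalence_range`
#' sets the presence rule: the species occupies exactly the cells whose
#' suitability is at or above the `1 - p` quantile of suitability over its
#' sampling domain (the whole grid by default, or the species' realm when
#' `realm_constrained`). There is no label noise: presences are exactly the
#' super-threshold cells, and the full truth (variables, optimum, breadth,
#' cutoff) is stored for recovery tests.
#'
#' Species are tagged with a taxon group (bird/mammal), a flying flag (all
#' birds fly; a bat-like share of mammals does) and a threatened flag.
#'
#' @param climate A `climate_table`; the current epoch is used.
#' @param regions Output of [gen_regions()].
#' @param n_species Number of species.
#' @param niche_breadth_range Range of Gaussian niche breadths (global-SD
#'   units).
#' @param prevalence_range Range of species prevalence (fraction of the
#'   sampling domain occupied).
#' @param seed Integer seed.
#' @param truth_vars Variables the true niches may use.
#' @param realm_constrained If `TRUE`, a species' candidate cells are
#'   restricted to one randomly chosen realm; otherwise the whole grid.
#' @param tropical_narrowing Latitude scaling of niche breadth in `[0, 1)`:
#'   a species whose optimum sits at the equator has its breadth multiplied
#'   by `1 - tropical_narrowing`, grading linearly to 1 at the poleward edge.
#'   Mirrors the empirical narrowing of climatic niches towards the tropics,
#'   which (with the flat tropical temperature gradient) makes low-latitude
#'   assemblages the most exposed to warming.
#' @param p_mammal,p_bat,p_threatened Tag probabilities.
#' @param max_retries Regeneration cap for degenerate (empty-presence)
#'   species.
#' @return A `species_table` tibble: `species_id`, `taxon_group`, `flying`,
#'   `threatened`, `n_presence`, and list-columns `presence` (cell ids) and
#'   `truth`.
#' @examples
#' g <- grid_spec(10, 10)
#' clim <- gen_climate(g, seed = 1)
#' reg <- gen_regions(g, 2, 4, 3, seed = 1)
#' sp <- gen_species(clim, reg, n_species = 5, seed = 1)
#' sp
#' @export
gen_species <- function(climate, regions, n_species,
                        niche_breadth_range = c(0.5, 1.5),
                        prevalence_range = c(0.1, 0.4),
                        seed = 1,
                        truth_vars = default_predictors(),
                        realm_constrained = FALSE,
                        tropical_narrowing = 0.6,
                        p_mammal = 0.5, p_bat = 0.2, p_threatened = 0.15,
                        max_retries = 20) {
  cur <- climate |> filter(.data$epoch == "current")
  if (nrow(cur) == 0) abort("`climate` has no current-epoch rows.")
  map <- regions$map
  set.seed(seed)
  sd_ref <- vapply(truth_vars, function(v) sd(cur[[v]]), numeric(1))

  make_one <- function(i) {
    for (try in seq_len(max_retries)) {
      k <- sample(2:min(3, length(truth_vars)), 1)
      # temperature is limiting for every species; the remaining niche axes
      # are drawn from the other candidate variables
      vars <- if ("temp_mean" %in% truth_vars) {
        c("temp_mean", sample(setdiff(truth_vars, "temp_mean"), k - 1))
      } else {
        sample(truth_vars, k)
      }
      realm <- sample(unique(map$realm), 1)
      domain <- if (realm_constrained) {
        cur[cur$cell %in% map$cell[map$realm == realm], ]
      } else {
        cur
      }
      opt_cell <- domain[sample.int(nrow(domain), 1), ]
      lat01 <- (opt_cell$lat - min(domain$lat)) /
        max(1e-9, diff(range(domain$lat)))
      breadth_mult <- 1 - tropical_narrowing * (1 - lat01)
      truth <- list(
        variables = vars,
        optimum = as.list(opt_cell[vars]),
        breadth = as.list(setNames(
          breadth_mult *
            runif(k, niche_breadth_range[1], niche_breadth_range[2]), vars
        )),
        sd_ref = as.list(sd_ref[vars]),
        realm = realm
      )
      suit <- niche_suitability(truth, domain)
      prev <- runif(1, prevalence_range[1], prevalence_range[2])
      cutoff <- quantile(suit, 1 - prev, names = FALSE)
      presence <- domain$cell[suit >= cutoff]
      if (length(presence) > 0) {
        truth$cutoff <- cutoff
        truth$prevalence <- prev
        is_mammal <- runif(1) < p_mammal
        return(tibble(
          species_id = sprintf("sp%03d", i),
          taxon_group = if (is_mammal) "mammal" else "bird",
          flying = if (is_mammal) runif(1) < p_bat else TRUE,
          threatened = runif(1) < p_threatened,
          n_presence = length(presence),
          presence = list(sort(presence)),
          truth = list(truth)
        ))
      }
    }
    warn(sprintf(
      "Species %d produced an empty presence set after %d retries; dropped.",
      i, max_retries
    ))
    NULL
  }

  out <- bind_rows(lapply(seq_len(n_species), make_one))
  class(out) <- c("species_table", class(out))
  out
}

#' True occupancy of a species under a given climate
#'
#' Applies a species' stored truth (suitability function and calibrated
#' cutoff) to any climate slice, yielding the ground-truth occupied cell set.
#' Under the current climate this reproduces `presence` exactly; under a
#' future slice it is the true future niche against which projections are
#' scored.
#'
#' @param species_row One row of a `species_table`.
#' @param climate_cells A climate slice (tibble of cells + variable columns).
#' @return Integer vector of occupied cell ids.
#' @export
true_occupancy <- function(species_row, climate_cells) {
  truth <- species_row$truth[[1]]
  suit <- niche_suitability(truth, climate_cells)
  sort(climate_cells$cell[suit >= truth$cutoff])
}
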