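# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Small world for generator/border tests: 12x12, 4 countries.
tiny_world <- function() {
  memo("tiny_world", function() {
    gen_world(
      n_rows = 12, n_cols = 12, n_realms = 2, n_ecoregions = 8,
      n_countries = 4, n_species = 6, seed = 42,
      prevalence_range = c(0.15, 0.35), barrier_frac = 0.4
    )
  })
}

# Mid-sized world with many borders for oracle-equivalence tests.
border_world <- function() {
  memo("border_world", function() {
    gen_world(
      n_rows = 18, n_cols = 18, n_realms = 2, n_ecoregions = 10,
      n_countries = 12, n_species = 50, seed = 7,
      prevalence_range = c(0.05, 0.3), barrier_frac = 0.3
    )
  })
}

# Truth-based binary "projections" (no model fitting): the species' true
# occupancy under a given climate slice, in the cell/binary layout the
# border and richness operations consume.
truth_projections <- function(world, epoch = "future",
                              scenario = "rcp85", gcm = "gcm2") {
  slice <- if (epoch == "current") {
    climate_slice(world$climate, "current")
  } else {
    climate_slice(world$climate, "future", scenario, gcm)
  }
  out <- lapply(seq_len(nrow(world$species)), function(i) {
    occ <- true_occupancy(world$species[i, ], slice)
    tibble::tibble(cell = slice$cell, binary = slice$cell %in% occ)
  })
  names(out) <- world$species$species_id
  out
}

# A small block-labelled occurrence table built from explicit vectors, for
# model-family unit tests (blocks assigned round-robin by row).
toy_occurrence <- function(n = 240, n_vars = 3, n_blocks = 6, seed = 1,
                           signal = function(X) X[, 1]) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_vars), n, n_vars)
  colnames(X) <- paste0("v", seq_len(n_vars))
  eta <- signal(X)
  y <- rbinom(n, 1, plogis(eta))
  tibble::tibble(
    species_id = "toy",
    cell = seq_len(n), row = 0L, col = 0L,
    label = ifelse(y == 1, "presence", "pseudoabsence"),
    block = rep_len(seq_len(n_blocks), n)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

# Deterministic occurrence labels (no Bernoulli noise), for separable cases.
toy_occurrence_sep <- function(n = 200, n_vars = 1, n_blocks = 5, seed = 1,
                               rule = function(X) X[, 1] > 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_vars), n, n_vars)
  colnames(X) <- paste0("v", seq_len(n_vars))
  y <- as.integer(rule(X))
  tibble::tibble(
    species_id = "toy",
    cell = seq_len(n), row = 0L, col = 0L,
    label = ifelse(y == 1, "presence", "pseudoabsence"),
    block = rep_len(seq_len(n_blocks), n)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

cell_of <- function(grid, row, col) row * grid$n_cols + col + 1L
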