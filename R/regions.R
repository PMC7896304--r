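#' Generate realms, ecoregions, fragments, countries and the border graph
#'
#' Builds the regional scaffolding of a virtual world. Zoogeographic realms
#' are contiguous longitudinal bands of near-equal width. Ecoregions
#' partition each realm by nearest-seed assignment in jittered coordinates
#' (the jitter produces occasional disjunct ecoregions, exercising the
#' fragment machinery); fragments are then the 4-connected components within
#' each ecoregion. Countries partition the whole grid by randomized
#' multi-source flood fill, so each country is contiguous and non-empty. The
#' border graph has one edge per pair of countries sharing at least one
#' 4-adjacent cell pair; a random `barrier_frac` share of edges is flagged as
#' fortified (wall/fence built or under construction).
#'
#' @param grid A [grid_spec()].
#' @param n_realms,n_ecoregions,n_countries Region counts
#'   (`1 <= n_realms <= n_ecoregions`, `n_countries >= 1`).
#' @param seed Integer seed.
#' @param barrier_frac Fraction of borders carrying a barrier.
#' @param ecoregion_jitter Coordinate jitter (cells) of the ecoregion seeds.
#' @return A list with elements
#'   * `map`: tibble `cell, row, col, lat, realm, ecoregion, fragment,
#'     country` (a complete partition in each column),
#'   * `borders`: tibble `border_id, country_a, country_b, barrier`,
#'   * `border_cells`: tibble `border_id, cell_a, cell_b` of the adjacent
#'     cross-border cell pairs.
#' @examples
#' reg <- gen_regions(grid_spec(8, 8), n_realms = 2, n_ecoregions = 4,
#'                    n_countries = 3, seed = 1)
#' dplyr::count(reg$map, country)
#' @export
gen_regions <- function(grid, n_realms, n_ecoregions, n_countries, seed,
                        barrier_frac = 0.15, ecoregion_jitter = 1.5) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_realms < 1 || n_ecoregions < n_realms) {
    abort("Need 1 <= n_realms <= n_ecoregions.")
  }
  if (n_countries < 1) abort("`n_countries` must be at least 1.")
  if (n_countries > n_cells(grid)) {
    abort("`n_countries` exceeds the number of grid cells.")
  }
  set.seed(seed)
  cells <- grid_cells(grid)

  # realms: contiguous longitudinal bands
  band <- if (n_realms == 1) {
    rep(1L, nrow(cells))
  } else {
    cut(cells$col, breaks = n_realms, labels = FALSE)
  }
  cells$realm <- band

  # ecoregions: jittered nearest-seed within each realm
  eco_per_realm <- table(factor(band, levels = seq_len(n_realms)))
  alloc <- pmax(1L, round(n_ecoregions * as.numeric(eco_per_realm) /
    sum(eco_per_realm)))
  # adjust to hit n_ecoregions exactly
  while (sum(alloc) > n_ecoregions) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < n_ecoregions) {
    i <- which.min(alloc)
    alloc[i] <- alloc[i] + 1L
  }
  cells$ecoregion <- NA_integer_
  eco_offset <- 0L
  for (r in seq_len(n_realms)) {
    idx <- which(cells$realm == r)
    k <- min(alloc[r], length(idx))
    seeds <- sample(idx, k)
    d <- outer(cells$row[idx], cells$row[seeds], "-")^2 +
      outer(cells$col[idx], cells$col[seeds], "-")^2
    d <- sqrt(d) + matrix(
      rnorm(length(idx) * k, sd = ecoregion_jitter),
      nrow = length(idx)
    )
    cells$ecoregion[idx] <- eco_offset + max.col(-d, ties.method = "first")
    eco_offset <- eco_offset + k
  }

  # fragments: 4-connected components within each ecoregion
  cells$fragment <- NA_integer_
  frag_offset <- 0L
  for (e in sort(unique(cells$ecoregion))) {
    idx <- which(cells$ecoregion == e)
    comp <- label_components(grid, cells$cell[idx])
    cells$fragment[idx] <- frag_offset + comp
    frag_offset <- frag_offset + max(comp)
  }

  # countries: randomized multi-source flood fill (contiguous, non-empty)
  cells$country <- flood_fill_partition(grid, n_countries)

  graph <- build_border_graph(grid, cells$country, barrier_frac)
  list(
    map = cells |> select(
      "cell", "row", "col", "lat", "realm", "ecoregion", "fragment", "country"
    ),
    borders = graph$borders,
    border_cells = graph$border_cells
  )
}

# Randomized multi-source BFS growth: n_parts contiguous labels covering grid.
flood_fill_partition <- function(grid, n_parts) {
  ncl <- n_cells(grid)
  nc <- grid$n_cols
  lab <- integer(ncl)
  seeds <- sample.int(ncl, n_parts)
  lab[seeds] <- seq_len(n_parts)
  frontier <- as.list(seeds)
  active <- seq_len(n_parts)
  while (length(active) > 0) {
    # each active part claims one random frontier-adjacent cell per sweep,
    # in random part order, yielding irregular but contiguous territories
    for (p in sample(active)) {
      fr <- frontier[[p]]
      claimed <- FALSE
      while (length(fr) > 0 && !claimed) {
        i <- sample.int(length(fr), 1)
        cur <- fr[i]
        row <- (cur - 1L) %/% nc
        col <- (cur - 1L) %% nc
        nb <- c(
          if (col > 0L) cur - 1L,
          if (col < nc - 1L) cur + 1L,
          if (row > 0L) cur - nc,
          if (row < grid$n_rows - 1L) cur + nc
        )
        free <- nb[lab[nb] == 0L]
        if (length(free) == 0) {
          fr <- fr[-i]
        } else {
          take <- if (length(free) == 1) free else sample(free, 1)
          lab[take] <- p
          fr <- c(fr, take)
          claimed <- TRUE
        }
      }
      frontier[[p]] <- fr
    }
    active <- which(vapply(
      frontier, function(fr) length(fr) > 0, logical(1)
    ))
    active <- active[vapply(active, function(p) {
      any_free_neighbour(grid, frontier[[p]], lab)
    }, logical(1))]
    if (all(lab != 0L)) break
  }
  lab
}

any_free_neighbour <- function(grid, cells, lab) {
  nc <- grid$n_cols
  for (cur in cells) {
    row <- (cur - 1L) %/% nc
    col <- (cur - 1L) %% nc
    nb <- c(
      if (col > 0L) cur - 1L,
      if (col < nc - 1L) cur + 1L,
      if (row > 0L) cur - nc,
      if (row < grid$n_rows - 1L) cur + nc
    )
    if (any(lab[nb] == 0L)) return(TRUE)
  }
  FALSE
}

# Border graph from a country labelling: one edge per country pair with
# >= 1 adjacent cell pair; barrier flags drawn for a random edge subset.
build_border_graph <- function(grid, country_of, barrier_frac) {
  adj <- grid_adjacency(grid)
  adj$ca <- country_of[adj$cell_a]
  adj$cb <- country_of[adj$cell_b]
  cross <- adj |> filter(.data$ca != .data$cb)
  if (nrow(cross) == 0) {
    return(list(
      borders = tibble(
        border_id = integer(0), country_a = integer(0),
        country_b = integer(0), barrier = logical(0)
      ),
      border_cells = tibble(
        border_id = integer(0), cell_a = integer(0), cell_b = integer(0)
      )
    ))
  }
  cross <- cross |>
    mutate(
      country_a = pmin(.data$ca, .data$cb),
      country_b = pmax(.data$ca, .data$cb)
    )
  borders <- cross |>
    distinct(.data$country_a, .data$country_b) |>
    arrange(.data$country_a, .data$country_b) |>
    mutate(border_id = row_number(), .before = 1)
  n_barrier <- round(barrier_frac * nrow(borders))
  barrier_ids <- if (n_barrier > 0) {
    sample(borders$border_id, n_barrier)
  } else {
    integer(0)
  }
  borders$barrier <- borders$border_id %in% barrier_ids
  border_cells <- cross |>
    inner_join(borders, by = c("country_a", "country_b")) |>
    select("border_id", "cell_a", "cell_b") |>
    arrange(.data$border_id, .data$cell_a, .data$cell_b)
  list(borders = borders, border_cells = border_cells)
}

#' Realm adjacency
#'
#' Two realms are adjacent when at least one 4-adjacent cell pair spans them.
#' Used to build projection domains (a species is projected across its
#' occupied realms and their neighbours).
#'
#' @param grid A [grid_spec()].
#' @param map The `map` tibble of [gen_regions()].
#' @return Tibble `realm_a`, `realm_b` (unordered pairs, `realm_a < realm_b`).
#' @export
realm_adjacency <- function(grid, map) {
  adj <- grid_adjacency(grid)
  ra <- map$realm[match(adj$cell_a, map$cell)]
  rb <- map$realm[match(adj$cell_b, map$cell)]
  tibble(realm_a = pmin(ra, rb), realm_b = pmax(ra, rb)) |>
    filter(.data$realm_a != .data$realm_b) |>
    distinct() |>
    arrange(.data$realm_a, .data$realm_b)
}
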