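# Brute-force oracles used throughout: plain double loops over species and
# borders, written independently of the package's join-based implementations.

oracle_country_set <- function(world, sp_row) {
  map <- world$regions$map
  sort(unique(map$country[map$cell %in% sp_row$presence[[1]]]))
}

oracle_future_countries <- function(world, projections, sp_id) {
  pr <- projections[[sp_id]]
  map <- world$regions$map
  sort(unique(map$country[map$cell %in% pr$cell[pr$binary]]))
}

test_that("current country sets and the transboundary flag match the oracle", {
  w <- border_world()
  cs <- current_country_set(w$species, w$regions)
  for (i in seq_len(nrow(w$species))) {
    expect_equal(cs$countries[[i]], oracle_country_set(w, w$species[i, ]))
  }
  expect_equal(cs$transboundary, lengths(cs$countries) >= 2)
})

test_that("bisection counting uses set semantics per border", {
  w <- border_world()
  stats <- border_bisection_counts(w$species, w$regions$borders, w$regions)
  for (b in seq_len(nrow(stats))) {
    oracle <- 0L
    oracle_thr <- 0L
    for (i in seq_len(nrow(w$species))) {
      set <- oracle_country_set(w, w$species[i, ])
      hit <- stats$country_a[b] %in% set && stats$country_b[b] %in% set
      oracle <- oracle + hit
      oracle_thr <- oracle_thr + (hit && w$species$threatened[i])
    }
    expect_equal(stats$n_bisecting[b], oracle)
    expect_equal(stats$n_bisecting_threatened[b], oracle_thr)
  }
})

test_that("a species on one side only never counts as bisecting", {
  g <- grid_spec(6, 6)
  country_of <- ifelse(grid_cells(g)$col < 3, 1L, 2L)
  graph <- borderniche:::build_border_graph(g, country_of, barrier_frac = 0)
  regions <- list(map = dplyr::mutate(grid_cells(g), country = country_of))
  one_side <- tibble::tibble(
    species_id = "a", threatened = FALSE, presence = list(c(1L, 2L, 7L))
  )
  both <- tibble::tibble(
    species_id = "b", threatened = TRUE, presence = list(c(3L, 4L))
  )
  s1 <- border_bisection_counts(one_side, graph$borders, regions)
  expect_equal(s1$n_bisecting, 0L)
  s2 <- border_bisection_counts(both, graph$borders, regions)
  expect_equal(s2$n_bisecting, 1L)
  expect_equal(s2$n_bisecting_threatened, 1L)
})

test_that("transboundary richness fractions match the ratio oracle", {
  w <- border_world()
  stats <- border_bisection_counts(w$species, w$regions$borders, w$regions) |>
    transboundary_richness_fraction(w$species, w$regions)
  for (b in seq_len(nrow(stats))) {
    denom <- 0L
    for (i in seq_len(nrow(w$species))) {
      set <- oracle_country_set(w, w$species[i, ])
      denom <- denom +
        any(c(stats$country_a[b], stats$country_b[b]) %in% set)
    }
    expect_equal(stats$combined_richness[b], denom)
    if (denom > 0) {
      expect_equal(stats$bisection_fraction[b], stats$n_bisecting[b] / denom)
      expect_true(stats$bisection_fraction[b] >= 0 &&
        stats$bisection_fraction[b] <= 1)
    }
  }
})

test_that("new-country fractions follow the cell-count definition", {
  w <- tiny_world()
  map <- w$regions$map
  # a crafted species confined to one country, so "new" cells exist
  sp <- tibble::tibble(
    species_id = "one_country",
    presence = list(head(map$cell[map$country == 1], 8))
  )
  cur_countries <- oracle_country_set(w, sp)
  inside <- map$cell[map$country %in% cur_countries]
  outside <- map$cell[!map$country %in% cur_countries]
  make_proj <- function(cells) {
    list(tibble::tibble(cell = map$cell, binary = map$cell %in% cells)) |>
      setNames(sp$species_id)
  }
  # future entirely within current countries
  prof <- new_country_fraction(sp, make_proj(inside[1:5]), w$regions)
  expect_equal(prof$new_country_fraction, 0)
  # future entirely in new countries
  prof <- new_country_fraction(sp, make_proj(outside[1:4]), w$regions)
  expect_equal(prof$new_country_fraction, 1)
  # 10 future cells, 4 in a new country
  prof <- new_country_fraction(
    sp, make_proj(c(inside[1:6], outside[1:4])), w$regions
  )
  expect_equal(prof$new_country_fraction, 0.4)
  # empty future niche: undefined and flagged lost
  prof <- new_country_fraction(sp, make_proj(integer(0)), w$regions)
  expect_true(prof$niche_lost)
  expect_true(is.na(prof$new_country_fraction))
})

test_that("adding future cells inside current countries never raises the fraction", {
  w <- tiny_world()
  map <- w$regions$map
  sp <- w$species[2, ]
  cur_countries <- oracle_country_set(w, sp)
  inside <- map$cell[map$country %in% cur_countries]
  outside <- map$cell[!map$country %in% cur_countries]
  set.seed(8)
  base_cells <- c(sample(inside, 6), sample(outside, 3))
  mk <- function(cells) {
    setNames(
      list(tibble::tibble(cell = map$cell, binary = map$cell %in% cells)),
      sp$species_id
    )
  }
  f0 <- new_country_fraction(sp, mk(base_cells), w$regions)$new_country_fraction
  extra <- setdiff(inside, base_cells)[1:4]
  f1 <- new_country_fraction(
    sp, mk(c(base_cells, extra)), w$regions
  )$new_country_fraction
  expect_lte(f1, f0)
})

test_that("summary shares re-aggregate the per-species profiles", {
  w <- border_world()
  fut <- truth_projections(w)
  prof <- new_country_fraction(w$species, fut, w$regions)
  smry <- summarise_new_country(prof)
  ok <- prof[!prof$niche_lost, ]
  expect_equal(smry$share_over_half, mean(ok$new_country_fraction > 0.5))
  expect_equal(smry$share_at_least_fifth, mean(ok$new_country_fraction >= 0.2))
  expect_equal(smry$n_species, nrow(prof))
})

test_that("per-border shift counts equal the brute-force double loop", {
  w <- border_world()
  fut <- truth_projections(w)
  res <- per_border_shift_counts(
    w$species, fut, w$regions$borders, w$regions
  )
  stats <- res$border_stats
  for (b in seq_len(nrow(stats))) {
    oracle <- 0L
    for (i in seq_len(nrow(w$species))) {
      cur_set <- oracle_country_set(w, w$species[i, ])
      fut_set <- oracle_future_countries(w, fut, w$species$species_id[i])
      a_b <- stats$country_a[b]
      b_b <- stats$country_b[b]
      crosses <-
        (a_b %in% cur_set && !(b_b %in% cur_set) && b_b %in% fut_set) ||
        (b_b %in% cur_set && !(a_b %in% cur_set) && a_b %in% fut_set)
      oracle <- oracle + crosses
    }
    expect_equal(stats$n_shift[b], oracle, info = paste("border", b))
  }
  # a species already present on both sides contributes no shift anywhere
  expect_true(all(stats$n_shift <= stats$combined_richness))
  defined <- !is.na(stats$normalized_shift)
  expect_equal(
    stats$normalized_shift[defined],
    stats$n_shift[defined] / stats$combined_richness[defined]
  )
})

test_that("barrier blocking is restricted to nonflying mammals and barrier edges", {
  w <- border_world()
  fut <- truth_projections(w)
  res <- barrier_blocked_species(
    w$species, fut, w$regions$borders, w$regions
  )
  nonflying <- w$species[w$species$taxon_group == "mammal" &
    !w$species$flying, ]
  expect_true(all(res$blocked_species %in% nonflying$species_id))
  expect_equal(res$n_candidates, nrow(nonflying))
  # oracle: shift condition on at least one barrier edge
  barrier_edges <- w$regions$borders[w$regions$borders$barrier, ]
  oracle_blocked <- character(0)
  for (i in seq_len(nrow(nonflying))) {
    cur_set <- oracle_country_set(w, nonflying[i, ])
    fut_set <- oracle_future_countries(w, fut, nonflying$species_id[i])
    gained <- setdiff(fut_set, cur_set)
    hit <- FALSE
    for (b in seq_len(nrow(barrier_edges))) {
      a_b <- barrier_edges$country_a[b]
      b_b <- barrier_edges$country_b[b]
      if ((a_b %in% gained && b_b %in% cur_set) ||
        (b_b %in% gained && a_b %in% cur_set)) {
        hit <- TRUE
      }
    }
    if (hit) oracle_blocked <- c(oracle_blocked, nonflying$species_id[i])
  }
  expect_setequal(res$blocked_species, oracle_blocked)

  # without barriers the blocked set is empty (and warned about)
  no_barrier <- w$regions$borders
  no_barrier$barrier <- FALSE
  expect_warning(
    res0 <- barrier_blocked_species(w$species, fut, no_barrier, w$regions),
    "No barrier"
  )
  expect_equal(res0$n_blocked, 0L)
})

test_that("an identical world with the barrier flag off blocks nobody", {
  g <- grid_spec(6, 6)
  cells <- grid_cells(g)
  country_of <- ifelse(cells$col < 3, 1L, 2L)
  regions <- list(map = dplyr::mutate(cells, country = country_of))
  borders_on <- tibble::tibble(
    border_id = 1L, country_a = 1L, country_b = 2L, barrier = TRUE
  )
  borders_off <- dplyr::mutate(borders_on, barrier = FALSE)
  sp <- tibble::tibble(
    species_id = "m1", taxon_group = "mammal", flying = FALSE,
    threatened = FALSE,
    presence = list(cells$cell[cells$col < 2])
  )
  fut <- list(m1 = tibble::tibble(
    cell = cells$cell, binary = cells$col >= 2
  ))
  on <- barrier_blocked_species(sp, fut, borders_on, regions)
  expect_equal(on$blocked_species, "m1")
  off <- suppressWarnings(
    barrier_blocked_species(sp, fut, borders_off, regions)
  )
  expect_equal(off$n_blocked, 0L)
})
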