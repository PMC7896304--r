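#' Countries a species currently occupies
#'
#' The set of countries containing at least one presence cell; a species is
#' transboundary when that set has two or more members (its range crosses at
#' least one international border).
#'
#' @param species A `species_table`.
#' @param regions Output of [gen_regions()].
#' @return Tibble: `species_id`, list-column `countries`, `n_countries`,
#'   `transboundary`.
#' @export
current_country_set <- function(species, regions) {
  map <- regions$map
  tibble(
    species_id = species$species_id,
    countries = map(species$presence, function(cells) {
      sort(unique(map$country[match(cells, map$cell)]))
    })
  ) |>
    mutate(
      n_countries = lengths(.data$countries),
      transboundary = .data$n_countries >= 2
    )
}

#' Border bisection counts
#'
#' A species' current range is bisected by border (A, B) when it has at
#' least one presence cell in A and one in B (set semantics: cell counts are
#' irrelevant). Counts are reported for all species and for the threatened
#' subset, with an optional tag filter applied first.
#'
#' @param species A `species_table`.
#' @param borders Border tibble (`border_id`, `country_a`, `country_b`,
#'   `barrier`).
#' @param regions Output of [gen_regions()].
#' @param tag_filter Optional predicate over species rows (e.g.
#'   `~ .x$taxon_group == "mammal"`) applied before counting.
#' @return The borders tibble plus `n_bisecting`, `n_bisecting_threatened`.
#' @export
border_bisection_counts <- function(species, borders, regions,
                                    tag_filter = NULL) {
  sp <- apply_tag_filter(species, tag_filter)
  cs <- current_country_set(sp, regions)
  counts <- integer(nrow(borders))
  counts_thr <- integer(nrow(borders))
  for (i in seq_len(nrow(cs))) {
    set <- cs$countries[[i]]
    hit <- borders$country_a %in% set & borders$country_b %in% set
    counts[hit] <- counts[hit] + 1L
    if (isTRUE(sp$threatened[i])) counts_thr[hit] <- counts_thr[hit] + 1L
  }
  borders |>
    mutate(n_bisecting = counts, n_bisecting_threatened = counts_thr)
}

#' Transboundary richness fraction per border
#'
#' Bisection counts normalised by the combined richness of the two bordering
#' countries: the share of the species found in either country whose range
#' spans the border.
#'
#' @param border_stats Output of [border_bisection_counts()].
#' @param species A `species_table` (same filter as used for the counts).
#' @param regions Output of [gen_regions()].
#' @param tag_filter Optional predicate, as in [border_bisection_counts()].
#' @return `border_stats` plus `combined_richness` and `bisection_fraction`.
#' @export
transboundary_richness_fraction <- function(border_stats, species, regions,
                                            tag_filter = NULL) {
  sp <- apply_tag_filter(species, tag_filter)
  cs <- current_country_set(sp, regions)
  combined <- map_int(seq_len(nrow(border_stats)), function(i) {
    ab <- c(border_stats$country_a[i], border_stats$country_b[i])
    sum(map_lgl(cs$countries, ~ any(.x %in% ab)))
  })
  border_stats |>
    mutate(
      combined_richness = combined,
      bisection_fraction = if_else(
        combined > 0, .data$n_bisecting / combined, NA_real_
      )
    )
}

#' New-country fraction of a species' future niche
#'
#' The share of a species' projected future cells that lie in countries
#' where it is not currently found (current occupancy taken from the
#' observed range, not the modelled current niche). An empty future map
#' leaves the fraction undefined and flags the species as having lost its
#' niche.
#'
#' @param species A `species_table`.
#' @param future_projections Named list (by species id) of future
#'   `ensemble_projection` tibbles.
#' @param regions Output of [gen_regions()].
#' @return Tibble per species: `species_id`, `n_future_cells`,
#'   `n_new_country_cells`, `new_country_fraction`, `niche_lost`,
#'   list-columns `countries` (current) and `future_countries`.
#' @export
new_country_fraction <- function(species, future_projections, regions) {
  map <- regions$map
  cs <- current_country_set(species, regions)
  rows <- lapply(seq_len(nrow(species)), function(i) {
    sp_id <- species$species_id[i]
    pr <- future_projections[[sp_id]]
    if (is.null(pr)) return(NULL)
    fut_cells <- pr$cell[pr$binary]
    fut_countries <- map$country[match(fut_cells, map$cell)]
    n_fut <- length(fut_cells)
    cur_set <- cs$countries[[i]]
    n_new <- sum(!(fut_countries %in% cur_set))
    tibble(
      species_id = sp_id,
      n_future_cells = n_fut,
      n_new_country_cells = n_new,
      new_country_fraction = if (n_fut > 0) n_new / n_fut else NA_real_,
      niche_lost = n_fut == 0,
      countries = list(cur_set),
      future_countries = list(sort(unique(fut_countries)))
    )
  })
  bind_rows(rows)
}

#' Summarise new-country shares across species
#'
#' Shares of species (with a surviving future niche) whose new-country
#' fraction exceeds one half, and reaches at least one fifth.
#'
#' @param profiles Output of [new_country_fraction()].
#' @return One-row tibble: `n_species`, `n_defined`, `share_over_half`,
#'   `share_at_least_fifth`.
#' @export
summarise_new_country <- function(profiles) {
  defined <- profiles |> filter(!.data$niche_lost)
  tibble(
    n_species = nrow(profiles),
    n_defined = nrow(defined),
    share_over_half = mean(defined$new_country_fraction > 0.5),
    share_at_least_fifth = mean(defined$new_country_fraction >= 0.2)
  )
}

#' Per-border transboundary shift counts
#'
#' Species s crosses border (A, B) when it currently occupies exactly one
#' side (say A but not B) and its projected future niche has at least one
#' cell in the other country; directions are folded and each species counts
#' at most once per border. Optionally normalised by the combined current
#' richness of the two countries. Future gains in countries not adjacent
#' (through any border) to a currently occupied country are long-distance
#' jumps: they are attributed to no border and reported separately.
#'
#' @param species A `species_table`.
#' @param future_projections Named list of future projections.
#' @param borders Border tibble.
#' @param regions Output of [gen_regions()].
#' @param tag_filter Optional species predicate.
#' @return A list: `border_stats` (borders plus `n_shift`,
#'   `combined_richness`, `normalized_shift`), `jumps` (tibble
#'   `species_id`, `country` of unattributed gains).
#' @export
per_border_shift_counts <- function(species, future_projections, borders,
                                    regions, tag_filter = NULL) {
  sp <- apply_tag_filter(species, tag_filter)
  profiles <- new_country_fraction(sp, future_projections, regions)
  cs <- current_country_set(sp, regions)
  counts <- integer(nrow(borders))
  jumps <- list()
  for (i in seq_len(nrow(sp))) {
    sp_id <- sp$species_id[i]
    prof <- profiles[profiles$species_id == sp_id, ]
    if (nrow(prof) == 0) next
    cur_set <- cs$countries[[i]]
    gained <- setdiff(prof$future_countries[[1]], cur_set)
    for (g in gained) {
      hit <- which(
        (borders$country_a == g & borders$country_b %in% cur_set) |
          (borders$country_b == g & borders$country_a %in% cur_set)
      )
      if (length(hit) > 0) {
        counts[hit] <- counts[hit] + 1L
      } else {
        jumps[[length(jumps) + 1]] <- tibble(
          species_id = sp_id, country = g
        )
      }
    }
  }
  stats <- borders |> mutate(n_shift = counts)
  stats <- normalized_shift_counts(stats, sp, regions)
  list(border_stats = stats, jumps = bind_rows(jumps))
}

#' Normalise shift counts by combined richness
#'
#' Divides each border's shift count by the number of distinct species
#' currently present in either of its two countries.
#'
#' @param border_stats Borders tibble with an `n_shift` column.
#' @param species The (already filtered) `species_table` used for counting.
#' @param regions Output of [gen_regions()].
#' @return `border_stats` plus `combined_richness`, `normalized_shift`.
#' @export
normalized_shift_counts <- function(border_stats, species, regions) {
  cs <- current_country_set(species, regions)
  combined <- map_int(seq_len(nrow(border_stats)), function(i) {
    ab <- c(border_stats$country_a[i], border_stats$country_b[i])
    sum(map_lgl(cs$countries, ~ any(.x %in% ab)))
  })
  border_stats |>
    mutate(
      combined_richness = combined,
      normalized_shift = if_else(
        combined > 0, .data$n_shift / combined, NA_real_
      )
    )
}

#' Species blocked by border barriers
#'
#' Restricted to nonflying mammals (the group for which walls and fences
#' obstruct dispersal), reports (i) current-range bisection counts over
#' barrier borders only, and (ii) the blocked species: those whose shift
#' condition holds on at least one barrier border — their current niche sits
#' on one side of a fortified border that their future niche is projected to
#' cross.
#'
#' @param species A `species_table`.
#' @param future_projections Named list of future projections.
#' @param borders Border tibble with `barrier` flags.
#' @param regions Output of [gen_regions()].
#' @return A list: `barrier_bisection` (bisection stats on barrier edges),
#'   `per_barrier` (shift counts on barrier edges), `blocked_species`
#'   (character vector), `n_blocked`, `n_candidates`.
#' @export
barrier_blocked_species <- function(species, future_projections, borders,
                                    regions) {
  nonflying <- species |>
    filter(.data$taxon_group == "mammal", !.data$flying)
  barrier_edges <- borders |> filter(.data$barrier)
  if (nrow(barrier_edges) == 0) {
    warn("No barrier edges in the border graph; empty result.")
    return(list(
      barrier_bisection = barrier_edges,
      per_barrier = barrier_edges,
      blocked_species = character(0),
      n_blocked = 0L, n_candidates = nrow(nonflying)
    ))
  }
  bisect <- border_bisection_counts(nonflying, barrier_edges, regions)
  cs <- current_country_set(nonflying, regions)
  profiles <- new_country_fraction(nonflying, future_projections, regions)
  blocked <- character(0)
  counts <- integer(nrow(barrier_edges))
  for (i in seq_len(nrow(nonflying))) {
    sp_id <- nonflying$species_id[i]
    prof <- profiles[profiles$species_id == sp_id, ]
    if (nrow(prof) == 0) next
    cur_set <- cs$countries[[i]]
    gained <- setdiff(prof$future_countries[[1]], cur_set)
    hit <- which(
      (barrier_edges$country_a %in% gained &
        barrier_edges$country_b %in% cur_set) |
        (barrier_edges$country_b %in% gained &
          barrier_edges$country_a %in% cur_set)
    )
    if (length(hit) > 0) {
      blocked <- c(blocked, sp_id)
      counts[hit] <- counts[hit] + 1L
    }
  }
  list(
    barrier_bisection = bisect,
    per_barrier = barrier_edges |> mutate(n_blocked = counts),
    blocked_species = blocked,
    n_blocked = length(blocked),
    n_candidates = nrow(nonflying)
  )
}

apply_tag_filter <- function(species, tag_filter) {
  if (is.null(tag_filter)) return(species)
  f <- rlang::as_function(tag_filter)
  keep <- map_lgl(seq_len(nrow(species)), function(i) isTRUE(f(species[i, ])))
  species[keep, , drop = FALSE]
}
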