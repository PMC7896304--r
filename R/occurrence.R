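#' Rasterize a range polygon onto the model grid
#'
#' Converts a species range map (a set of sub-polygons with standard
#' presence/origin/seasonality attribute codes) to a presence cell set.
#' Sub-polygons are first filtered to the extant native breeding/resident
#' range: presence code 1 or 2, origin code 1, seasonal code 1 or 2. A cell
#' is classed as presence when the retained sub-polygons cover at least
#' `min_overlap` (default 10%) of its area. Overlap is computed by exact
#' polygon-rectangle clipping (Sutherland-Hodgman) plus the shoelace formula;
#' overlapping retained sub-polygons would be double counted, so ranges are
#' expected in the usual non-overlapping form.
#'
#' Polygon coordinates live in grid units: cell `(row, col)` spans
#' `x` in `[col, col + 1]` and `y` in `[n_rows - row - 1, n_rows - row]`
#' (y increases northward).
#'
#' @param range_polys A tibble with one row per sub-polygon: integer columns
#'   `presence`, `origin`, `seasonal` and a list-column `coords` of n x 2
#'   vertex matrices.
#' @param grid A [grid_spec()].
#' @param min_overlap Minimum covered fraction of a cell (inclusive).
#' @param species_id Used in error messages.
#' @return Sorted integer vector of presence cell ids.
#' @export
rasterize_range <- function(range_polys, grid, min_overlap = 0.10,
                            species_id = "<unknown>") {
  needed <- c("presence", "origin", "seasonal", "coords")
  if (!all(needed %in% names(range_polys))) {
    abort(sprintf(
      "Range table for species %s lacks columns %s.", species_id,
      paste(setdiff(needed, names(range_polys)), collapse = ", ")
    ))
  }
  kept <- range_polys |>
    filter(
      .data$presence %in% c(1L, 2L),
      .data$origin == 1L,
      .data$seasonal %in% c(1L, 2L)
    )
  if (nrow(kept) == 0) return(integer(0))
  for (i in seq_len(nrow(kept))) {
    p <- kept$coords[[i]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 ||
      any(!is.finite(p))) {
      abort(sprintf(
        "Invalid range geometry for species %s (sub-polygon %d).",
        species_id, i
      ))
    }
  }
  cells <- grid_cells(grid)
  overlap <- rep(0, nrow(cells))
  for (i in seq_len(nrow(kept))) {
    poly <- kept$coords[[i]]
    xr <- range(poly[, 1])
    yr <- range(poly[, 2])
    # candidate cells from the polygon bounding box only
    cand <- which(
      cells$col + 1 > xr[1] & cells$col < xr[2] &
        (grid$n_rows - cells$row) > yr[1] &
        (grid$n_rows - cells$row - 1) < yr[2]
    )
    for (j in cand) {
      x0 <- cells$col[j]
      y0 <- grid$n_rows - cells$row[j] - 1
      a <- clip_area_rect(poly, x0, x0 + 1, y0, y0 + 1)
      overlap[j] <- overlap[j] + a
    }
  }
  sort(cells$cell[overlap >= min_overlap - 1e-12])
}

# Area of `poly` clipped to the axis-aligned rectangle, via
# Sutherland-Hodgman against each of the four half-planes then shoelace.
clip_area_rect <- function(poly, xmin, xmax, ymin, ymax) {
  p <- poly
  clip_half <- function(p, inside, intersect) {
    if (nrow(p) == 0) return(p)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(p)
    for (i in seq_len(n)) {
      cur <- p[i, ]
      prev <- p[if (i == 1) n else i - 1, ]
      cur_in <- inside(cur)
      prev_in <- inside(prev)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(a, b, t) a + (b - a) * t
  p <- clip_half(p, function(v) v[1] >= xmin, function(a, b) {
    t <- (xmin - a[1]) / (b[1] - a[1])
    c(xmin, ix(a[2], b[2], t))
  })
  p <- clip_half(p, function(v) v[1] <= xmax, function(a, b) {
    t <- (xmax - a[1]) / (b[1] - a[1])
    c(xmax, ix(a[2], b[2], t))
  })
  p <- clip_half(p, function(v) v[2] >= ymin, function(a, b) {
    t <- (ymin - a[2]) / (b[2] - a[2])
    c(ix(a[1], b[1], t), ymin)
  })
  p <- clip_half(p, function(v) v[2] <= ymax, function(a, b) {
    t <- (ymax - a[2]) / (b[2] - a[2])
    c(ix(a[1], b[1], t), ymax)
  })
  if (nrow(p) < 3) return(0)
  x <- p[, 1]
  y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Exclude range-restricted species
#'
#' Species present in fewer than `min_cells` grid cells are excluded from
#' modelling (climate is unlikely to determine such restricted
#' distributions); the boundary is inclusive, so a species with exactly
#' `min_cells` presences is retained.
#'
#' @param species A `species_table` (needs `species_id` and `presence`).
#' @param min_cells Minimum presence-cell count (default 10).
#' @return A list: `retained` (filtered species table) and `excluded`
#'   (tibble `species_id`, `n_presence`, `empty`).
#' @export
filter_restricted <- function(species, min_cells = 10) {
  n <- map_int(species$presence, length)
  excluded <- tibble(
    species_id = species$species_id[n < min_cells],
    n_presence = n[n < min_cells],
    empty = n[n < min_cells] == 0L
  )
  list(
    retained = species[n >= min_cells, , drop = FALSE],
    excluded = excluded
  )
}

#' Sample pseudoabsences and assemble an occurrence table
#'
#' Draws `n_pseudo` pseudoabsence cells uniformly without replacement from
#' the cells of the zoogeographic realm(s) in which the species has at least
#' one presence cell, excluding the presence cells themselves. When fewer
#' eligible cells exist, all of them are taken and the shortfall is reported
#' via a message; zero eligible cells is an error. Presence rows and
#' pseudoabsence rows are bound together with the current-climate variable
#' values attached and an (initially `NA`) `block` column.
#'
#' @param species_row One row of a `species_table`.
#' @param regions Output of [gen_regions()].
#' @param climate A `climate_table` (current epoch is used).
#' @param n_pseudo Number of pseudoabsence cells (default 1000).
#' @param seed Integer seed.
#' @param variables Climate variable columns to attach.
#' @return An occurrence tibble: `species_id`, `cell`, `row`, `col`, `label`
#'   (`"presence"`/`"pseudoabsence"`), `block` (`NA`), plus one column per
#'   variable.
#' @export
sample_pseudoabsences <- function(species_row, regions, climate,
                                  n_pseudo = 1000, seed = 1,
                                  variables = bioclim_vars()$variable) {
  presence <- species_row$presence[[1]]
  if (length(presence) == 0) {
    abort(sprintf(
      "Species %s has no presence cells.", species_row$species_id
    ))
  }
  map <- regions$map
  occ_realms <- unique(map$realm[match(presence, map$cell)])
  eligible <- map$cell[map$realm %in% occ_realms]
  eligible <- setdiff(eligible, presence)
  if (length(eligible) == 0) {
    abort(sprintf(
      "No eligible pseudoabsence cells for species %s (realm fully occupied).",
      species_row$species_id
    ))
  }
  set.seed(seed)
  if (length(eligible) < n_pseudo) {
    inform(sprintf(
      "Species %s: only %d eligible pseudoabsence cells (requested %d).",
      species_row$species_id, length(eligible), n_pseudo
    ))
    drawn <- eligible
  } else {
    drawn <- sample(sort(eligible), n_pseudo)
  }
  cur <- climate |> filter(.data$epoch == "current")
  rows <- tibble(
    species_id = species_row$species_id,
    cell = c(presence, sort(drawn)),
    label = rep(
      c("presence", "pseudoabsence"),
      c(length(presence), length(drawn))
    )
  ) |>
    inner_join(
      cur |> select("cell", "row", "col", all_of(variables)),
      by = "cell"
    ) |>
    mutate(block = NA_integer_, .after = "label") |>
    relocate("species_id", "cell", "row", "col", "label", "block")
  rows
}

#' Build occurrence tables for every retained species
#'
#' Composes [filter_restricted()] and [sample_pseudoabsences()] over a
#' species table, with per-species seeds derived from `seed`.
#'
#' @inheritParams sample_pseudoabsences
#' @param species A `species_table`.
#' @param min_cells Presence-count filter passed to [filter_restricted()].
#' @return A list: `tables` (named list of occurrence tibbles), `excluded`
#'   (exclusion report).
#' @export
build_occurrence_tables <- function(species, regions, climate,
                                    n_pseudo = 1000, seed = 1,
                                    min_cells = 10,
                                    variables = bioclim_vars()$variable) {
  flt <- filter_restricted(species, min_cells = min_cells)
  tables <- lapply(seq_len(nrow(flt$retained)), function(i) {
    sample_pseudoabsences(
      flt$retained[i, ], regions, climate,
      n_pseudo = n_pseudo,
      seed = stage_seed(seed, flt$retained$species_id[i]),
      variables = variables
    )
  })
  names(tables) <- flt$retained$species_id
  list(tables = tables, excluded = flt$excluded)
}
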