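#' Define an equal-area model grid
#'
#' The pipeline works on an abstract equal-area grid: every cell has the same
#' nominal area, so all area computations reduce to cell counts times
#' `cell_area`. Cells are identified by `(row, col)` with `row = 0` the
#' northernmost row; a scalar cell id `cell = row * n_cols + col + 1` is used
#' as the join key throughout. A nominal latitude (degrees) is attached to
#' each row, decreasing linearly from `lat_north` (row 0) to `lat_south`
#' (last row); it drives the latitudinal temperature gradient of the climate
#' generator and the latitude-linked national covariates.
#'
#' @param n_rows,n_cols Grid dimensions (both at least 4).
#' @param cell_area Nominal area of one cell (positive; arbitrary units).
#' @param lat_north,lat_south Nominal latitude of the first and last row.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 12)
#' grid_cells(g)
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 1,
                      lat_north = 65, lat_south = 0) {
  if (!is.numeric(n_rows) || length(n_rows) != 1 || n_rows < 4) {
    abort("`n_rows` must be a single integer >= 4.")
  }
  if (!is.numeric(n_cols) || length(n_cols) != 1 || n_cols < 4) {
    abort("`n_cols` must be a single integer >= 4.")
  }
  if (!is.numeric(cell_area) || length(cell_area) != 1 || cell_area <= 0) {
    abort("`cell_area` must be a single positive number.")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_area = as.numeric(cell_area),
      lat_north = lat_north, lat_south = lat_south
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells (area %g each), lat %g..%g\n",
    x$n_rows, x$n_cols, x$cell_area, x$lat_north, x$lat_south
  ))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Enumerate the cells of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `cell`, `row`, `col`, `lat` (one row per
#'   grid cell; `row`/`col` are 0-based).
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  tibble(
    cell = row * grid$n_cols + col + 1L,
    row = row, col = col,
    lat = grid$lat_north + row / (grid$n_rows - 1) *
      (grid$lat_south - grid$lat_north)
  )
}

cell_id <- function(grid, row, col) row * grid$n_cols + col + 1L

#' All 4-adjacent cell pairs of a grid
#'
#' Adjacency is rook-style (shared edge). Used both to derive country borders
#' and as the contiguity relation for ecoregion fragments.
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `cell_a`, `cell_b` (`cell_a < cell_b`).
#' @export
grid_adjacency <- function(grid) {
  cells <- grid_cells(grid)
  right <- cells |>
    filter(.data$col < grid$n_cols - 1L) |>
    transmute(cell_a = .data$cell, cell_b = .data$cell + 1L)
  down <- cells |>
    filter(.data$row < grid$n_rows - 1L) |>
    transmute(cell_a = .data$cell, cell_b = .data$cell + grid$n_cols)
  bind_rows(right, down) |> arrange(.data$cell_a, .data$cell_b)
}

# Connected-component labelling of a cell subset under 4-adjacency.
# `cells` is an integer vector of cell ids; returns an integer component
# label per input cell (components numbered by smallest member cell).
label_components <- function(grid, cells) {
  if (length(cells) == 0) return(integer(0))
  idx <- match(cells, cells)
  in_set <- logical(n_cells(grid))
  in_set[cells] <- TRUE
  pos <- integer(n_cells(grid))
  pos[cells] <- seq_along(cells)
  comp <- integer(length(cells))
  nc <- grid$n_cols
  label <- 0L
  for (start in order(cells)) {
    if (comp[start] != 0L) next
    label <- label + 1L
    queue <- cells[start]
    comp[start] <- label
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      row <- (cur - 1L) %/% nc
      col <- (cur - 1L) %% nc
      nb <- c(
        if (col > 0L) cur - 1L,
        if (col < nc - 1L) cur + 1L,
        if (row > 0L) cur - nc,
        if (row < grid$n_rows - 1L) cur + nc
      )
      nb <- nb[in_set[nb]]
      for (x in nb) {
        p <- pos[x]
        if (comp[p] == 0L) {
          comp[p] <- label
          queue <- c(queue, x)
        }
      }
    }
  }
  comp
}

# Separable Gaussian smoothing of a matrix (reflected edges). `sigma` in
# cell units controls the spatial autocorrelation range of generated fields.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_smooth <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    idx <- pmin(pmax(idx, 1L), n)
    padded <- v[idx]
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  m2 <- apply(m, 2, pad_smooth)
  t(apply(t(m2), 2, pad_smooth))
}
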