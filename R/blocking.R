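#' Summarise ecoregion fragments
#'
#' Fragments — the 4-connected components within each ecoregion — are the
#' sampling units of the spatial blocking. Each fragment is summarised by its
#' cell count, area and mean current climate over the selected variables.
#'
#' @param regions Output of [gen_regions()].
#' @param climate A `climate_table` (current epoch used).
#' @param grid A [grid_spec()] (for `cell_area`).
#' @param variables Climate variables to average.
#' @return Tibble: `fragment`, `ecoregion`, `n_cells`, `area`, one mean
#'   column per variable.
#' @export
build_fragments <- function(regions, climate, grid,
                            variables = default_predictors()) {
  cur <- climate |> filter(.data$epoch == "current")
  regions$map |>
    inner_join(cur |> select("cell", all_of(variables)), by = "cell") |>
    group_by(fragment = .data$fragment, ecoregion = .data$ecoregion) |>
    summarise(
      n_cells = dplyr::n(),
      across(all_of(variables), mean),
      .groups = "drop"
    ) |>
    mutate(area = .data$n_cells * grid$cell_area, .after = "n_cells") |>
    arrange(.data$fragment)
}

#' Group fragments into balanced spatial blocks
#'
#' Assigns fragments to `n_blocks` blocks so that total area and
#' area-weighted mean climate are approximately equal across blocks — the
#' construction behind spatially disaggregated cross-validation. The
#' assignment is greedy: fragments are sorted by area (descending, ties
#' broken by a seeded random order) and each is placed in the block that
#' minimises the running imbalance score of [block_imbalance()]. After
#' assignment, each block's climate envelope (min-max per variable) is
#' compared with the global envelope; coverage below `envelope_min` is
#' reported as a message, not an error.
#'
#' @param fragments Output of [build_fragments()].
#' @param n_blocks Number of blocks (default 10).
#' @param seed Integer seed (tie-breaking only).
#' @param variables Climate mean columns used in the balance score.
#' @param area_weight,climate_weight Relative weight of the two balance
#'   terms.
#' @param envelope_min Minimum per-variable envelope coverage expected of
#'   each block.
#' @return A list: `assignment` (tibble `fragment`, `block`), `summary`
#'   (per-block area and climate means), `imbalance` (final score),
#'   `envelope_ok` (logical matrix block x variable).
#' @export
assign_blocks <- function(fragments, n_blocks = 10, seed = 1,
                          variables = default_predictors(),
                          area_weight = 1, climate_weight = 1,
                          envelope_min = 0.8) {
  if (nrow(fragments) < n_blocks) {
    abort(paste0(
      "Fewer fragments (", nrow(fragments), ") than blocks (", n_blocks,
      "); use coarser ecoregions."
    ))
  }
  set.seed(seed)
  ord <- order(-fragments$area, sample.int(nrow(fragments)))
  frag <- fragments[ord, ]
  gsd <- vapply(variables, function(v) {
    s <- sd(frag[[v]])
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))

  block_area <- rep(0, n_blocks)
  block_wsum <- matrix(0, n_blocks, length(variables),
    dimnames = list(NULL, variables)
  )
  assignment <- integer(nrow(frag))
  score_state <- function(area, wsum) {
    ar <- area_weight * sd(area) / mean(fragments$area)
    filled <- area > 0
    cl <- 0
    if (sum(filled) > 1) {
      means <- sweep(wsum[filled, , drop = FALSE], 1, area[filled], "/")
      cl <- climate_weight *
        sum(apply(means, 2, sd) / gsd) / length(variables)
    }
    ar + cl
  }
  for (i in seq_len(nrow(frag))) {
    best <- NA_integer_
    best_score <- Inf
    # every block must end non-empty: while empty blocks remain, the next
    # (largest unassigned) fragment must open one of them
    cand <- if (any(block_area == 0)) {
      which(block_area == 0)
    } else {
      seq_len(n_blocks)
    }
    for (b in cand) {
      a2 <- block_area
      a2[b] <- a2[b] + frag$area[i]
      w2 <- block_wsum
      w2[b, ] <- w2[b, ] +
        frag$area[i] * as.numeric(frag[i, variables])
      s <- score_state(a2, w2)
      if (s < best_score - 1e-12) {
        best_score <- s
        best <- b
      }
    }
    assignment[i] <- best
    block_area[best] <- block_area[best] + frag$area[i]
    block_wsum[best, ] <- block_wsum[best, ] +
      frag$area[i] * as.numeric(frag[i, variables])
  }
  out <- tibble(fragment = frag$fragment, block = assignment) |>
    arrange(.data$fragment)

  summary <- frag |>
    mutate(block = assignment) |>
    group_by(block = .data$block) |>
    summarise(
      n_fragments = dplyr::n(),
      across(all_of(variables), ~ stats::weighted.mean(.x, .data$area)),
      area = sum(.data$area),
      .groups = "drop"
    )

  env <- envelope_coverage(frag, assignment, variables)
  low <- which(env < envelope_min, arr.ind = TRUE)
  if (nrow(low) > 0) {
    inform(sprintf(
      "%d block x variable envelope(s) cover < %.0f%% of the global range.",
      nrow(low), 100 * envelope_min
    ))
  }
  list(
    assignment = out,
    summary = summary,
    imbalance = score_state(block_area, block_wsum),
    envelope_ok = env >= envelope_min
  )
}

envelope_coverage <- function(frag, assignment, variables) {
  glob <- vapply(variables, function(v) diff(range(frag[[v]])), numeric(1))
  glob[glob == 0] <- 1
  blocks <- sort(unique(assignment))
  env <- matrix(0, length(blocks), length(variables),
    dimnames = list(blocks, variables)
  )
  for (b in seq_along(blocks)) {
    sub <- frag[assignment == blocks[b], , drop = FALSE]
    env[b, ] <- vapply(
      variables, function(v) diff(range(sub[[v]])), numeric(1)
    ) / glob
  }
  env
}

#' Imbalance score of a block assignment
#'
#' The objective the greedy grouping minimises: the between-block standard
#' deviation of total area (scaled by the mean fragment area) plus the mean
#' across variables of the between-block standard deviation of area-weighted
#' climate means (each scaled by that variable's between-fragment SD).
#' Lower is better; a perfectly symmetric assignment scores 0.
#'
#' @param fragments Output of [build_fragments()].
#' @param assignment Tibble `fragment`, `block` (as from [assign_blocks()]).
#' @param variables Climate mean columns.
#' @param area_weight,climate_weight Term weights.
#' @return A single non-negative score.
#' @export
block_imbalance <- function(fragments, assignment,
                            variables = default_predictors(),
                            area_weight = 1, climate_weight = 1) {
  dat <- fragments |> inner_join(assignment, by = "fragment")
  gsd <- vapply(variables, function(v) {
    s <- sd(fragments[[v]])
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  per_block <- dat |>
    group_by(block = .data$block) |>
    summarise(
      across(all_of(variables), ~ stats::weighted.mean(.x, .data$area)),
      area = sum(.data$area),
      .groups = "drop"
    )
  ar <- area_weight * sd(per_block$area) / mean(fragments$area)
  cl <- if (nrow(per_block) > 1) {
    climate_weight * sum(vapply(
      variables, function(v) sd(per_block[[v]]), numeric(1)
    ) / gsd) / length(variables)
  } else 0
  ar + cl
}

#' Attach block labels to an occurrence table
#'
#' Each occurrence row inherits the block of the fragment containing its
#' cell; rows are otherwise untouched.
#'
#' @param occ An occurrence tibble.
#' @param assignment Tibble `fragment`, `block`.
#' @param regions Output of [gen_regions()].
#' @return The occurrence tibble with `block` filled in.
#' @export
label_occurrences <- function(occ, assignment, regions) {
  frag_block <- setNames(assignment$block, assignment$fragment)
  frag_of <- regions$map$fragment[match(occ$cell, regions$map$cell)]
  if (anyNA(frag_of)) abort("Occurrence cell not covered by the region map.")
  occ$block <- as.integer(frag_block[as.character(frag_of)])
  if (anyNA(occ$block)) abort("Occurrence fragment missing from assignment.")
  occ
}
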