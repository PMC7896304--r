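#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end run, with one section per stage.
#' Unknown keys anywhere in a supplied config are rejected, so typos cannot
#' silently fall back to defaults. All stage randomness derives from the
#' single `seed` through per-stage seeds.
#'
#' @param seed Global seed.
#' @return Nested named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    world = list(
      n_rows = 20, n_cols = 20, n_realms = 2, n_ecoregions = 12,
      n_countries = 6, n_species = 10, autocorr_range = 3,
      niche_breadth_low = 0.5, niche_breadth_high = 1.5,
      prevalence_low = 0.1, prevalence_high = 0.4,
      barrier_frac = 0.3, gradient_strength = 1
    ),
    prep = list(n_pseudo = 1000, min_cells = 10),
    selection = list(
      run = TRUE, min_size = 3, max_size = 8, r_max = 0.7,
      n_test_species = 8
    ),
    blocking = list(n_blocks = 10),
    ensemble = list(
      predictors = default_predictors(),
      families = c("glm_poly", "gam_spline", "random_forest", "boosted_trees"),
      scenario = "rcp85", min_projections = 20
    ),
    national = list(covariates = c("governance", "gdp", "co2")),
    borders = list(run = TRUE)
  )
}

validate_config <- function(config, template = default_config()) {
  walk_keys <- function(cfg, tmpl, path = "") {
    extra <- setdiff(names(cfg), names(tmpl))
    if (length(extra) > 0) {
      abort(sprintf(
        "Unknown config key(s): %s",
        paste0(path, extra, collapse = ", ")
      ))
    }
    for (k in names(cfg)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]]))) {
        if (!is.list(cfg[[k]])) abort(sprintf("Config key %s%s must be a section.", path, k))
        walk_keys(cfg[[k]], tmpl[[k]], paste0(path, k, "."))
      }
    }
  }
  walk_keys(config, template)
  utils::modifyList(template, config)
}

#' Read a pipeline configuration from YAML
#'
#' The file holds any subset of the keys of [default_config()]; missing
#' keys take their defaults and unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A validated config list.
#' @export
read_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- seed
  validate_config(cfg, default_config(seed = cfg$seed %||% 1))
}

pipeline_stages <- function() {
  c(
    "world", "prep", "select", "block", "ensemble", "project",
    "national", "borders"
  )
}

#' Run one pipeline stage
#'
#' Executes a single named stage against the in-memory pipeline state,
#' checking that the upstream artifacts it needs are present, and appends a
#' provenance record (stage, derived seed, config hash, timestamp, output
#' counts).
#'
#' @param stage One of `world`, `prep`, `select`, `block`, `ensemble`,
#'   `project`, `national`, `borders`.
#' @param config A config list (see [default_config()]).
#' @param state Pipeline state from earlier stages (empty list to start).
#' @return The updated state, with `state[[stage]]` filled and
#'   `state$provenance` extended.
#' @export
run_stage <- function(stage, config = default_config(), state = list()) {
  stage <- match.arg(stage, pipeline_stages())
  config <- validate_config(config, default_config(config$seed %||% 1))
  need <- function(what) {
    if (is.null(state[[what]])) {
      abort(sprintf(
        "Stage '%s' needs the '%s' artifact; run that stage first.",
        stage, what
      ))
    }
  }
  seed <- stage_seed(config$seed, stage)
  t0 <- Sys.time()
  counts <- list()

  if (stage == "world") {
    w <- config$world
    state$world <- gen_world(
      n_rows = w$n_rows, n_cols = w$n_cols, n_realms = w$n_realms,
      n_ecoregions = w$n_ecoregions, n_countries = w$n_countries,
      n_species = w$n_species, seed = config$seed,
      autocorr_range = w$autocorr_range,
      niche_breadth_range = c(w$niche_breadth_low, w$niche_breadth_high),
      prevalence_range = c(w$prevalence_low, w$prevalence_high),
      barrier_frac = w$barrier_frac,
      gradient_strength = w$gradient_strength
    )
    counts <- list(
      n_species = nrow(state$world$species),
      n_borders = nrow(state$world$regions$borders)
    )
  } else if (stage == "prep") {
    need("world")
    w <- state$world
    state$prep <- build_occurrence_tables(
      w$species, w$regions, w$climate,
      n_pseudo = config$prep$n_pseudo, seed = seed,
      min_cells = config$prep$min_cells
    )
    counts <- list(
      n_retained = length(state$prep$tables),
      n_excluded = nrow(state$prep$excluded)
    )
  } else if (stage == "select") {
    need("world")
    need("prep")
    state$select <- run_selection_stage(config, state, seed)
    counts <- list(
      n_candidates = sum(state$select$subsets$status == "final_pool"),
      winner = paste(state$select$winner, collapse = "+")
    )
  } else if (stage == "block") {
    need("world")
    w <- state$world
    frags <- build_fragments(
      w$regions, w$climate, w$grid,
      variables = config$ensemble$predictors
    )
    asg <- assign_blocks(
      frags,
      n_blocks = config$blocking$n_blocks, seed = seed,
      variables = config$ensemble$predictors
    )
    state$block <- c(list(fragments = frags), asg)
    counts <- list(
      n_fragments = nrow(frags), imbalance = asg$imbalance
    )
  } else if (stage == "ensemble") {
    need("world")
    need("prep")
    need("block")
    state$ensemble <- run_ensemble_stage(config, state, seed)
    counts <- list(
      n_species = length(state$ensemble$current),
      n_models = sum(state$ensemble$audit$n_fits),
      n_future_projections = sum(state$ensemble$audit$n_future_projections)
    )
  } else if (stage == "project") {
    need("world")
    need("ensemble")
    grid <- state$world$grid
    cur <- richness_map(state$ensemble$current, grid)
    fut <- richness_map(state$ensemble$future, grid)
    state$project <- list(
      richness_current = cur, richness_future = fut,
      change = percent_change_map(cur, fut)
    )
    counts <- list(
      total_current_richness = sum(cur$richness),
      total_future_richness = sum(fut$richness)
    )
  } else if (stage == "national") {
    need("world")
    need("project")
    nat <- national_mean_change(state$project$change, state$world$regions)
    fits <- lapply(config$national$covariates, function(cv) {
      tryCatch(
        fit_covariate_model(nat, state$world$covariates, covariate = cv),
        error = function(e) NULL
      )
    })
    names(fits) <- config$national$covariates
    state$national <- list(
      change_table = nat,
      fits = fits,
      coefficients = bind_rows(lapply(
        fits[!vapply(fits, is.null, logical(1))], glance
      ))
    )
    counts <- list(n_countries = nrow(nat))
  } else if (stage == "borders") {
    need("world")
    need("ensemble")
    if (isTRUE(config$borders$run)) {
      state$borders <- run_borders_stage(config, state)
      counts <- list(
        share_transboundary = state$borders$share_transboundary,
        n_blocked = state$borders$barrier$n_blocked
      )
    }
  }

  prov <- tibble(
    stage = stage, seed = seed,
    config_hash = rlang::hash(config),
    started = format(t0), elapsed_s = as.numeric(Sys.time() - t0, "secs"),
    counts = list(counts)
  )
  state$provenance <- bind_rows(state$provenance, prov)
  state
}

run_selection_stage <- function(config, state, seed) {
  sel <- config$selection
  subsets <- enumerate_subsets(
    bioclim_vars()$variable,
    min_size = sel$min_size, max_size = sel$max_size
  ) |>
    filter_class_balance() |>
    filter_collinearity(
      state$world$climate |> filter(.data$epoch == "current"),
      r_max = sel$r_max
    )
  if (!isTRUE(sel$run)) {
    return(list(
      subsets = subsets, tally = NULL, winner = config$ensemble$predictors
    ))
  }
  tables <- state$prep$tables
  set.seed(seed)
  take <- sample(names(tables), min(sel$n_test_species, length(tables)))
  ranked <- rank_by_quartile_tally(subsets, tables[take])
  list(subsets = subsets, tally = ranked$tally, winner = ranked$winner)
}

run_ensemble_stage <- function(config, state, seed) {
  w <- state$world
  ens <- config$ensemble
  tables <- state$prep$tables
  climate <- w$climate
  future_slices <- lapply(gcm_ids(), function(g) {
    climate_slice(climate, "future", scenario = ens$scenario, gcm = g)
  })
  current_slice <- climate_slice(climate, "current")
  sp_tbl <- w$species
  audit <- list()
  current <- list()
  future <- list()
  fit_meta <- list()
  for (sp_id in names(tables)) {
    occ <- label_occurrences(
      tables[[sp_id]], state$block$assignment, w$regions
    )
    fits <- fit_species_ensemble(
      occ,
      predictors = ens$predictors,
      seed = stage_seed(seed, sp_id), families = ens$families
    )
    sp_row <- sp_tbl[sp_tbl$species_id == sp_id, ]
    domain <- projection_domain(sp_row, w$regions, w$grid)
    cur_pr <- ensemble_project(
      fits, current_slice, domain,
      min_projections = ens$min_projections
    )
    fut_pr <- ensemble_project(
      fits, future_slices, domain,
      min_projections = ens$min_projections
    )
    current[[sp_id]] <- cur_pr
    future[[sp_id]] <- fut_pr
    audit[[sp_id]] <- tibble(
      species_id = sp_id,
      n_fits = nrow(fits),
      n_usable = sum(!is.na(fits$auc)),
      mean_auc = mean(fits$auc, na.rm = TRUE),
      n_current_projections = attr(cur_pr, "n_projections"),
      n_future_projections = attr(fut_pr, "n_projections"),
      unreliable = attr(fut_pr, "unreliable")
    )
    fit_meta[[sp_id]] <- fits |>
      select("species_id", "family", "block", "auc", "threshold", "n_train")
    rm(fits) # model objects can be large; only projections are kept
  }
  list(
    current = current, future = future,
    audit = bind_rows(audit), fit_table = bind_rows(fit_meta),
    scenario = ens$scenario
  )
}

run_borders_stage <- function(config, state) {
  w <- state$world
  borders <- w$regions$borders
  cs <- current_country_set(w$species, w$regions)
  bisect <- border_bisection_counts(w$species, borders, w$regions) |>
    transboundary_richness_fraction(w$species, w$regions)
  profiles <- new_country_fraction(
    w$species, state$ensemble$future, w$regions
  )
  shifts <- per_border_shift_counts(
    w$species, state$ensemble$future, borders, w$regions
  )
  barrier <- barrier_blocked_species(
    w$species, state$ensemble$future, borders, w$regions
  )
  list(
    country_sets = cs,
    share_transboundary = mean(cs$transboundary),
    bisection = bisect,
    profiles = profiles,
    new_country_summary = summarise_new_country(profiles),
    shifts = shifts,
    barrier = barrier
  )
}

#' Run the full pipeline
#'
#' Chains every stage — world generation, occurrence prep, predictor
#' selection, spatial blocking, the model ensemble with current and future
#' projections, richness aggregation, national covariate models and the
#' border analyses — and optionally writes the tabular artifacts of each
#' stage to `outdir` as CSV plus a JSON provenance log.
#'
#' @param config A config list (see [default_config()]).
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return The full pipeline state (invisibly a list by stage).
#' @export
run_all <- function(config = default_config(), outdir = NULL) {
  state <- list()
  for (stage in pipeline_stages()) {
    state <- run_stage(stage, config, state)
  }
  if (!is.null(outdir)) write_pipeline_outputs(state, outdir)
  state
}

write_pipeline_outputs <- function(state, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
      row.names = FALSE
    )
  }
  w <- state$world
  wr(w$regions$map, "regions")
  wr(w$regions$borders, "borders")
  wr(w$regions$border_cells, "border_cells")
  wr(w$covariates, "covariates")
  wr(
    w$species |> select(-"presence", -"truth") |>
      mutate(across(where(is.logical), as.integer)),
    "species"
  )
  wr(
    w$species |>
      select("species_id", "presence") |>
      unnest("presence") |>
      rename(cell = "presence"),
    "presences"
  )
  wr(w$climate, "climate")
  if (!is.null(state$prep)) {
    wr(bind_rows(state$prep$tables), "occurrences")
    wr(state$prep$excluded, "excluded_species")
  }
  if (!is.null(state$select)) {
    subsets <- state$select$subsets |>
      mutate(members = map_chr(.data$members, paste, collapse = "|"))
    wr(subsets, "selection_subsets")
    if (!is.null(state$select$tally)) {
      wr(
        state$select$tally |>
          mutate(members = map_chr(.data$members, paste, collapse = "|")),
        "selection_tally"
      )
    }
  }
  if (!is.null(state$block)) {
    wr(state$block$fragments, "fragments")
    wr(state$block$assignment, "block_assignment")
    wr(state$block$summary, "block_summary")
  }
  if (!is.null(state$ensemble)) {
    wr(state$ensemble$audit, "model_audit")
    wr(state$ensemble$fit_table, "model_fits")
    wr(
      bind_rows(lapply(state$ensemble$current, identity), .id = "species_id"),
      "projection_current"
    )
    wr(
      bind_rows(lapply(state$ensemble$future, identity), .id = "species_id"),
      "projection_future"
    )
  }
  if (!is.null(state$project)) {
    wr(state$project$richness_current, "richness_current")
    wr(state$project$richness_future, "richness_future")
    wr(state$project$change, "richness_change")
  }
  if (!is.null(state$national)) {
    wr(state$national$change_table, "national_change")
    wr(state$national$coefficients, "covariate_models")
  }
  if (!is.null(state$borders)) {
    wr(state$borders$bisection, "border_bisection")
    wr(
      state$borders$profiles |>
        select(-"countries", -"future_countries"),
      "species_shift_profiles"
    )
    wr(state$borders$shifts$border_stats, "border_shifts")
    wr(state$borders$barrier$per_barrier, "barrier_shifts")
    wr(state$borders$new_country_summary, "new_country_summary")
  }
  if (!is.null(state$provenance)) {
    jsonlite::write_json(
      state$provenance |> mutate(counts = map(.data$counts, identity)),
      file.path(outdir, "provenance.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(outdir)
}
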