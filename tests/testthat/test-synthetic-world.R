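test_that("grid specification validates inputs and enumerates cells", {
  expect_error(grid_spec(3, 10), "n_rows")
  expect_error(grid_spec(10, 10, cell_area = 0), "cell_area")
  g <- grid_spec(5, 7)
  cells <- grid_cells(g)
  expect_equal(nrow(cells), 35)
  expect_equal(cells$cell, 1:35)
  expect_equal(cells$lat[1], g$lat_north)
  expect_equal(cells$lat[35], g$lat_south)
})

test_that("climate generation is deterministic and respects zero deltas", {
  g <- grid_spec(8, 8)
  c1 <- gen_climate(g, seed = 5)
  c2 <- gen_climate(g, seed = 5)
  expect_identical(c1, c2)
  expect_error(gen_climate(g, seed = 1, autocorr_range = 0), "autocorr_range")

  cz <- gen_climate(g, seed = 5, future_delta_spec = delta_spec_zero())
  cur <- dplyr::filter(cz, epoch == "current")
  for (sc in c("rcp26", "rcp85")) {
    fut <- climate_slice(cz, "future", sc, "gcm1")
    for (v in bioclim_vars()$variable) {
      expect_equal(fut[[v]], cur[[v]])
    }
  }
})

test_that("non-negative layers stay non-negative in every epoch", {
  clim <- gen_climate(grid_spec(10, 10), seed = 9, noise_sd = 6)
  for (v in c("prec_mean", "prec_wettest", "prec_driest", "prec_seasonality",
              "temp_seasonality")) {
    expect_true(all(clim[[v]] >= 0), info = v)
  }
})

test_that("configured warming shift is recovered from the generated fields", {
  g <- grid_spec(20, 20)
  spec <- delta_spec_default(gcm_noise_sd = 0.02)
  clim <- gen_climate(g, seed = 21, future_delta_spec = spec)
  cur <- dplyr::filter(clim, epoch == "current")
  shift_cfg <- unname(spec$shifts$shift[
    spec$shifts$scenario == "rcp85" & spec$shifts$variable == "temp_mean"
  ])
  # gcm2 carries multiplier 1, so its mean shift equals the configured one
  fut <- climate_slice(clim, "future", "rcp85", "gcm2")
  expect_equal(
    mean(fut$temp_mean) - mean(cur$temp_mean), shift_cfg,
    tolerance = 0.05
  )
  # scenario severity ordering: the high-emissions analogue warms most
  mean_shift <- function(sc) {
    mean(vapply(gcm_ids(), function(gc) {
      mean(climate_slice(clim, "future", sc, gc)$temp_mean)
    }, numeric(1))) - mean(cur$temp_mean)
  }
  shifts <- vapply(c("rcp26", "rcp45", "rcp60", "rcp85"), mean_shift, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("region maps partition the grid and realms are contiguous bands", {
  w <- tiny_world()
  map <- w$regions$map
  expect_false(anyNA(map$realm))
  expect_false(anyNA(map$ecoregion))
  expect_false(anyNA(map$fragment))
  expect_false(anyNA(map$country))
  expect_equal(sort(unique(map$cell)), grid_cells(w$grid)$cell)
  # each fragment lies within exactly one ecoregion
  frag_eco <- dplyr::distinct(map, fragment, ecoregion)
  expect_equal(nrow(frag_eco), length(unique(map$fragment)))
  # realm bands: each column belongs to one realm
  col_realm <- dplyr::distinct(map, col, realm)
  expect_equal(nrow(col_realm), length(unique(map$col)))
})

test_that("fragments are 4-connected components of their ecoregion", {
  w <- tiny_world()
  map <- w$regions$map
  for (f in unique(map$fragment)) {
    cells <- map$cell[map$fragment == f]
    comp <- borderniche:::label_components(w$grid, cells)
    expect_equal(length(unique(comp)), 1, info = paste("fragment", f))
  }
})

test_that("a one-country world has no borders", {
  reg <- gen_regions(grid_spec(6, 6), 1, 2, 1, seed = 3)
  expect_equal(nrow(reg$borders), 0)
  expect_equal(nrow(reg$border_cells), 0)
})

test_that("a straight two-country split yields one border with 6 cell pairs", {
  g <- grid_spec(6, 6)
  country_of <- ifelse(grid_cells(g)$col < 3, 1L, 2L)
  graph <- borderniche:::build_border_graph(g, country_of, barrier_frac = 0)
  expect_equal(nrow(graph$borders), 1)
  expect_equal(nrow(graph$border_cells), 6)
  expect_false(any(graph$borders$barrier))
})

test_that("the border graph matches a brute-force adjacency scan", {
  w <- border_world()
  map <- w$regions$map
  g <- w$grid
  # oracle: scan all horizontally/vertically adjacent cell pairs
  oracle <- list()
  for (r in 0:(g$n_rows - 1)) {
    for (cl in 0:(g$n_cols - 1)) {
      a <- r * g$n_cols + cl + 1L
      for (d in list(c(0, 1), c(1, 0))) {
        r2 <- r + d[1]; c2 <- cl + d[2]
        if (r2 >= g$n_rows || c2 >= g$n_cols) next
        b <- r2 * g$n_cols + c2 + 1L
        ca <- map$country[map$cell == a]
        cb <- map$country[map$cell == b]
        if (ca != cb) {
          oracle[[length(oracle) + 1]] <- c(min(ca, cb), max(ca, cb))
        }
      }
    }
  }
  oracle_edges <- unique(do.call(rbind, oracle))
  oracle_edges <- oracle_edges[order(oracle_edges[, 1], oracle_edges[, 2]), ]
  got <- as.matrix(w$regions$borders[, c("country_a", "country_b")])
  dimnames(got) <- NULL
  expect_equal(got, oracle_edges)
  expect_equal(nrow(w$regions$border_cells), length(oracle))
  expect_false(any(w$regions$borders$country_a == w$regions$borders$country_b))
})

test_that("species generation is deterministic with presences above cutoff", {
  w <- tiny_world()
  sp1 <- gen_species(w$climate, w$regions, n_species = 4, seed = 99)
  sp2 <- gen_species(w$climate, w$regions, n_species = 4, seed = 99)
  expect_identical(sp1, sp2)
  cur <- climate_slice(w$climate, "current")
  for (i in seq_len(nrow(sp1))) {
    truth <- sp1$truth[[i]]
    suit <- niche_suitability(truth, cur)
    occupied <- cur$cell %in% sp1$presence[[i]]
    # presences are exactly the super-threshold suitability cells
    expect_true(min(suit[occupied]) >= max(suit[!occupied]))
    expect_equal(sort(cur$cell[suit >= truth$cutoff]), sp1$presence[[i]])
    # and true_occupancy reproduces them under the current climate
    expect_equal(true_occupancy(sp1[i, ], cur), sp1$presence[[i]])
  }
})

test_that("an extremely broad niche saturates suitability everywhere", {
  w <- tiny_world()
  cur <- climate_slice(w$climate, "current")
  truth <- list(
    variables = "temp_mean",
    optimum = list(temp_mean = mean(cur$temp_mean)),
    breadth = list(temp_mean = 1e6),
    sd_ref = list(temp_mean = sd(cur$temp_mean)),
    cutoff = 0.5
  )
  expect_true(all(niche_suitability(truth, cur) > 0.999))
  row <- tibble::tibble(truth = list(truth))
  expect_equal(true_occupancy(row, cur), sort(cur$cell))
})

test_that("covariates respect documented ranges and the latitude gradient", {
  reg <- gen_regions(grid_spec(20, 20), 2, 10, 30, seed = 4)
  cov <- gen_covariates(reg, seed = 5, gradient_strength = 1)
  expect_equal(nrow(cov), 30)
  gov_cols <- paste0("gov", 1:6)
  for (gc in gov_cols) {
    expect_true(all(cov[[gc]] >= -2.5 & cov[[gc]] <= 2.5))
  }
  expect_true(all(cov$gdp_per_capita > 0))
  expect_true(all(cov$co2_per_capita > 0))
  expect_true(cor(cov$governance, cov$mean_lat) > 0.5)

  # no built-in signal without the gradient: correlation near zero on average
  cors <- vapply(1:8, function(s) {
    cv <- gen_covariates(reg, seed = s, gradient_strength = 0)
    cor(cv$governance, cv$mean_lat)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.25)
})

test_that("governance score is the row mean of the six indicators", {
  cov <- tibble::tibble(
    country = 1:3,
    gov1 = c(0, -1, 0.3), gov2 = c(0, -1, 0.1), gov3 = c(0, -1, -0.2),
    gov4 = c(0, 1, 0.5), gov5 = c(0, 1, -0.4), gov6 = c(0, 1, 0.9)
  )
  out <- governance_score(cov)
  expect_equal(out$governance[1], 0)
  expect_equal(out$governance[2], 0)
  expect_equal(out$governance[3], mean(c(0.3, 0.1, -0.2, 0.5, -0.4, 0.9)))
})
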