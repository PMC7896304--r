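#' Enumerate candidate predictor subsets
#'
#' All subsets of the candidate variables with sizes between `min_size` and
#' `max_size`, each exactly once. With the default eight candidates and
#' sizes 3..8 this yields 219 subsets.
#'
#' @param variables Character vector of distinct variable names.
#' @param min_size,max_size Inclusive subset-size bounds.
#' @return A tibble: `subset_id`, `size`, list-column `members`, and
#'   `status = "candidate"`.
#' @examples
#' nrow(enumerate_subsets(bioclim_vars()$variable)) # 219
#' @export
enumerate_subsets <- function(variables, min_size = 3,
                              max_size = length(variables)) {
  if (anyDuplicated(variables)) abort("`variables` must be distinct.")
  if (min_size < 1 || max_size > length(variables) || min_size > max_size) {
    abort("Invalid subset size bounds.")
  }
  members <- unlist(
    lapply(min_size:max_size, function(k) {
      combn(variables, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  tibble(
    subset_id = seq_along(members),
    size = lengths(members),
    members = members,
    status = "candidate"
  )
}

#' Discard subsets lacking a climate class
#'
#' A subset is retained only when it contains at least one temperature-class
#' and one precipitation-class variable; models driven by a single climate
#' dimension are not considered. Over the canonical 219 subsets this
#' discards 10 (retaining 209).
#'
#' @param subsets Output of [enumerate_subsets()].
#' @param classes Tibble `variable`, `class`; defaults to [bioclim_vars()].
#' @return The subsets tibble with `status` updated to `"discarded_class"`
#'   for unbalanced subsets.
#' @export
filter_class_balance <- function(subsets, classes = bioclim_vars()) {
  class_of <- setNames(classes$class, classes$variable)
  ok <- map_lgl(subsets$members, function(m) {
    cls <- class_of[m]
    if (anyNA(cls)) abort("Subset contains a variable with no class.")
    length(unique(cls)) >= 2
  })
  subsets$status[!ok & subsets$status == "candidate"] <- "discarded_class"
  subsets
}

#' Discard collinear subsets
#'
#' A subset is discarded when any pair of its members has absolute pairwise
#' Pearson correlation strictly greater than `r_max` over the supplied cell
#' sample (a pair at exactly `r_max` is retained). A constant variable, whose
#' correlation is undefined, is treated as a violation.
#'
#' @param subsets Subset tibble (only rows still `"candidate"` are tested).
#' @param climate_sample Tibble of cells with the variable columns.
#' @param r_max Collinearity threshold (default 0.7).
#' @return The subsets tibble with `status` updated to
#'   `"discarded_collinear"` where violated, `"final_pool"` otherwise.
#' @export
filter_collinearity <- function(subsets, climate_sample, r_max = 0.7) {
  vars <- sort(unique(unlist(subsets$members)))
  missing <- setdiff(vars, names(climate_sample))
  if (length(missing) > 0) {
    abort(paste("Climate sample lacks variables:", paste(missing, collapse = ", ")))
  }
  if (nrow(climate_sample) < 3) abort("Need at least 3 sample rows.")
  constant <- vars[vapply(
    vars, function(v) sd(climate_sample[[v]]) == 0, logical(1)
  )]
  if (length(constant) > 0) {
    warn(paste(
      "Constant variable(s) treated as collinearity violations:",
      paste(constant, collapse = ", ")
    ))
  }
  cm <- suppressWarnings(
    abs(cor(as.matrix(climate_sample[vars])))
  )
  ok <- map_lgl(subsets$members, function(m) {
    if (any(m %in% constant)) return(FALSE)
    sub <- cm[m, m, drop = FALSE]
    max(sub[upper.tri(sub)], -Inf) <= r_max + 1e-12
  })
  cand <- subsets$status == "candidate"
  subsets$status[cand & !ok] <- "discarded_collinear"
  subsets$status[cand & ok] <- "final_pool"
  subsets
}

#' Rank predictor subsets by AIC quartile tallies
#'
#' For each test species, one penalised additive model (thin-plate spline per
#' member variable, binomial/logit) is fitted per candidate subset on the
#' species' occurrence table; subsets are ranked by AIC (ascending, ties
#' broken by fewer members) and the best `ceiling(n/4)` subsets form the top
#' quartile. Each subset's tally counts its top-quartile appearances across
#' species; the winner is the subset with the largest tally, ties broken by
#' smaller size then lexicographic member order. Failed fits are logged and
#' skipped (the quartile is taken over the subsets that did fit for that
#' species).
#'
#' @param subsets Subset tibble; rows with `status == "final_pool"` (or
#'   `"candidate"` if no pool was marked) are ranked.
#' @param occ_tables Named list of occurrence tibbles (one per test species).
#' @param k Spline basis size per smooth.
#' @return A list: `tally` (tibble `subset_id`, `members`, `size`, `tally`,
#'   `share`), `winner` (character vector of member names),
#'   `n_species_tested`, `failures` (tibble of skipped fits).
#' @export
rank_by_quartile_tally <- function(subsets, occ_tables, k = 6) {
  pool <- subsets |> filter(.data$status %in% c("final_pool", "candidate"))
  if (nrow(pool) == 0) abort("No candidate subsets to rank.")
  failures <- list()
  tally <- setNames(rep(0L, nrow(pool)), pool$subset_id)
  for (sp in names(occ_tables)) {
    occ <- occ_tables[[sp]]
    aics <- rep(NA_real_, nrow(pool))
    for (i in seq_len(nrow(pool))) {
      fit <- tryCatch(
        fit_additive_spline(occ, pool$members[[i]], k = k),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        failures[[length(failures) + 1]] <- tibble(
          species_id = sp, subset_id = pool$subset_id[i]
        )
      } else {
        aics[i] <- AIC(fit)
      }
    }
    ok <- which(!is.na(aics))
    if (length(ok) == 0) next
    n_top <- ceiling(length(ok) / 4)
    ord <- ok[order(aics[ok], pool$size[ok])]
    top <- head(ord, n_top)
    tally[top] <- tally[top] + 1L
  }
  n_tested <- length(occ_tables)
  res <- pool |>
    mutate(
      tally = as.integer(tally),
      share = .data$tally / n_tested
    ) |>
    arrange(
      desc(.data$tally), .data$size,
      map_chr(.data$members, paste, collapse = ",")
    )
  list(
    tally = res |> select("subset_id", "members", "size", "tally", "share"),
    winner = res$members[[1]],
    n_species_tested = n_tested,
    failures = bind_rows(failures)
  )
}

# Penalised thin-plate additive logistic fit used by the subset ranking and
# by the spline family of the ensemble. bam(discrete = TRUE) is used for
# speed; fitted probabilities agree closely with gam() on these data sizes.
fit_additive_spline <- function(occ, variables, k = 6) {
  dat <- occ |> mutate(y = as.integer(.data$label == "presence"))
  rhs <- paste(sprintf("s(%s, k = %d)", variables, k), collapse = " + ")
  f <- as.formula(paste("y ~", rhs))
  suppressWarnings(tryCatch(
    mgcv::bam(f, family = binomial(), data = dat, discrete = TRUE),
    error = function(e) mgcv::gam(f, family = binomial(), data = dat)
  ))
}
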