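test_that("subset enumeration matches closed forms and a combn oracle", {
  s8 <- enumerate_subsets(bioclim_vars()$variable, 3, 8)
  expect_equal(nrow(s8), 219)
  expect_equal(sum(choose(8, 3:8)), 219)
  expect_equal(anyDuplicated(purrr::map_chr(s8$members, paste, collapse = ",")), 0)

  s1 <- enumerate_subsets(c("a", "b", "c"), 3, 3)
  expect_equal(nrow(s1), 1)

  s4 <- enumerate_subsets(c("w", "x", "y", "z"), 2, 4)
  oracle <- unlist(lapply(2:4, function(k) {
    combn(c("w", "x", "y", "z"), k, simplify = FALSE)
  }), recursive = FALSE)
  expect_equal(nrow(s4), length(oracle)) # 6 + 4 + 1 = 11
  expect_equal(nrow(s4), 11)

  expect_error(enumerate_subsets(c("a", "a", "b")), "distinct")
})

test_that("the class-balance filter discards exactly the one-class subsets", {
  s8 <- enumerate_subsets(bioclim_vars()$variable, 3, 8) |>
    filter_class_balance()
  expect_equal(sum(s8$status == "discarded_class"), 10)
  expect_equal(sum(s8$status == "candidate"), 209)

  # any all-temperature triple is among the discards
  temp3 <- enumerate_subsets(
    c("temp_mean", "temp_seasonality", "temp_max_warmest"), 3, 3
  ) |> filter_class_balance()
  expect_equal(temp3$status, "discarded_class")

  # 2 + 2 variables, sizes 2..4: brute-force count of one-class subsets
  classes <- tibble::tibble(
    variable = c("t1", "t2", "p1", "p2"),
    class = c("temperature", "temperature", "precipitation", "precipitation")
  )
  s4 <- enumerate_subsets(classes$variable, 2, 4) |>
    filter_class_balance(classes)
  oracle_discards <- sum(purrr::map_lgl(s4$members, function(m) {
    length(unique(classes$class[match(m, classes$variable)])) < 2
  }))
  expect_equal(sum(s4$status == "discarded_class"), oracle_discards)
  expect_equal(oracle_discards, 2) # {t1,t2} and {p1,p2}
})

test_that("enumeration plus class filter matches binomial sums for any split", {
  set.seed(4)
  for (n_temp in c(2, 3, 5)) {
    n_prec <- 8 - n_temp
    classes <- tibble::tibble(
      variable = paste0("v", 1:8),
      class = rep(c("temperature", "precipitation"), c(n_temp, n_prec))
    )
    s <- enumerate_subsets(classes$variable, 3, 8) |>
      filter_class_balance(classes)
    # one-class subsets of size k: C(n_temp, k) + C(n_prec, k)
    expected_discards <- sum(choose(n_temp, 3:8) + choose(n_prec, 3:8))
    expect_equal(sum(s$status == "discarded_class"), expected_discards)
  }
})

test_that("collinearity filtering is strict-inequality and constant-safe", {
  n <- 400
  set.seed(2)
  x <- as.numeric(scale(rnorm(n)))
  z <- as.numeric(scale(stats::resid(lm(rnorm(n) ~ x))))
  make_cor <- function(r) r * x + sqrt(1 - r^2) * z # exact sample correlation r
  sample_tbl <- tibble::tibble(
    a = x, b = make_cor(0.7), c = make_cor(0.71), d = a # duplicated variable
  )
  subsets <- enumerate_subsets(c("a", "b", "c", "d"), 2, 2)
  classes <- tibble::tibble(
    variable = c("a", "b", "c", "d"),
    class = c("temperature", "precipitation", "precipitation", "precipitation")
  )
  out <- subsets |>
    filter_class_balance(classes) |>
    filter_collinearity(sample_tbl, r_max = 0.7)
  status_of <- function(m) {
    out$status[purrr::map_lgl(out$members, ~ setequal(.x, m))]
  }
  expect_equal(status_of(c("a", "b")), "final_pool")          # r = 0.70 kept
  expect_equal(status_of(c("a", "c")), "discarded_collinear") # r = 0.71
  expect_equal(status_of(c("a", "d")), "discarded_collinear") # r = 1
})

test_that("independent variables keep all 209 class-balanced subsets", {
  set.seed(8)
  sample_tbl <- tibble::as_tibble(
    setNames(
      as.data.frame(matrix(rnorm(8 * 10000), ncol = 8)),
      bioclim_vars()$variable
    )
  )
  cm <- abs(cor(as.matrix(sample_tbl)))
  expect_true(max(cm[upper.tri(cm)]) < 0.7)
  out <- enumerate_subsets(bioclim_vars()$variable, 3, 8) |>
    filter_class_balance() |>
    filter_collinearity(sample_tbl)
  expect_equal(sum(out$status == "final_pool"), 209)
})

test_that("a constant variable is reported and treated as a violation", {
  sample_tbl <- tibble::tibble(a = rnorm(50), b = rnorm(50), k = 1)
  subsets <- enumerate_subsets(c("a", "b", "k"), 2, 3)
  subsets$status <- "candidate"
  expect_warning(
    out <- filter_collinearity(subsets, sample_tbl, r_max = 0.7),
    "Constant"
  )
  has_k <- purrr::map_lgl(out$members, ~ "k" %in% .x)
  expect_true(all(out$status[has_k] == "discarded_collinear"))
})

test_that("the collinearity filter is monotone in subset growth", {
  set.seed(11)
  n <- 300
  base <- matrix(rnorm(n * 5), n, 5)
  base[, 2] <- base[, 1] * 0.95 + rnorm(n, sd = 0.2) # one collinear pair
  sample_tbl <- tibble::as_tibble(setNames(as.data.frame(base), paste0("v", 1:5)))
  subsets <- enumerate_subsets(paste0("v", 1:5), 2, 5)
  subsets$status <- "candidate"
  out <- filter_collinearity(subsets, sample_tbl)
  key <- purrr::map_chr(out$members, ~ paste(sort(.x), collapse = ","))
  status <- setNames(out$status, key)
  for (i in seq_len(nrow(out))) {
    m <- out$members[[i]]
    if (status[[paste(sort(m), collapse = ",")]] != "discarded_collinear") next
    supersets <- out$members[purrr::map_lgl(out$members, ~ all(m %in% .x))]
    for (sup in supersets) {
      expect_equal(
        status[[paste(sort(sup), collapse = ",")]], "discarded_collinear"
      )
    }
  }
})

test_that("a single candidate subset trivially tops every quartile", {
  occ <- list(
    s1 = toy_occurrence(n = 120, seed = 1),
    s2 = toy_occurrence(n = 120, seed = 2)
  )
  subsets <- enumerate_subsets(c("v1", "v2", "v3"), 3, 3)
  res <- rank_by_quartile_tally(subsets, occ, k = 4)
  expect_equal(res$tally$tally, 2L)
  expect_equal(res$n_species_tested, 2)
  expect_equal(sort(res$winner), c("v1", "v2", "v3"))
})

test_that("subsets containing the true niche variables win the tally", {
  set.seed(33)
  n_sp <- 12
  occ <- lapply(seq_len(n_sp), function(i) {
    toy_occurrence(
      n = 150, n_vars = 5, seed = 100 + i,
      signal = function(X) 2.5 * X[, 1] - 2 * X[, 2]^2 + 1
    )
  })
  names(occ) <- paste0("s", seq_len(n_sp))
  subsets <- enumerate_subsets(paste0("v", 1:5), 3, 3)
  res <- rank_by_quartile_tally(subsets, occ, k = 4)
  has_truth <- purrr::map_lgl(res$tally$members, ~ all(c("v1", "v2") %in% .x))
  best_with <- max(res$tally$tally[has_truth])
  best_without <- max(res$tally$tally[!has_truth])
  expect_gt(best_with, best_without)
  expect_true(all(c("v1", "v2") %in% res$winner))
  # tally bookkeeping: each species contributes ceiling(n/4) appearances
  n_top <- ceiling(nrow(res$tally) / 4)
  expect_equal(sum(res$tally$tally), n_sp * n_top - nrow(res$failures))
})
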