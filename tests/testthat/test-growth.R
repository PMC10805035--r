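test_that("a perfect linear series is fit exactly", {
  s <- tibble::tibble(year = 2000:2004, unique_authors = 2 * (0:4) + 10)
  fit <- fit_linear(s)
  expect_equal(fit$slope, 2)
  expect_equal(fit$adj_r2, 1)
  expect_equal(fit$sigma, 0)
})

test_that("a toy series matches the closed-form normal equations", {
  s <- tibble::tibble(year = c(0, 1, 2), unique_authors = c(1, 3, 4))
  fit <- fit_linear(s)
  want <- ols_oracle(s$year, s$unique_authors)
  for (f in c("slope", "intercept", "adj_r2", "sigma", "f_stat")) {
    expect_equal(fit[[f]], want[[f]], tolerance = 1e-12)
  }
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$intercept, 7 / 6)
})

test_that("a constant series has zero slope and zero F", {
  s <- tibble::tibble(year = 2000:2005, unique_authors = 7)
  fit <- fit_linear(s)
  expect_equal(fit$slope, 0)
  expect_equal(fit$f_stat, 0)
})

test_that("an exactly exponential series recovers its rate on the log scale", {
  s <- tibble::tibble(year = 2000:2009, unique_authors = 100 * exp(0.05 * (0:9)))
  fit <- fit_exponential(s)
  expect_equal(fit$slope, 0.05, tolerance = 1e-9)
  expect_equal(fit$adj_r2, 1)
  expect_equal(fit$annual_growth_rate, exp(0.05) - 1, tolerance = 1e-9)
})

test_that("non-positive counts are dropped before the log, reducing n", {
  s <- tibble::tibble(year = 2000:2005, unique_authors = c(5, 0, 7, 9, 12, 16))
  fit <- fit_exponential(s)
  expect_equal(fit$n, 5)
  expect_equal(fit$n_dropped, 1)
})

test_that("fits agree with the normal-equations oracle on random series", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:15, 1)
    s <- tibble::tibble(
      year = sort(sample(1980:2020, n)),
      unique_authors = exp(stats::rnorm(n, 4, 1))
    )
    lin <- fit_linear(s)
    wl <- ols_oracle(s$year, s$unique_authors)
    ex <- fit_exponential(s)
    we <- ols_oracle(s$year, log(s$unique_authors))
    for (f in c("slope", "intercept", "adj_r2", "sigma", "f_stat")) {
      expect_equal(lin[[f]], wl[[f]], tolerance = 1e-9)
      expect_equal(ex[[f]], we[[f]], tolerance = 1e-9)
    }
    # defining identities hold exactly on every fit
    for (fit in list(lin, ex)) {
      expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - 2))
      expect_equal(fit$f_stat, fit$r2 / (1 - fit$r2) * (fit$n - 2))
    }
  }
})

test_that("shifting all years moves the intercept only", {
  set.seed(42)
  s <- tibble::tibble(year = 1990:2005, unique_authors = exp(stats::rnorm(16, 3, 0.5)))
  base <- fit_linear(s)
  shifted <- fit_linear(dplyr::mutate(s, year = year + 500))
  expect_equal(shifted$slope, base$slope, tolerance = 1e-9)
  expect_equal(shifted$adj_r2, base$adj_r2, tolerance = 1e-9)
  expect_equal(shifted$sigma, base$sigma, tolerance = 1e-9)
  expect_equal(shifted$f_stat, base$f_stat, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(shifted$intercept, base$intercept)))
})

test_that("degenerate inputs are hard errors", {
  expect_error(fit_linear(tibble::tibble(year = 1:2, unique_authors = 1:2)), "3")
  expect_error(
    fit_linear(tibble::tibble(year = c(5, 5, 5), unique_authors = 1:3)),
    "variance"
  )
  expect_error(
    fit_exponential(tibble::tibble(year = 1:5, unique_authors = c(1, 2, 0, 0, 0))),
    "3"
  )
})

test_that("model comparison prefers the generating model", {
  yrs <- 2000:2014
  exp_s <- tibble::tibble(year = yrs, unique_authors = 50 * exp(0.08 * (yrs - 2000)))
  expect_equal(compare_growth(exp_s)$preferred, "exponential")
  lin_s <- tibble::tibble(year = yrs, unique_authors = 50 + 12 * (yrs - 2000))
  expect_equal(compare_growth(lin_s)$preferred, "linear")
})

test_that("a rise-then-fall series is flagged as poorly fit by both models", {
  yrs <- 2000:2020
  tri <- tibble::tibble(
    year = yrs,
    unique_authors = 100 + 20 * (10 - abs(yrs - 2010))
  )
  cmp <- compare_growth(tri)
  # confirm with the oracle that both models really are poor here
  expect_lt(ols_oracle(yrs, tri$unique_authors)$adj_r2, 0.5)
  expect_lt(ols_oracle(yrs, log(tri$unique_authors))$adj_r2, 0.5)
  expect_lt(cmp$linear$adj_r2, 0.5)
  expect_lt(cmp$exponential$adj_r2, 0.5)
  expect_match(cmp$note, "poor fit")
})

test_that("tidy and glance views expose the fit-table columns", {
  s <- tibble::tibble(
    label = "toy", year = 2000:2009,
    unique_authors = round(30 * exp(0.07 * (0:9))), papers = 10
  )
  tab <- growth_fit_table(s)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$model, c("linear", "exponential"))
  expect_true(all(c("label", "model", "adj_r2", "sigma", "f_stat", "n") %in% names(tab)))
  g <- glance(compare_growth(s))
  expect_equal(g$preferred, "exponential")
  td <- tidy(fit_linear(s))
  expect_equal(td$term, c("intercept", "year"))
})
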