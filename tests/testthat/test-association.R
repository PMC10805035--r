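test_that("deflators derive from published adjusted/unadjusted pairs", {
  expect_equal(derive_deflator(2083159.08, 761372), 2.73606, tolerance = 1e-5)
  expect_equal(derive_deflator(37044435, 37044435), 1)
  expect_error(derive_deflator(100, 0), "positive")
})

test_that("same-year deflators agree across fields in the packaged table", {
  defl <- derive_deflators(fungal_field_data())
  spread <- defl |>
    dplyr::group_by(year) |>
    dplyr::summarise(rel = (max(deflator) - min(deflator)) / min(deflator), n = dplyr::n())
  expect_true(all(spread$rel < 1e-5))
  expect_gte(min(spread$n), 5) # all six fields except the Blastomyces 1996 gap
})

test_that("CPI adjustment is the identity at base year and invertible", {
  cpi <- cpi_table(data.frame(year = 2020:2022, index = c(258.8, 271.0, 292.7)))
  expect_equal(attr(cpi, "base_year"), 2022L)
  expect_equal(adjust_funding(5e6, 2022, cpi), 5e6)
  adj <- adjust_funding(5e6, 2020, cpi)
  back <- adj * 258.8 / 292.7
  expect_equal(back, 5e6, tolerance = 1e-12)
  expect_error(adjust_funding(1, 1999, cpi), "1999")
})

test_that("a CPI table built from the packaged deflators reproduces published amounts", {
  # index proportional to 1/deflator puts the base year at the latest year
  defl <- derive_deflators(fungal_field_data()) |>
    dplyr::filter(label == "Cryptococcus")
  cpi <- cpi_table(data.frame(year = defl$year, index = 100 / defl$deflator))
  got <- adjust_funding(1698140, 1990, cpi)
  expect_equal(got, 3825037.6, tolerance = 0.5 / 3825037.6)
})

test_that("funding per author divides on the year intersection", {
  funding <- tibble::tibble(year = c(2001, 2002, 2003), funding = c(1000, 2000, 500))
  series <- tibble::tibble(year = c(2001, 2002), unique_authors = c(10, 40))
  out <- funding_per_author(funding, series)
  expect_equal(out$year, c(2001, 2002))
  expect_equal(out$funding_per_author, c(100, 50))
  expect_error(
    funding_per_author(funding, tibble::tibble(year = 1990, unique_authors = 5)),
    "overlap"
  )
  expect_warning(
    z <- funding_per_author(funding, tibble::tibble(year = 2001:2002, unique_authors = c(0, 4))),
    "zero"
  )
  expect_equal(z$year, 2002)
})

test_that("funding per author respects gaps in the packaged series", {
  fd <- fungal_field_data()
  blasto <- fd |>
    dplyr::filter(label == "Blastomyces", inflation == "Adjusted") |>
    dplyr::select(label, year, funding)
  sizes <- fd |>
    dplyr::filter(label == "Blastomyces", inflation == "Adjusted") |>
    dplyr::select(label, year, unique_authors)
  out <- funding_per_author(blasto, sizes)
  expect_equal(nrow(out), 37) # 1985-2022 with no 1996 row
  expect_false(1996 %in% out$year)
})

test_that("funding per author scales linearly in funding, inversely in authors", {
  set.seed(7)
  funding <- tibble::tibble(year = 2001:2010, funding = stats::runif(10, 1e5, 1e7))
  series <- tibble::tibble(year = 2001:2010, unique_authors = sample(10:500, 10))
  base <- funding_per_author(funding, series)
  doubled <- funding_per_author(dplyr::mutate(funding, funding = 2 * funding), series)
  halved <- funding_per_author(funding, dplyr::mutate(series, unique_authors = 2L * unique_authors))
  expect_equal(doubled$funding_per_author, 2 * base$funding_per_author)
  expect_equal(halved$funding_per_author, base$funding_per_author / 2)
})

test_that("correlation handles perfect, reversed and tied data", {
  d <- tibble::tibble(x = 1:6, y = 1:6)
  out <- correlate(d, x, y)
  expect_equal(out$pearson, 1)
  expect_equal(out$spearman, 1)
  dec <- correlate(tibble::tibble(x = 1:6, y = exp(-(1:6))), x, y)
  expect_equal(dec$spearman, -1)
  # 5-point table with a tie against the brute-force rank oracle
  tied <- tibble::tibble(x = c(1, 2, 2, 3, 4), y = c(2, 1, 4, 4, 5))
  got <- correlate(tied, x, y)
  expect_equal(got$spearman, spearman_oracle(tied$x, tied$y), tolerance = 1e-12)
  expect_equal(got$pearson, pearson_oracle(tied$x, tied$y), tolerance = 1e-12)
  expect_error(correlate(tibble::tibble(x = 1:2, y = 1:2), x, y), "3")
  expect_warning(flat <- correlate(tibble::tibble(x = 1:5, y = rep(2, 5)), x, y), "variance")
  expect_true(flat$degenerate)
  expect_true(is.na(flat$pearson))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- tibble::tibble(x = stats::runif(12), y = stats::runif(12))
    base <- correlate(d, x, y)$spearman
    expect_equal(correlate(dplyr::mutate(d, x = exp(5 * x)), x, y)$spearman, base)
    expect_equal(correlate(dplyr::mutate(d, y = y^3), x, y)$spearman, base)
  }
})

test_that("burden-size comparison joins diseases and ranks them", {
  burden <- tibble::tibble(
    label = c("Candidiasis", "Aspergillosis", "Histoplasmosis", "Other"),
    year = 2018,
    cases = c(25000, 15000, 3000, 100)
  )
  sizes <- tibble::tibble(
    label = c("candidiasis", "aspergillosis", "histoplasmosis"),
    year = 2018,
    unique_authors = c(250, 150, 30) # exactly proportional
  )
  out <- burden_vs_size(burden, sizes, 2018)
  expect_equal(out$spearman, 1)
  expect_equal(out$n, 3) # "Other" excluded by the inner join
  expect_error(burden_vs_size(burden[1:2, ], sizes, 2018), "at least 3")
})

test_that("permuted burden labels decorrelate on average", {
  set.seed(11)
  n <- 12
  truth <- tibble::tibble(
    label = paste0("d", 1:n), year = 2018,
    cases = sort(stats::rlnorm(n, 8, 1))
  )
  sizes <- tibble::tibble(
    label = paste0("d", 1:n), year = 2018,
    unique_authors = rank(truth$cases) * 10
  )
  expect_equal(burden_vs_size(truth, sizes, 2018)$spearman, 1)
  perms <- replicate(40, {
    shuffled <- dplyr::mutate(sizes, label = sample(label))
    burden_vs_size(truth, shuffled, 2018)$spearman
  })
  expect_lt(abs(mean(perms)), 0.2)
})
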