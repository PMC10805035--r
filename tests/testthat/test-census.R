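test_that("name keys fold case and whitespace but never merge distinct names", {
  expect_equal(name_key("SMITH", "john"), name_key("Smith", "John"))
  expect_false(name_key("Smith", "J") == name_key("Smith", "John"))
  expect_equal(name_key("Nguyen", "  Thi  Minh "), name_key("Nguyen", "Thi Minh"))
  # byte-level encoding variants of one printed name agree (NFC)...
  expect_equal(name_key("Nuñez", "José"), name_key("Nuñez", "José"))
  # ...but accents themselves are preserved
  expect_false(name_key("Muller", "Eva") == name_key("Müller", "Eva"))
  # concatenation cannot alias across the last/first boundary
  expect_false(name_key("ab", "c") == name_key("a", "bc"))
  expect_error(name_key("Smith", ""), "non-empty")
  expect_error(name_key(NA, "John"), "non-empty")
})

test_that("the census counts papers and per-year unique authors", {
  rs <- record_set("1", 2001L,
    authors = list(make_authors(c("Aa", "Bb"), c("Cc", "Dd")))
  )
  out <- census(rs, label = "toy")
  expect_equal(out$papers, 1L)
  expect_equal(out$unique_authors, 2L)

  rs2 <- record_set(c("1", "2"), c(2001L, 2001L),
    authors = rep(list(make_authors(c("Smith", "John"))), 2)
  )
  out2 <- census(rs2)
  expect_equal(out2$papers, 2L)
  expect_equal(out2$unique_authors, 1L)
})

test_that("census matches the brute-force name-set oracle on random corpora", {
  for (seed in 1:20) {
    spec <- small_corpus_spec(
      years = 2001:2006,
      rate = stats::runif(1, 0, 0.15),
      initial = sample(5:40, 1),
      name_collision_rate = stats::runif(1, 0, 0.2)
    )
    sim <- simulate_corpus(spec, seed = seed)
    rs <- eligible_records(sim$records, quiet = TRUE)
    got <- census(rs)
    want <- census_oracle(rs)
    expect_equal(got$year, want$year)
    expect_equal(got$unique_authors, want$unique_authors)
  }
})

test_that("census is monotone in records and invariant to record order", {
  sim <- simulate_corpus(small_corpus_spec(years = 2001:2004), seed = 3)
  rs <- eligible_records(sim$records, quiet = TRUE)
  full <- census(rs, label = "x")
  sub <- tibble::as_tibble(rs)[-c(1, 5), ]
  part <- census(record_set(sub$pmid, sub$year, sub$authors), label = "x")
  joined <- dplyr::left_join(part, full, by = c("label", "year"))
  expect_true(all(joined$unique_authors.x <= joined$unique_authors.y))
  expect_true(all(joined$papers.x <= joined$papers.y))

  set.seed(1)
  shuf <- tibble::as_tibble(rs)[sample(nrow(rs)), ]
  expect_equal(
    tibble::as_tibble(census(record_set(shuf$pmid, shuf$year, shuf$authors), label = "x")),
    tibble::as_tibble(full),
    ignore_attr = TRUE
  )
})

test_that("the cumulative variant dominates the per-year census", {
  sim <- simulate_corpus(small_corpus_spec(), seed = 6)
  rs <- eligible_records(sim$records, quiet = TRUE)
  per_year <- census(rs)
  cum <- census(rs, cumulative = TRUE)
  expect_true(all(diff(cum$unique_authors) >= 0))
  expect_true(all(cum$unique_authors >= per_year$unique_authors))
  expect_equal(cum$unique_authors[1], per_year$unique_authors[1])
})

test_that("series pooling stacks points and preserves regression structure", {
  s1 <- census(
    record_set(c("1", "2", "3"), c(2001L, 2002L, 2003L),
      authors = rep(list(make_authors(c("Aa", "Bb"))), 3)
    ),
    label = "f1"
  )
  s2 <- dplyr::mutate(s1, label = "f2")
  pooled1 <- merge_series(list(s1), mode = "pooled")
  expect_equal(nrow(pooled1), 3)
  pooled2 <- merge_series(list(s1, s2), mode = "pooled")
  expect_equal(nrow(pooled2), 6)

  # pooling two identical linear series leaves the OLS slope unchanged
  lin <- tibble::tibble(
    label = "a", year = 2001:2005,
    unique_authors = 10 + 3 * (0:4), papers = 5
  )
  lin2 <- dplyr::mutate(lin, label = "b")
  single <- fit_linear(lin)
  pooled <- fit_linear(merge_series(list(lin, lin2), mode = "pooled"))
  want <- ols_oracle(lin$year, lin$unique_authors)
  expect_equal(single$slope, want$slope, tolerance = 1e-12)
  expect_equal(pooled$slope, want$slope, tolerance = 1e-12)

  wide <- merge_series(list(s1, s2), mode = "per_field")
  expect_equal(names(wide), c("year", "f1", "f2"))
  expect_error(merge_series(list()), "at least one")
})
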