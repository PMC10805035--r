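#' Consumer price index tables
#'
#' Funding series are deflated with an annual-average all-urban-consumers
#' CPI. The base year defaults to the latest year in the table, so the
#' latest year's adjusted amounts equal the nominal ones.
#'
#' @param data data frame with columns `year` and `index` (index > 0).
#' @param base_year base year for adjustment; must be present in `data`.
#' @return A tibble of class `cpi_table` with a `base_year` attribute.
#' @export
#' @examples
#' cpi <- cpi_table(data.frame(year = 2020:2022, index = c(258.8, 271.0, 292.7)))
#' adjust_funding(1e6, 2020, cpi)
cpi_table <- function(data, base_year = max(data$year)) {
  if (!all(c("year", "index") %in% names(data))) {
    abort("cpi_table() needs columns 'year' and 'index'")
  }
  out <- tibble::tibble(year = as.integer(data$year), index = as.numeric(data$index))
  if (any(is.na(out$index)) || any(out$index <= 0)) abort("CPI index values must be positive")
  if (anyDuplicated(out$year)) abort("duplicate years in CPI table")
  if (!base_year %in% out$year) abort(glue::glue("base year {base_year} not present in CPI table"))
  structure(dplyr::arrange(out, .data$year),
    base_year = as.integer(base_year),
    class = c("cpi_table", class(tibble::tibble()))
  )
}

#' Derive a deflator from an adjusted/unadjusted amount pair
#'
#' The deflator for a year is `adjusted / unadjusted`; within one year it
#' is field-independent, which makes pairs of published nominal and
#' inflation-adjusted amounts a check on (and substitute for) the CPI
#' vintage that produced them.
#'
#' @param adjusted,unadjusted numeric vectors of amounts (USD);
#'   `unadjusted` must be positive.
#' @return Numeric vector of deflators.
#' @export
#' @examples
#' derive_deflator(2083159.08, 761372) # about 2.736
derive_deflator <- function(adjusted, unadjusted) {
  if (any(is.na(unadjusted)) || any(unadjusted <= 0)) {
    abort("unadjusted amounts must be positive")
  }
  adjusted / unadjusted
}

#' Deflators implied by a paired funding table
#'
#' Given a long funding table with both `Unadjusted` and `Adjusted` rows
#' per (label, year), returns the implied deflator of every pair — useful
#' for validating that same-year deflators agree across fields and for
#' reconstructing a CPI-equivalent series.
#'
#' @param funding data frame with columns `label`, `year`, `funding`,
#'   `inflation` (values `"Unadjusted"`/`"Adjusted"`, case-insensitive).
#' @return A tibble `label`, `year`, `deflator`.
#' @export
derive_deflators <- function(funding) {
  f <- tibble::as_tibble(funding) |>
    dplyr::filter(!is.na(.data$funding)) |>
    dplyr::mutate(inflation = stringr::str_to_lower(.data$inflation))
  wide <- tidyr::pivot_wider(
    f[, c("label", "year", "funding", "inflation")],
    names_from = "inflation", values_from = "funding"
  )
  if (!all(c("unadjusted", "adjusted") %in% names(wide))) {
    abort("funding table needs both Unadjusted and Adjusted rows")
  }
  wide |>
    dplyr::filter(!is.na(.data$unadjusted), !is.na(.data$adjusted), .data$unadjusted > 0) |>
    dplyr::transmute(.data$label, .data$year,
      deflator = derive_deflator(.data$adjusted, .data$unadjusted)
    )
}

#' Adjust a nominal amount for inflation
#'
#' Converts nominal dollars of `year` into base-year dollars:
#' `amount * index[base_year] / index[year]`.
#'
#' @param amount numeric amounts in nominal USD.
#' @param year integer year(s) of the amounts; every year must appear in
#'   the CPI table.
#' @param cpi a [cpi_table()].
#' @return Numeric vector of base-year USD.
#' @export
adjust_funding <- function(amount, year, cpi) {
  if (!inherits(cpi, "cpi_table")) cpi <- cpi_table(cpi)
  idx <- setNames(cpi$index, cpi$year)
  year <- as.integer(year)
  missing_years <- setdiff(unique(year), cpi$year)
  if (length(missing_years)) {
    abort(glue::glue("year(s) not in CPI table: {paste(missing_years, collapse = ', ')}"))
  }
  base <- attr(cpi, "base_year")
  amount * idx[[as.character(base)]] / unname(idx[as.character(year)])
}

#' Funding per unique author
#'
#' Joins a per-year funding series with a census series and divides:
#' the per-capita resource measure of a field. Years present in only one
#' input are dropped (intersection semantics); years with zero authors
#' are skipped with a warning.
#'
#' @param funding data frame with columns `year`, `funding` (and
#'   optionally `label`).
#' @param series census tibble with columns `year`, `unique_authors` (and
#'   optionally `label`); when both sides carry `label` the join includes it.
#' @return A tibble `label?`, `year`, `funding`, `unique_authors`,
#'   `funding_per_author`.
#' @export
funding_per_author <- function(funding, series) {
  by <- intersect(c("label", "year"), intersect(names(funding), names(series)))
  if (!"year" %in% by) abort("both inputs need a 'year' column")
  joined <- dplyr::inner_join(
    tibble::as_tibble(funding)[, intersect(names(funding), c("label", "year", "funding"))],
    tibble::as_tibble(series)[, intersect(names(series), c("label", "year", "unique_authors"))],
    by = by
  )
  if (nrow(joined) == 0) abort("no overlapping years between funding and census series")
  zero <- joined$unique_authors == 0
  if (any(zero)) {
    warn(glue::glue("skipped {sum(zero)} year(s) with zero unique authors"))
    joined <- joined[!zero, , drop = FALSE]
  }
  dplyr::mutate(joined, funding_per_author = .data$funding / .data$unique_authors)
}

#' Correlate two paired series
#'
#' Pearson product-moment and Spearman rank correlation (average ranks on
#' ties) on complete pairs of two columns.
#'
#' @param data a data frame.
#' @param x,y column names (tidy-select, unquoted or strings).
#' @return A one-row tibble: `x_label`, `y_label`, `pearson`, `spearman`,
#'   `n`, `degenerate` (`TRUE` when either variable has zero variance, in
#'   which case both coefficients are `NA`).
#' @export
#' @examples
#' correlate(data.frame(a = 1:5, b = c(2, 4, 5, 7, 9)), a, b)
correlate <- function(data, x, y) {
  xq <- rlang::as_name(rlang::enquo(x))
  yq <- rlang::as_name(rlang::enquo(y))
  d <- tibble::tibble(x = as.numeric(data[[xq]]), y = as.numeric(data[[yq]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) abort("correlate() needs at least 3 complete pairs")
  degenerate <- stats::var(d$x) == 0 || stats::var(d$y) == 0
  if (degenerate) {
    warn("zero variance in one variable: correlation undefined")
    pe <- sp <- NA_real_
  } else {
    pe <- cor(d$x, d$y, method = "pearson")
    sp <- cor(d$x, d$y, method = "spearman")
  }
  tibble::tibble(
    x_label = xq, y_label = yq,
    pearson = pe, spearman = sp, n = nrow(d), degenerate = degenerate
  )
}

#' Correlate field size with disease case burden
#'
#' Inner-joins a case-burden table with a census table on case-folded
#' disease label for one year and correlates case counts with
#' unique-author counts across diseases. Spearman is the headline
#' statistic; Pearson is reported alongside.
#'
#' @param burden data frame with columns `label`, `year`, `cases`.
#' @param census_tbl census tibble with columns `label`, `year`,
#'   `unique_authors`.
#' @param year the comparison year.
#' @return A one-row tibble as from [correlate()].
#' @export
burden_vs_size <- function(burden, census_tbl, year) {
  b <- tibble::as_tibble(burden) |>
    dplyr::filter(.data$year == !!year) |>
    dplyr::mutate(label_key = stringr::str_to_lower(stringr::str_squish(.data$label)))
  s <- tibble::as_tibble(census_tbl) |>
    dplyr::filter(.data$year == !!year) |>
    dplyr::mutate(label_key = stringr::str_to_lower(stringr::str_squish(.data$label)))
  joined <- dplyr::inner_join(
    b[, c("label_key", "cases")], s[, c("label_key", "unique_authors")],
    by = "label_key"
  )
  if (nrow(joined) < 3) {
    abort(glue::glue("need at least 3 diseases shared in {year}; got {nrow(joined)}"))
  }
  correlate(joined, cases, unique_authors)
}
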