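#' Normalised author name keys
#'
#' Unique authors are defined by the exact (first, last) name pair as
#' recorded in the database, after a deterministic normalisation: Unicode
#' canonical composition (NFC), trimming, collapsing of internal
#' whitespace, and case folding. No fuzzy merging is performed: initials
#' never expand ("Smith, J" stays distinct from "Smith, John"), and
#' accents are preserved (é differs from e) because stripping them would
#' merge distinct names. Homonymous authors therefore merge and
#' name-variant authors split — a stated limitation of the census, which
#' is reported rather than corrected.
#'
#' @param last,first character vectors of equal length; both must be
#'   non-empty for every element (filter with [eligible_records()] first).
#' @return A character vector of keys (one per input pair).
#' @export
#' @examples
#' name_key("SMITH", "john") == name_key("Smith", "John")
#' name_key("Smith", "J") == name_key("Smith", "John")
name_key <- function(last, first) {
  last <- as.character(last)
  first <- as.character(first)
  if (length(last) != length(first)) abort("last and first must have equal length")
  bad <- is.na(last) | is.na(first) |
    !nzchar(stringr::str_trim(last)) | !nzchar(stringr::str_trim(first))
  if (any(bad)) {
    abort("name_key() requires non-empty first and last names; apply eligible_records() first")
  }
  norm <- function(x) {
    stringr::str_to_lower(stringr::str_squish(stringi::stri_trans_nfc(x)))
  }
  paste(norm(last), norm(first), sep = "\u001f")
}

#' Census a field: unique authors and papers per year
#'
#' The core field-size measurement: for each calendar year present in the
#' record set, counts the number of papers and the number of unique author
#' name keys appearing on that year's bylines. Uniqueness is per calendar
#' year (an author active in several years counts once in each), not
#' cumulative; set `cumulative = TRUE` for the unique-names-to-date
#' variant. Years with no records are omitted (gaps, never interpolated).
#'
#' @param rs a [record_set()] that has passed [eligible_records()].
#' @param label field label attached to every row (default: provenance).
#' @param cumulative count unique names to date instead of per year.
#' @return A tibble of class `field_size_tbl` with columns `label`, `year`,
#'   `unique_authors`, `papers`, ordered by year.
#' @export
#' @examples
#' rs <- record_set(c("1", "2"), c(2001L, 2001L),
#'   authors = rep(list(data.frame(last = "Smith", first = "John")), 2))
#' census(rs, label = "toy") # papers 2, unique_authors 1
census <- function(rs, label = attr(rs, "provenance") %||% "field", cumulative = FALSE) {
  long <- authors_long(rs)
  papers <- tibble::as_tibble(rs) |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::count(.data$year, name = "papers")
  long <- dplyr::filter(long, !is.na(.data$year))
  long$key <- name_key(long$last, long$first)
  if (cumulative) {
    yrs <- sort(unique(long$year))
    uniq <- tibble::tibble(
      year = yrs,
      unique_authors = purrr::map_int(yrs, ~ length(unique(long$key[long$year <= .x])))
    )
  } else {
    uniq <- long |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(unique_authors = dplyr::n_distinct(.data$key), .groups = "drop")
  }
  out <- dplyr::inner_join(uniq, papers, by = "year") |>
    dplyr::arrange(.data$year) |>
    dplyr::mutate(label = label, .before = 1)
  new_field_size_tbl(out)
}

new_field_size_tbl <- function(x) {
  class(x) <- unique(c("field_size_tbl", class(tibble::tibble())))
  x
}

#' Combine field-size series across fields
#'
#' Two combination modes for a set of per-field census series (e.g. all
#' fungal pathogens in one WHO priority category):
#' * `"per_field"`: an aligned year-by-field table of unique-author
#'   counts (one column per field, gaps as `NA`).
#' * `"pooled"`: the stacked (year, count) point set under a single pooled
#'   label, suitable for a single combined regression. Points are stacked,
#'   never summed — summing would double-count authors shared between
#'   fields.
#'
#' @param series a list of census tibbles (from [census()]) or a single
#'   tibble with a `label` column covering several fields.
#' @param mode `"per_field"` or `"pooled"`.
#' @param pooled_label label for the pooled series.
#' @return A tibble: wide year-by-field for `"per_field"`, a
#'   `field_size_tbl` of stacked points for `"pooled"`.
#' @export
merge_series <- function(series, mode = c("per_field", "pooled"), pooled_label = "pooled") {
  mode <- match.arg(mode)
  if (is.data.frame(series)) series <- list(series)
  if (length(series) == 0) abort("merge_series() needs at least one series")
  stacked <- dplyr::bind_rows(purrr::map(series, tibble::as_tibble))
  if (nrow(stacked) == 0) abort("merge_series() got only empty series")
  if (mode == "pooled") {
    out <- stacked |>
      dplyr::mutate(label = pooled_label) |>
      dplyr::arrange(.data$year)
    return(new_field_size_tbl(out))
  }
  tidyr::pivot_wider(
    stacked[, c("label", "year", "unique_authors")],
    names_from = "label", values_from = "unique_authors"
  ) |>
    dplyr::arrange(.data$year)
}

#' Plot a field-size series
#'
#' Unique authors and papers per year, one panel per field label.
#'
#' @param object a `field_size_tbl` from [census()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.field_size_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("unique_authors", "papers"),
    names_to = "measure", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$count, colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), scales = "free_y") +
    ggplot2::labs(x = "year", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}
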