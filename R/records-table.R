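#' Write and read the flat records table
#'
#' The delimited interchange form of a record set: one row per
#' (pmid, author position), tab-separated, header `pmid, year, last,
#' first`, ordered by pmid then byline position. A record with an empty
#' author list is represented by a single row with empty `last` and
#' `first` so that the round trip preserves its pmid and year.
#' `read_records_table(write_records_table(rs))` reproduces `rs` up to the
#' fields the table keeps (pmid, year, author names; titles and initials
#' are census-irrelevant and not stored).
#'
#' @param rs a [record_set()].
#' @param path file path to write to (or read from).
#' @return `write_records_table()` returns `path` invisibly;
#'   `read_records_table()` returns a [record_set()].
#' @export
write_records_table <- function(rs, path) {
  long <- authors_long(rs)
  empty <- tibble::as_tibble(rs)[purrr::map_int(rs$authors, nrow) == 0, c("pmid", "year")]
  if (nrow(empty)) {
    empty <- dplyr::mutate(empty, position = 1L, last = "", first = "", initials = NA_character_)
    long <- dplyr::bind_rows(long, empty)
  }
  long <- dplyr::arrange(long, .data$pmid, .data$position)
  readr::write_tsv(long[, c("pmid", "year", "last", "first")], path, na = "")
  invisible(path)
}

#' @rdname write_records_table
#' @export
read_records_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      pmid = readr::col_character(),
      year = readr::col_character(),
      last = readr::col_character(),
      first = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  tab$year <- as.integer(dplyr::na_if(tab$year, ""))
  if (nrow(tab) == 0) {
    return(record_set(provenance = path))
  }
  recs <- split(tab, tab$pmid)
  authors <- purrr::map(recs, function(g) {
    g <- g[nzchar(g$last) | nzchar(g$first), , drop = FALSE]
    tibble::tibble(last = g$last, first = g$first, initials = NA_character_)
  })
  record_set(
    pmid = names(recs),
    year = purrr::map_int(recs, ~ .x$year[1]),
    authors = unname(authors),
    provenance = path
  )
}
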