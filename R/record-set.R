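#' Publication record sets
#'
#' A record set is the package's container for parsed bibliographic records:
#' a tibble with one row per article and columns
#' \describe{
#'   \item{pmid}{character article identifier, unique within the set}
#'   \item{year}{integer publication year, `NA` when the source lacks a
#'     parseable date}
#'   \item{title}{character, may be `NA`}
#'   \item{authors}{list column; each element is a tibble with columns
#'     `last`, `first`, `initials` (character, `NA` where absent), one row
#'     per byline author in byline order}
#' }
#' The set carries a `provenance` attribute (file path or query descriptor).
#' Author name fields preserve the source text verbatim; normalisation
#' happens only when names are turned into census keys (see [name_key()]).
#'
#' @param pmid character vector of identifiers.
#' @param year integer vector of publication years (`NA` allowed).
#' @param authors list of data frames with columns `last`, `first`,
#'   `initials`, one per record.
#' @param title optional character vector of titles.
#' @param provenance single string describing where the records came from.
#'
#' @return A tibble of class `record_set`.
#' @export
#' @examples
#' record_set(
#'   pmid = "1",
#'   year = 2001L,
#'   authors = list(data.frame(last = "Rivera", first = "Ana", initials = "A"))
#' )
record_set <- function(pmid = character(), year = integer(),
                       authors = list(), title = NULL,
                       provenance = "constructed") {
  pmid <- as.character(pmid)
  year <- as.integer(year)
  title <- if (is.null(title)) rep(NA_character_, length(pmid)) else as.character(title)
  authors <- unname(purrr::map(authors, as_author_tbl))
  out <- tibble::tibble(pmid = pmid, year = year, title = title, authors = authors)
  validate_record_set(new_record_set(out, provenance))
}

new_record_set <- function(x, provenance = "constructed") {
  structure(x,
    class = c("record_set", class(tibble::tibble())),
    provenance = provenance
  )
}

as_author_tbl <- function(a) {
  stopifnot(all(c("last", "first") %in% names(a)))
  new_author_tbl(
    as.character(a$last),
    as.character(a$first),
    if ("initials" %in% names(a)) as.character(a$initials) else NULL
  )
}

# validation-free tibble constructor: author tables are built in bulk
new_author_tbl <- function(last, first, initials = NULL) {
  initials <- initials %||% rep(NA_character_, length(last))
  tibble::new_tibble(
    list(last = last, first = first, initials = initials),
    nrow = length(last)
  )
}

validate_record_set <- function(rs) {
  if (anyNA(rs$pmid) || any(!nzchar(rs$pmid))) {
    abort("every record needs a non-empty pmid")
  }
  if (anyDuplicated(rs$pmid)) {
    abort("pmids must be unique within a record_set (use collapse_pmids())")
  }
  yr <- rs$year[!is.na(rs$year)]
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  if (length(yr) && (any(yr < 1800L) || any(yr > this_year + 1L))) {
    abort("publication years must lie in [1800, current year + 1]")
  }
  rs
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf(
    "<record_set: %d records, provenance: %s>\n",
    nrow(x), attr(x, "provenance") %||% "unknown"
  ))
  NextMethod()
}

# dplyr verbs strip custom classes; keep helpers for rebuilding
restore_record_set <- function(x, template) {
  new_record_set(tibble::as_tibble(x), attr(template, "provenance") %||% "constructed")
}

#' Collapse duplicate identifiers to their first occurrence
#'
#' PubMed exports can repeat records across result pages, so the parsers
#' collapse duplicated pmids keeping the first occurrence and report how
#' many rows were dropped.
#'
#' @param x a tibble shaped like a [record_set()] (duplicate pmids allowed).
#' @param provenance provenance string for the result.
#' @return A `record_set`; number of collapsed rows is reported via a message.
#' @export
collapse_pmids <- function(x, provenance = attr(x, "provenance") %||% "constructed") {
  dup <- duplicated(x$pmid)
  if (any(dup)) {
    inform(glue::glue("collapsed {sum(dup)} duplicate pmid(s) to first occurrence"))
    x <- x[!dup, , drop = FALSE]
  }
  validate_record_set(new_record_set(tibble::as_tibble(x), provenance))
}

#' Flatten a record set to one row per author position
#'
#' @param rs a [record_set()].
#' @return A tibble with columns `pmid`, `year`, `position`, `last`,
#'   `first`, `initials`. Records with no authors contribute no rows.
#' @export
#' @examples
#' rs <- record_set("9", 1999L,
#'   authors = list(data.frame(last = c("Ho", "Diaz"), first = c("Mei", "Luis"))))
#' authors_long(rs)
authors_long <- function(rs) {
  if (nrow(rs) == 0) {
    return(tibble::tibble(
      pmid = character(), year = integer(), position = integer(),
      last = character(), first = character(), initials = character()
    ))
  }
  n <- purrr::map_int(rs$authors, ~ length(.x$last))
  tibble::tibble(
    pmid = rep(rs$pmid, n),
    year = rep(rs$year, n),
    position = sequence(n),
    last = unlist(purrr::map(rs$authors, "last"), use.names = FALSE) %||% character(),
    first = unlist(purrr::map(rs$authors, "first"), use.names = FALSE) %||% character(),
    initials = unlist(purrr::map(rs$authors, "initials"), use.names = FALSE) %||% character()
  )
}
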