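#' Apply the census eligibility filter
#'
#' The unique-author census only counts articles with a publication date
#' and authors with a recorded first and last name. This filter
#' * removes, within each record, authors whose `first` or `last` field is
#'   empty or missing (abbreviated `AU`-only authors therefore drop out);
#' * removes records whose year is absent or whose author list becomes
#'   empty.
#'
#' The filter is total (never errors) and idempotent. Counts of dropped
#' records and authors are reported via a message and attached as the
#' `drop_counts` attribute.
#'
#' @param rs a [record_set()].
#' @param quiet suppress the drop-count message.
#' @return The filtered `record_set`, with attribute
#'   `drop_counts = c(records = ..., authors = ...)`.
#' @export
#' @examples
#' rs <- record_set(
#'   pmid = c("1", "2"),
#'   year = c(2000L, NA),
#'   authors = list(
#'     data.frame(last = c("Smith", "Doe"), first = c("John", "")),
#'     data.frame(last = "Lee", first = "Ana")
#'   )
#' )
#' eligible_records(rs) # record 2 excluded (no year); Doe dropped (no first)
eligible_records <- function(rs, quiet = FALSE) {
  n_rec0 <- nrow(rs)
  n_auth0 <- sum(purrr::map_int(rs$authors, nrow))

  filtered <- purrr::map(rs$authors, function(a) {
    ok <- !is.na(a$last) & nzchar(stringr::str_trim(a$last)) &
      !is.na(a$first) & nzchar(stringr::str_trim(a$first))
    if (all(ok)) a else new_author_tbl(a$last[ok], a$first[ok], a$initials[ok])
  })
  keep <- !is.na(rs$year) & purrr::map_int(filtered, nrow) > 0

  out <- tibble::as_tibble(rs)[keep, , drop = FALSE]
  out$authors <- filtered[keep]
  out <- restore_record_set(out, rs)

  n_auth1 <- sum(purrr::map_int(out$authors, nrow))
  drops <- c(records = n_rec0 - nrow(out), authors = n_auth0 - n_auth1)
  if (!quiet && any(drops > 0)) {
    inform(glue::glue(
      "eligibility filter dropped {drops[['records']]} record(s) and {drops[['authors']]} author name(s)"
    ))
  }
  attr(out, "drop_counts") <- drops
  out
}
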