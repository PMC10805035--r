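#' Build a field-defining query
#'
#' A field is denoted by a search query whose tokens are joined with `+`
#' (e.g. `"Penicillium+marneffei"`); genus-only and genus+species searches
#' are simply different token lists. Queries are unfielded: the backend is
#' expected to match them against title, abstract and keywords.
#'
#' @param terms character vector of one or more non-empty tokens.
#' @param label field label; defaults to the space-joined terms.
#' @return A one-row tibble of class `field_query` with columns `label`,
#'   `joined` and list-column `terms`.
#' @export
#' @examples
#' build_query(c("Penicillium", "marneffei"))
#' build_query("Cryptococcus")
build_query <- function(terms, label = paste(terms, collapse = " ")) {
  terms <- as.character(terms)
  if (length(terms) == 0 || any(is.na(terms)) || any(!nzchar(stringr::str_trim(terms)))) {
    abort("build_query() needs at least one non-empty term")
  }
  if (!nzchar(label)) abort("label must be non-empty")
  out <- tibble::tibble(
    label = label,
    joined = paste(terms, collapse = "+"),
    terms = list(terms)
  )
  class(out) <- c("field_query", class(out))
  out
}

#' Quantify sensitivity to query phrasing
#'
#' Even small differences in a query can markedly change the set of
#' returned articles. This compares two record sets (presumably retrieved
#' with different queries for the same intended field) by pmid overlap.
#'
#' @param rs_a,rs_b [record_set()]s to compare.
#' @param label_a,label_b labels for the two sides (default: provenance).
#' @return A one-row tibble: `label_a`, `label_b`, `n_a`, `n_b`,
#'   `n_intersection`, `jaccard` (0 when both sets are empty).
#' @export
#' @examples
#' a <- record_set(c("1", "2", "3"), rep(2000L, 3),
#'   authors = rep(list(data.frame(last = "X", first = "Y")), 3))
#' b <- record_set(c("2", "3", "4"), rep(2000L, 3),
#'   authors = rep(list(data.frame(last = "X", first = "Y")), 3))
#' compare_queries(a, b)
compare_queries <- function(rs_a, rs_b,
                            label_a = attr(rs_a, "provenance") %||% "a",
                            label_b = attr(rs_b, "provenance") %||% "b") {
  n_a <- length(unique(rs_a$pmid))
  n_b <- length(unique(rs_b$pmid))
  n_int <- length(intersect(rs_a$pmid, rs_b$pmid))
  union_n <- n_a + n_b - n_int
  tibble::tibble(
    label_a = label_a, label_b = label_b,
    n_a = n_a, n_b = n_b, n_intersection = n_int,
    jaccard = if (union_n == 0) 0 else n_int / union_n
  )
}

#' File-based record fetcher
#'
#' The retrieval contract is a function `f(query, from, to)` returning a
#' [record_set()] restricted to the requested year range (an `NA` bound is
#' open) together with a `total_hits` attribute. This implementation reads
#' from local MEDLINE or PubMed XML files, making the whole pipeline
#' runnable offline and reproducible; a live E-utilities client satisfying
#' the same contract can be plugged in where network retrieval is wanted.
#' Year restriction is applied post hoc from the parsed dates.
#'
#' @param paths character vector of file paths (`.xml` files are parsed as
#'   PubMed XML, anything else as MEDLINE text).
#' @return A fetcher function `f(query = NULL, from = NA, to = NA)`.
#' @export
file_fetcher <- function(paths) {
  if (length(paths) == 0 || !all(file.exists(paths))) {
    abort("file_fetcher(): all paths must exist")
  }
  force(paths)
  function(query = NULL, from = NA, to = NA) {
    sets <- purrr::map(paths, function(p) {
      if (grepl("\\.xml$", p, ignore.case = TRUE)) read_pubmed_xml(p) else read_medline(p)
    })
    all <- dplyr::bind_rows(purrr::map(sets, tibble::as_tibble))
    all <- collapse_pmids(all, provenance = paste(paths, collapse = ";"))
    keep <- rep(TRUE, nrow(all))
    if (!is.na(from)) keep <- keep & !is.na(all$year) & all$year >= from
    if (!is.na(to)) keep <- keep & !is.na(all$year) & all$year <= to
    out <- restore_record_set(tibble::as_tibble(all)[keep, , drop = FALSE], all)
    attr(out, "total_hits") <- nrow(out)
    out
  }
}
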