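#' Read PubMed XML records
#'
#' Parses a `PubmedArticleSet` document (the XML exchange format of the
#' same database the MEDLINE text format exports) into a [record_set()].
#' `LastName`/`ForeName`/`Initials` elements map to the author fields;
#' the year comes from `PubDate/Year`, falling back to the first 4-digit
#' token of `PubDate/MedlineDate` (so `"1998 Dec-1999 Jan"` yields 1998).
#' Author entries without a `LastName` (e.g. `CollectiveName` group
#' authors) are dropped with a warning; a document that is not well-formed
#' XML is a hard error.
#'
#' @param input a file path, URL, literal XML string, or connection
#'   accepted by [xml2::read_xml()].
#' @return A [record_set()].
#' @export
read_pubmed_xml <- function(input) {
  doc <- xml2::read_xml(input)
  provenance <- if (is.character(input) && length(input) == 1 && file.exists(input)) {
    input
  } else {
    "pubmed xml"
  }
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0) {
    return(record_set(provenance = provenance))
  }
  dropped <- 0L
  parsed <- purrr::map(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    year <- parse_pubdate(a)
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    au_nodes <- xml2::xml_find_all(a, ".//AuthorList/Author")
    has_last <- purrr::map_lgl(au_nodes, ~ !is.na(xml2::xml_find_first(.x, "./LastName")))
    dropped <<- dropped + sum(!has_last)
    au_nodes <- au_nodes[has_last]
    authors <- tibble::tibble(
      last = purrr::map_chr(au_nodes, ~ xml2::xml_text(xml2::xml_find_first(.x, "./LastName"))),
      first = purrr::map_chr(au_nodes, ~ {
        v <- xml2::xml_text(xml2::xml_find_first(.x, "./ForeName"))
        if (is.na(v)) "" else v
      }),
      initials = purrr::map_chr(au_nodes, ~ xml2::xml_text(xml2::xml_find_first(.x, "./Initials")))
    )
    list(pmid = pmid, year = year, title = title, authors = authors)
  })
  if (dropped > 0) {
    warn(glue::glue("dropped {dropped} author entr(ies) lacking a LastName (e.g. collective names)"))
  }
  out <- tibble::tibble(
    pmid = purrr::map_chr(parsed, "pmid"),
    year = purrr::map_int(parsed, "year"),
    title = purrr::map_chr(parsed, "title"),
    authors = purrr::map(parsed, "authors")
  )
  collapse_pmids(out, provenance)
}

parse_pubdate <- function(article) {
  y <- xml2::xml_text(xml2::xml_find_first(article, ".//Journal//PubDate/Year"))
  if (!is.na(y) && stringr::str_detect(y, "^\\d{4}$")) {
    return(as.integer(y))
  }
  md <- xml2::xml_text(xml2::xml_find_first(article, ".//Journal//PubDate/MedlineDate"))
  if (!is.na(md)) extract_year(md) else NA_integer_
}
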