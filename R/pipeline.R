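#' Packaged field-size and funding series for six fungal genera
#'
#' A compiled reference table of per-year unique-author counts, paper
#' counts and NIH funding (nominal and CPI-adjusted to 2022 dollars) for
#' six medically important fungal genera (Cryptococcus, Candida,
#' Histoplasma, Blastomyces, Coccidioides, Aspergillus) over 1985-2022,
#' plus single-year entries for a panel of other infectious-disease
#' fields. Blastomyces has no 1996 row: missing years are genuine gaps.
#' This table doubles as the layout contract for [census()] output and as
#' the source of the implied year deflators used in tests.
#'
#' @return A tibble with columns `year`, `label`, `unique_authors`,
#'   `papers`, `funding`, `query`, `inflation`
#'   (`"Unadjusted"`/`"Adjusted"`/`NA`).
#' @export
#' @examples
#' head(fungal_field_data())
fungal_field_data <- function() {
  path <- system.file("extdata", "fungal_field_funding.tsv",
    package = "fieldcensus", mustWork = TRUE
  )
  readr::read_tsv(
    path,
    col_types = readr::cols(
      year = readr::col_integer(),
      label = readr::col_character(),
      unique_authors = readr::col_integer(),
      papers = readr::col_integer(),
      funding = readr::col_double(),
      query = readr::col_character(),
      inflation = readr::col_character()
    ),
    na = "NA", progress = FALSE
  )
}

#' Run the census pipeline end to end
#'
#' Reads publication records, applies the eligibility filter, runs the
#' per-year unique-author census, fits and compares growth models, and —
#' when a funding table and CPI table are supplied — computes
#' inflation-adjusted funding per author. All stage outputs are written as
#' flat files under `out_dir` (`field_size.tsv`, `fits.tsv`, optional
#' `funding_per_author.tsv`) together with `report.json` holding the run
#' manifest (inputs, digests, package version, warning counts). Identical
#' inputs give byte-identical outputs.
#'
#' @param input a [record_set()], or character vector of MEDLINE/XML file
#'   paths.
#' @param out_dir output directory (created if needed).
#' @param label field label for the census.
#' @param funding optional data frame `year`, `funding` (nominal USD).
#' @param cpi optional [cpi_table()] used to adjust `funding`.
#' @return Invisibly, a list with elements `field_size`, `fits`,
#'   `funding_per_author` (or `NULL`) and `report`.
#' @export
run_census_pipeline <- function(input, out_dir, label = "field",
                                funding = NULL, cpi = NULL) {
  if (is.character(input)) {
    missing_files <- input[!file.exists(input)]
    if (length(missing_files)) {
      abort(glue::glue("input stage: missing file(s): {paste(missing_files, collapse = ', ')}"))
    }
    rs <- file_fetcher(input)()
    digests <- unname(tools::md5sum(input))
    inputs <- input
  } else if (inherits(input, "record_set")) {
    rs <- input
    digests <- NA_character_
    inputs <- attr(input, "provenance") %||% "in-memory record_set"
  } else {
    abort("input stage: input must be file paths or a record_set")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  filtered <- eligible_records(rs, quiet = TRUE)
  drops <- attr(filtered, "drop_counts")
  if (nrow(filtered) == 0) abort("census stage: no eligible records")

  size <- census(filtered, label = label)
  readr::write_tsv(tibble::as_tibble(size), file.path(out_dir, "field_size.tsv"))

  fits <- growth_fit_table(size)
  readr::write_tsv(fits, file.path(out_dir, "fits.tsv"))

  fpa <- NULL
  if (!is.null(funding)) {
    if (!is.null(cpi)) {
      funding <- dplyr::mutate(
        tibble::as_tibble(funding),
        funding = adjust_funding(.data$funding, .data$year, cpi)
      )
    }
    fpa <- funding_per_author(funding, size)
    readr::write_tsv(fpa, file.path(out_dir, "funding_per_author.tsv"))
  }

  report <- list(
    tool = "fieldcensus",
    version = as.character(utils::packageVersion("fieldcensus")),
    label = label,
    inputs = as.list(inputs),
    input_md5 = as.list(digests),
    records_in = nrow(rs),
    records_eligible = nrow(filtered),
    dropped_records = unname(drops[["records"]]),
    dropped_authors = unname(drops[["authors"]]),
    years = range(size$year),
    preferred_model = fits$model[which.max(fits$adj_r2)]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    field_size = size, fits = fits, funding_per_author = fpa, report = report
  ))
}
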