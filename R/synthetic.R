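#' Specify a synthetic publication corpus
#'
#' The generator emulates the data-generating process behind a field's
#' publication record: an active-author population following a prescribed
#' growth law, per-author yearly productivity, multi-author collaboration,
#' author turnover between years, and homonym collisions (two distinct
#' researchers sharing a printed name). Ground truth — the true number of
#' active authors and papers per year, and the name-to-author multiplicity
#' — is stored alongside the corpus so the census and growth fits can be
#' validated exactly.
#'
#' Defaults model a small biomedical subfield: each author leads on
#' average 1.5 paper-appearances a year (at least one, so every active
#' author is observable), bylines of 1–8 authors with mean about 3.9, 30%
#' of each year's authors new to the field, and a 2% homonym rate at
#' name-minting time.
#'
#' @param years integer vector of consecutive years (e.g. `1991:2020`).
#' @param growth a growth law from [growth_linear()] or
#'   [growth_exponential()] for the active-author population.
#' @param papers_per_author_mean mean yearly paper-appearances per active
#'   author (>= 1; each author appears at least once a year).
#' @param authors_per_paper probability vector over byline sizes `1, 2,
#'   ...`; byline sizes are truncated to the available population.
#' @param name_collision_rate probability in `[0, 1)` that a newly minted
#'   author reuses an existing name key (exact homonym).
#' @param author_turnover fraction in `[0, 1]` of each year's authors new
#'   to the field.
#' @return A `corpus_spec` list.
#' @export
#' @examples
#' spec <- corpus_spec(2001:2010, growth_exponential(rate = 0.08, initial = 50))
#' sim <- simulate_corpus(spec, seed = 7)
#' sim$truth$series
corpus_spec <- function(years,
                        growth,
                        papers_per_author_mean = 1.5,
                        authors_per_paper = c(0.10, 0.15, 0.20, 0.20, 0.15, 0.10, 0.06, 0.04),
                        name_collision_rate = 0.02,
                        author_turnover = 0.3) {
  years <- as.integer(years)
  stopifnot(length(years) >= 1, !anyNA(years))
  if (!inherits(growth, "growth_law")) abort("growth must come from growth_linear()/growth_exponential()")
  if (papers_per_author_mean < 1) abort("papers_per_author_mean must be >= 1 (every active author publishes)")
  if (any(authors_per_paper < 0) || sum(authors_per_paper) <= 0) abort("invalid byline-size distribution")
  if (name_collision_rate < 0 || name_collision_rate >= 1) abort("name_collision_rate must be in [0, 1)")
  if (author_turnover < 0 || author_turnover > 1) abort("author_turnover must be in [0, 1]")
  pop <- purrr::map_int(seq_along(years) - 1L, ~ as.integer(round(growth$fn(.x))))
  if (any(pop < 1)) {
    abort("infeasible spec: the growth law implies fewer than one active author in some year")
  }
  structure(
    list(
      years = years, growth = growth,
      population = pop,
      papers_per_author_mean = papers_per_author_mean,
      authors_per_paper = authors_per_paper / sum(authors_per_paper),
      name_collision_rate = name_collision_rate,
      author_turnover = author_turnover
    ),
    class = "corpus_spec"
  )
}

#' Growth laws for the synthetic author population
#'
#' `growth_linear()` gives a population `intercept + slope * t` and
#' `growth_exponential()` a population `initial * exp(rate * t)`, with
#' `t = 0, 1, ...` indexing years from the first simulated year.
#'
#' @param slope authors per year.
#' @param intercept authors in the first year.
#' @param rate continuous yearly growth rate.
#' @param initial authors in the first year.
#' @return A `growth_law` object.
#' @export
growth_linear <- function(slope, intercept) {
  structure(
    list(kind = "linear", slope = slope, intercept = intercept,
         fn = function(t) intercept + slope * t),
    class = "growth_law"
  )
}

#' @rdname growth_linear
#' @export
growth_exponential <- function(rate, initial) {
  structure(
    list(kind = "exponential", rate = rate, initial = initial,
         fn = function(t) initial * exp(rate * t)),
    class = "growth_law"
  )
}

# synthetic-only name material: pronounceable fragments crossed
# combinatorially; no real-person names intended
surname_pool <- function() {
  a <- c("Bal", "Cor", "Dren", "Fal", "Gor", "Hale", "Jor", "Kel", "Lor",
         "Mar", "Nor", "Pel", "Quin", "Rav", "Sol", "Tor", "Vel", "Wren",
         "Yar", "Zel")
  b <- c("an", "ber", "den", "dor", "en", "fen", "gan", "hart", "lin",
         "mond", "ner", "rick", "sen", "stad", "ton", "vek", "wick", "zor")
  as.vector(outer(a, b, paste0))
}

forename_pool <- function() {
  c("Amira", "Bren", "Calla", "Darin", "Elio", "Farrah", "Galen", "Hesper",
    "Ilsa", "Joren", "Kiva", "Lenna", "Maro", "Nadir", "Orla", "Pavel",
    "Quilla", "Renn", "Sorel", "Talia", "Ulric", "Vesna", "Wynn", "Xeni",
    "Yova", "Zarek", "Anselm", "Brig", "Cyra", "Doran", "Esmé", "Fiora")
}

#' Generate a synthetic corpus with ground truth
#'
#' Simulates the process described in [corpus_spec()]: per year, the
#' active-author set is formed by carrying over a `1 - author_turnover`
#' fraction of the previous year's authors and minting the rest (new
#' authors reuse an existing name key with probability
#' `name_collision_rate`); each active author draws
#' `1 + Poisson(papers_per_author_mean - 1)` paper-appearances; bylines
#' are assembled by drawing a size from the byline distribution and
#' sampling that many distinct authors in proportion to their remaining
#' appearances. Identical spec and seed give an identical corpus.
#'
#' @param spec a [corpus_spec()].
#' @param seed integer seed; the simulation is deterministic given
#'   (spec, seed).
#' @return A list:
#'   \describe{
#'     \item{records}{a [record_set()] of the synthetic articles}
#'     \item{truth}{list with `series` (tibble `year`, `true_authors`,
#'       `papers`) and `name_multiplicity` (tibble `key`, `n_authors`)}
#'   }
#' @export
simulate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(as.integer(seed), simulate_corpus_impl(spec))
}

simulate_corpus_impl <- function(spec) {
  surnames <- surname_pool()
  forenames <- forename_pool()
  # author registry grows as authors are minted
  auth_last <- character()
  auth_first <- character()
  auth_key <- character()
  used_names <- new.env(hash = TRUE, parent = emptyenv())

  mint_author <- function(collide) {
    if (collide && length(auth_key) > 0) {
      src <- sample.int(length(auth_key), 1)
      auth_last <<- c(auth_last, auth_last[src])
      auth_first <<- c(auth_first, auth_first[src])
      auth_key <<- c(auth_key, auth_key[src])
    } else {
      repeat {
        la <- sample(surnames, 1)
        fi <- sample(forenames, 1)
        nm <- paste(la, fi, sep = "|")
        if (is.null(used_names[[nm]])) {
          used_names[[nm]] <- TRUE
          break
        }
      }
      auth_last <<- c(auth_last, la)
      auth_first <<- c(auth_first, fi)
      auth_key <<- c(auth_key, name_key(la, fi))
    }
    length(auth_key)
  }

  sizes <- seq_along(spec$authors_per_paper)
  prev_active <- integer()
  papers <- list() # each element: list(year, author ids)
  truth_rows <- vector("list", length(spec$years))

  for (i in seq_along(spec$years)) {
    yr <- spec$years[i]
    n_target <- spec$population[i]
    n_carry <- min(floor((1 - spec$author_turnover) * n_target), length(prev_active))
    carried <- if (n_carry > 0) sample(prev_active, n_carry) else integer()
    n_new <- n_target - n_carry
    minted <- integer(n_new)
    if (n_new > 0) {
      collide <- stats::runif(n_new) < spec$name_collision_rate
      for (j in seq_len(n_new)) minted[j] <- mint_author(collide[j])
    }
    active <- c(carried, minted)

    # multiset of paper-appearance slots, permuted, cut into bylines;
    # a duplicated author within one byline is dropped (rare unless the
    # population is tiny), shrinking that byline rather than re-drawing
    rem <- 1L + stats::rpois(length(active), spec$papers_per_author_mean - 1)
    slots <- rep(seq_along(active), times = rem)
    slots <- slots[sample.int(length(slots))]
    sz <- integer(0)
    while (sum(sz) < length(slots)) {
      sz <- c(sz, sample(sizes, max(16L, length(slots)), replace = TRUE,
                         prob = spec$authors_per_paper))
    }
    cut_id <- rep(seq_along(sz), times = sz)[seq_along(slots)]
    bylines <- lapply(unname(split(slots, cut_id)), unique)
    papers <- c(papers, lapply(bylines, function(p) list(year = yr, authors = active[p])))
    truth_rows[[i]] <- tibble::tibble(
      year = yr, true_authors = length(active), papers = length(bylines)
    )
    prev_active <- active
  }

  authors_list <- purrr::map(papers, function(p) {
    new_author_tbl(
      auth_last[p$authors],
      auth_first[p$authors],
      stringr::str_sub(auth_first[p$authors], 1, 1)
    )
  })
  rs <- record_set(
    pmid = sprintf("SYN%07d", seq_along(papers)),
    year = purrr::map_int(papers, "year"),
    authors = authors_list,
    title = sprintf("Synthetic article %d", seq_along(papers)),
    provenance = "synthetic corpus"
  )
  multiplicity <- tibble::tibble(key = auth_key) |>
    dplyr::count(.data$key, name = "n_authors")
  list(
    records = rs,
    truth = list(
      series = dplyr::bind_rows(truth_rows),
      name_multiplicity = multiplicity
    )
  )
}

#' Write a record set as MEDLINE tagged text
#'
#' Serialises a record set to the tagged text format read by
#' [read_medline()]; the round trip is lossless for pmid, year and author
#' names (UTF-8 throughout, so diacritics survive byte-identically). An
#' empty record set yields an empty file.
#'
#' @param rs a [record_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
emit_medline <- function(rs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(rs) == 0) {
    return(invisible(path))
  }
  rec <- seq_len(nrow(rs))
  # assemble (record, rank, text) rows, then order; ranks: header 1-3,
  # author k at 10 + 2k (FAU) and 10 + 2k + 1 (AU), trailing blank at Inf
  header <- tibble::tibble(
    rec = rep(rec, 3),
    rank = rep(1:3, each = nrow(rs)),
    text = c(
      paste0("PMID- ", rs$pmid),
      ifelse(is.na(rs$year), NA, paste0("DP  - ", rs$year)),
      ifelse(is.na(rs$title), NA, paste0("TI  - ", rs$title))
    )
  )
  long <- authors_long(rs)
  long$rec <- match(long$pmid, rs$pmid)
  has_first <- !is.na(long$first) & nzchar(long$first)
  has_ini <- !is.na(long$initials) & nzchar(long$initials)
  fau <- ifelse(has_first, paste0("FAU - ", long$last, ", ", long$first), NA)
  au <- dplyr::case_when(
    has_first & has_ini ~ paste0("AU  - ", long$last, " ", long$initials),
    has_first ~ NA,
    has_ini ~ paste0("AU  - ", long$last, " ", long$initials),
    .default = paste0("AU  - ", long$last)
  )
  body <- tibble::tibble(
    rec = rep(long$rec, 2),
    rank = c(10 + 2 * long$position, 11 + 2 * long$position),
    text = c(fau, au)
  )
  blank <- tibble::tibble(rec = rec, rank = Inf, text = "")
  all_lines <- dplyr::bind_rows(header, body, blank) |>
    dplyr::filter(!is.na(.data$text)) |>
    dplyr::arrange(.data$rec, .data$rank)
  writeLines(enc2utf8(all_lines$text), con, useBytes = TRUE)
  invisible(path)
}
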