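#' Read MEDLINE tagged-text records
#'
#' Parses the tagged plain-text exchange format exported by Entrez for
#' PubMed records (`.nbib`, rettype "medline"). Only the fields the census
#' needs are kept: `PMID`, the publication date (`DP`), the title (`TI`)
#' and the author byline (`FAU` full-author lines, `AU` abbreviated lines).
#'
#' Parsing rules:
#' * `FAU` lines are split as `"Last, First"`; a following `AU` line for
#'   the same author supplies initials.
#' * An `AU` line with no preceding `FAU` yields an author with the last
#'   name and initials only; its `first` is empty, so such authors fail the
#'   eligibility filter (see [eligible_records()]).
#' * The year is the first 4-digit token of the `DP` value, so seasons and
#'   ranges such as `"1998 Dec-1999 Jan"` resolve to the leading year; an
#'   unparseable `DP` leaves the year `NA`.
#' * A line that is neither a tag line, a continuation (leading spaces) nor
#'   blank causes the enclosing record to be skipped with a warning.
#' * Duplicate PMIDs collapse to the first occurrence (reported).
#'
#' Input is treated as UTF-8; undecodable bytes are replaced (with a
#' warning), never fatal.
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @return A [record_set()].
#' @export
#' @examples
#' txt <- c(
#'   "PMID- 1",
#'   "DP  - 2003 Jul",
#'   "TI  - A short title.",
#'   "FAU - Harwell, Dana",
#'   "AU  - Harwell D"
#' )
#' read_medline(txt)
read_medline <- function(input) {
  lines <- read_input_lines(input)
  provenance <- if (is.character(input) && length(input) == 1 && file.exists(input)) {
    input
  } else {
    "medline text"
  }

  # classify every line once (tag / continuation / blank), fold
  # continuation lines into their tag line, then work block-wise
  m <- stringr::str_match(lines, "^([A-Z0-9]{1,4})\\s*- (.*)$")
  is_tag <- !is.na(m[, 1])
  is_blank <- !nzchar(stringr::str_trim(lines))
  is_cont <- !is_tag & !is_blank & stringr::str_detect(lines, "^\\s{2,}\\S")
  malformed_line <- !is_tag & !is_blank & !is_cont

  tags <- m[is_tag, 2]
  vals <- m[is_tag, 3]
  val_id <- cumsum(is_tag)
  if (any(is_cont & val_id > 0)) {
    use <- is_cont & val_id > 0
    agg <- tapply(stringr::str_trim(lines[use]), val_id[use], paste, collapse = " ")
    ids <- as.integer(names(agg))
    vals[ids] <- paste(vals[ids], agg)
  }

  is_pmid_line <- is_tag & m[, 2] == "PMID"
  if (!any(is_pmid_line)) {
    return(record_set(provenance = provenance))
  }
  block_of_line <- cumsum(is_pmid_line)
  block <- block_of_line[is_tag] # block id per tag row
  n_blocks <- max(block)
  bad_blocks <- unique(block_of_line[malformed_line & block_of_line > 0])

  in_block <- block > 0
  first_val <- function(tagname) {
    sel <- which(in_block & tags == tagname)
    sel <- sel[!duplicated(block[sel])]
    out <- rep(NA_character_, n_blocks)
    out[block[sel]] <- vals[sel]
    out
  }
  pmid <- stringr::str_trim(first_val("PMID"))
  year <- as.integer(stringr::str_extract(first_val("DP"), "\\b\\d{4}\\b"))
  title <- first_val("TI")

  authors <- parse_bylines(tags, vals, block, n_blocks)

  bad <- seq_len(n_blocks) %in% bad_blocks | is.na(pmid) | !nzchar(pmid)
  if (any(bad)) {
    warn(glue::glue("skipped {sum(bad)} malformed MEDLINE record(s)"))
  }
  out <- tibble::tibble(
    pmid = pmid[!bad], year = year[!bad], title = title[!bad],
    authors = authors[!bad]
  )
  collapse_pmids(out, provenance)
}

# vectorised FAU/AU byline parsing for all blocks at once; returns a list
# of author tables indexed by block
parse_bylines <- function(tags, vals, block, n_blocks) {
  sel <- which(block > 0 & tags %in% c("FAU", "AU"))
  if (length(sel) == 0) {
    return(rep(list(new_author_tbl(character(), character())), n_blocks))
  }
  t <- tags[sel]
  v <- vals[sel]
  b <- block[sel]
  prev_same <- c(FALSE, b[-1] == b[-length(b)])
  au_attaches <- t == "AU" & prev_same & c("", t[-length(t)]) == "FAU"

  # "Nguyen TM" -> last + initials; single token or no short final token ->
  # everything is the last name
  au_parts <- stringr::str_match(stringr::str_trim(v), "^(.*\\S)\\s+([A-Za-z]{1,3})$")
  au_last <- ifelse(is.na(au_parts[, 1]), stringr::str_trim(v), au_parts[, 2])
  au_ini <- au_parts[, 3]

  fau_parts <- stringr::str_match(v, "^(.*?),\\s*(.*)$")
  fau_last <- stringr::str_trim(ifelse(is.na(fau_parts[, 1]), v, fau_parts[, 2]))
  fau_first <- ifelse(is.na(fau_parts[, 1]), "", stringr::str_trim(fau_parts[, 3]))

  is_author_row <- t == "FAU" | (t == "AU" & !au_attaches)
  idx <- which(is_author_row)
  # initials for an FAU author come from a directly following attached AU
  nxt <- idx + 1L
  ini <- rep(NA_character_, length(idx))
  take <- t[idx] == "FAU" & nxt <= length(t) & au_attaches[pmin(nxt, length(t))]
  ini[take] <- au_ini[nxt[take]]
  ini[t[idx] == "AU"] <- au_ini[idx[t[idx] == "AU"]]

  author_tbl <- tibble::tibble(
    block = b[idx],
    last = ifelse(t[idx] == "FAU", fau_last[idx], au_last[idx]),
    first = ifelse(t[idx] == "FAU", fau_first[idx], ""),
    initials = ini
  )
  pieces <- split(
    seq_len(nrow(author_tbl)),
    factor(author_tbl$block, levels = seq_len(n_blocks))
  )
  purrr::map(unname(pieces), function(i) {
    new_author_tbl(author_tbl$last[i], author_tbl$first[i], author_tbl$initials[i])
  })
}

read_input_lines <- function(input) {
  if (inherits(input, "connection")) {
    return(readLines(input, encoding = "UTF-8", warn = FALSE))
  }
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    lines <- readLines(input, encoding = "UTF-8", warn = FALSE)
  } else if (is.character(input)) {
    lines <- unlist(stringr::str_split(input, "\n")) %||% character()
  } else {
    abort("input must be a file path, connection, or character vector")
  }
  bad <- !validUTF8(lines)
  if (any(bad)) {
    warn(glue::glue("replaced undecodable bytes on {sum(bad)} line(s)"))
    lines[bad] <- iconv(lines[bad], from = "UTF-8", to = "UTF-8", sub = "�")
  }
  lines
}

extract_year <- function(dp) {
  m <- stringr::str_extract(dp, "\\b\\d{4}\\b")
  if (is.na(m)) NA_integer_ else as.integer(m)
}
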